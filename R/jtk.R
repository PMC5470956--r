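# JTK-style nonparametric rhythmicity testing.
#
# The statistic is Kendall concordance between the observed series and a
# fixed-period cosine reference evaluated at each observation's ZT, scanned
# over candidate peak lags. Replicates at one ZT (and cosine symmetries)
# tie in the reference; ties are handled by tau-b. The null tail
# probability of the concordance count is exact for small series (dynamic
# programming over the permutation distribution, which with reference ties
# is the Jonckheere-Terpstra interleaving distribution) and a
# tie-corrected normal approximation with continuity correction otherwise.

.EXACT_N_MAX <- 30L

# Interleaving-count distribution of the Mann-Whitney count U for merging
# a block of size t into m existing elements; counts over U = 0..m*t.
.ucount <- function(m, t) {
  if (m == 0L || t == 0L) return(1)
  # 2D DP on counts: N[a,b](u) = N[a-1,b](u-b) + N[a,b-1](u)
  cur <- vector("list", m + 1L)
  for (a in 0:m) cur[[a + 1L]] <- 1           # b = 0
  for (b in seq_len(t)) {
    nxt <- vector("list", m + 1L)
    nxt[[1L]] <- 1                             # a = 0
    for (a in seq_len(m)) {
      v1 <- nxt[[a]]                           # N_{a-1, b}
      v2 <- cur[[a + 1L]]                      # N_{a, b-1}
      out <- numeric(a * b + 1L)
      out[seq_along(v2)] <- v2
      idx <- (b + 1L):(b + length(v1))
      out[idx] <- out[idx] + v1
      nxt[[a + 1L]] <- out
    }
    cur <- nxt
  }
  cur[[m + 1L]]
}

.convolveCounts <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

# Exact null pmf of the total concordance count J given reference
# tie-group sizes (order immaterial); support 0..sum_{k<l} t_k t_l.
.jtkNullDist <- function(groupSizes) {
  p <- 1
  n <- 0L
  for (t in as.integer(groupSizes)) {
    u <- .ucount(n, t)
    p <- if (identical(p, 1)) u else .convolveCounts(p, u)
    n <- n + t
  }
  p / sum(p)
}

# process-wide cache keyed by the sorted tie-group structure
.jtkDistCache <- new.env(parent = emptyenv())

.jtkNullDistCached <- function(groupSizes) {
  key <- paste(sort(groupSizes), collapse = ",")
  d <- .jtkDistCache[[key]]
  if (is.null(d)) {
    d <- .jtkNullDist(sort(groupSizes))
    .jtkDistCache[[key]] <- d
  }
  d
}

# Upper-tail probability of Kendall's S with reference ties, normal
# approximation with tie correction and continuity correction.
.jtkNormalTail <- function(S, n, refTies, obsTies) {
  t <- refTies; u <- obsTies
  v <- (n * (n - 1) * (2 * n + 5) - sum(t * (t - 1) * (2 * t + 5)) -
          sum(u * (u - 1) * (2 * u + 5))) / 18 +
    sum(t * (t - 1) * (t - 2)) * sum(u * (u - 1) * (u - 2)) /
      (9 * n * (n - 1) * (n - 2)) +
    sum(t * (t - 1)) * sum(u * (u - 1)) / (2 * n * (n - 1))
  if (v <= 0) return(1)
  stats::pnorm((S - 1) / sqrt(v), lower.tail = FALSE)
}

# Tie-group sizes of a numeric vector (order immaterial).
.tieSizes <- function(x) {
  as.vector(tabulate(match(x, unique(x))))
}

# Precompute per-lag reference structures shared by every gene tested on
# the same observation times.
.jtkRefs <- function(ztObs, period, lags) {
  n <- length(ztObs)
  lapply(lags, function(L) {
    ref <- round(cos(2 * pi * (ztObs - L) / period), 9)
    ties <- .tieSizes(ref)
    list(sr = sign(outer(ref, ref, "-")), ties = ties,
         K = choose(n, 2) - sum(choose(ties, 2)))
  })
}

# Core of the test for one series against precomputed references;
# returns plain scalars (fast path used by detectCyclers).
.jtkCore <- function(values, refs, lags, exact) {
  n <- length(values)
  if (length(unique(values)) == 1L)
    return(list(tau = NA_real_, best_lag = NA_real_, p_value = 1,
                degenerate = TRUE))
  sx <- sign(outer(values, values, "-"))
  obsTies <- .tieSizes(values)
  D0 <- choose(n, 2)
  Tobs <- sum(choose(obsTies, 2))
  ps <- numeric(length(refs))
  taus <- numeric(length(refs))
  for (i in seq_along(refs)) {
    r <- refs[[i]]
    S <- sum(sx * r$sr) / 2
    if (exact) {
      J <- (S + r$K) / 2
      d <- .jtkNullDistCached(r$ties)
      jv <- seq_along(d) - 1
      p <- sum(d[jv >= J - 1e-9])
    } else {
      p <- .jtkNormalTail(S, n, r$ties, obsTies)
    }
    ps[i] <- min(1, p)
    denom <- sqrt((D0 - sum(choose(r$ties, 2))) * (D0 - Tobs))
    taus[i] <- if (denom > 0) S / denom else NA_real_
  }
  best <- which.min(ps)
  list(tau = taus[best], best_lag = lags[best],
       p_value = min(1, length(refs) * ps[best]), degenerate = FALSE)
}

#' JTK-style rhythmicity test for one expression series
#'
#' Tests a series observed at zeitgeber times `ztObs` for a fixed-period
#' rhythm by scanning cosine reference waveforms
#' \eqn{\cos\{2\pi(t - \mathrm{lag})/\mathrm{period}\}} over candidate
#' peak lags and scoring each with Kendall's tau-b between the observed
#' values and the reference values. The reported p-value is the minimum
#' one-sided (upper-tail) probability of the concordance count over lags,
#' Bonferroni-multiplied by the number of lags and capped at 1. The tail
#' is exact (permutation null by dynamic programming) for series of up to
#' 30 observations, and a tie-corrected normal approximation with
#' continuity correction beyond that.
#'
#' A constant series has no defined concordance; it is reported as
#' degenerate with `p_value = 1` and `tau = NA`, not as an error.
#'
#' @param values numeric expression values (replicates included).
#' @param ztObs zeitgeber time of each observation (hours); at least two
#'   distinct times are required.
#' @param period rhythm period in hours (default 24; fixed, not searched).
#' @param lags candidate peak lags in hours (default every 2 h over the
#'   period).
#' @param exact force (`TRUE`)/suppress (`FALSE`) the exact null; default
#'   `NULL` switches on series length (exact up to n = 30).
#' @return a one-row [S4Vectors::DataFrame] with `tau` (at the best lag),
#'   `best_lag`, `period`, `p_value`, `degenerate`.
#' @examples
#' t6 <- c(2, 6, 10, 14, 18, 22)
#' jtkTest(cos(2 * pi * (t6 - 6) / 24), t6)  # best_lag 6, tau 1
#' @export
jtkTest <- function(values, ztObs, period = 24,
                    lags = seq(0, period - 2, by = 2), exact = NULL) {
  if (length(values) != length(ztObs))
    stop("values and ztObs must have equal length")
  if (length(unique(ztObs)) < 2L)
    stop("at least two distinct ZTs are required")
  if (any(!is.finite(values)))
    stop("all values must be finite")
  n <- length(values)
  if (is.null(exact)) exact <- n <= .EXACT_N_MAX
  refs <- .jtkRefs(ztObs, period, lags)
  res <- .jtkCore(values, refs, lags, exact)
  DataFrame(tau = res$tau, best_lag = res$best_lag, period = period,
            p_value = res$p_value, degenerate = res$degenerate)
}

#' Detect rhythmic genes in one condition
#'
#' Applies [jtkTest()] to every sufficiently expressed gene of one
#' condition (time-averaged mean abundance of at least 1 on the FPKM-like
#' scale) and controls the false discovery rate across genes by
#' Benjamini-Hochberg. A gene is called rhythmic when its q-value is at
#' most `alpha`.
#'
#' @param ce a [CircadianExperiment-class].
#' @param cond `"sham"` or `"tumor"`.
#' @param alpha FDR level for the rhythmic call (default 0.05).
#' @param period,lags passed to [jtkTest()].
#' @return a [S4Vectors::DataFrame] with one row per tested gene:
#'   `gene_id`, `condition`, `tau`, `best_lag`, `period`, `p_value`,
#'   `q_value`, `rhythmic`, `degenerate`. Genes failing the expression
#'   filter are listed in `metadata(.)$filtered_out`.
#' @export
detectCyclers <- function(ce, cond, alpha = 0.05, period = 24,
                          lags = seq(0, period - 2, by = 2)) {
  stopifnot(methods::is(ce, "CircadianExperiment"))
  keep <- condition(ce) == cond
  if (!any(keep)) stop("condition '", cond, "' not present")
  ab <- abundance(ce)[, keep, drop = FALSE]
  tz <- zt(ce)[keep]
  expressed <- rowMeans(ab) >= 1 & rowMeans(ab) > 0
  if (!any(expressed)) {
    warning("no genes pass the expression filter in condition ", cond)
    out <- DataFrame(gene_id = character(), condition = character(),
                     tau = numeric(), best_lag = numeric(),
                     period = numeric(), p_value = numeric(),
                     q_value = numeric(), rhythmic = logical(),
                     degenerate = logical())
    metadata(out)$filtered_out <- rownames(ab)
    return(out)
  }
  genes <- rownames(ab)[expressed]
  exact <- sum(keep) <= .EXACT_N_MAX
  refs <- .jtkRefs(tz, period, lags)
  rows <- lapply(genes, function(g)
    .jtkCore(ab[g, ], refs, lags, exact))
  out <- DataFrame(gene_id = genes, condition = cond,
                   tau = vapply(rows, `[[`, 0, "tau"),
                   best_lag = vapply(rows, `[[`, 0, "best_lag"),
                   period = period,
                   p_value = vapply(rows, `[[`, 0, "p_value"),
                   degenerate = vapply(rows, `[[`, TRUE, "degenerate"))
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$rhythmic <- out$q_value <= alpha & !out$degenerate
  metadata(out)$filtered_out <- setdiff(rownames(ab), genes)
  metadata(out)$alpha <- alpha
  out
}

#' Build the reliable-cycler set
#'
#' Combines the rhythmic genes detected in this dataset with an external
#' reference list of known cyclers: the reliable set is their
#' intersection, plus explicitly named manual additions that are rhythmic
#' in at least one of the two sources (genes supported by only one source
#' but independently validated).
#'
#' @param cyclersOurs character vector of genes called rhythmic here.
#' @param referenceList character vector of reference cycling genes.
#' @param manualAdditions character vector of genes to add by hand; each
#'   must appear in `cyclersOurs` or `referenceList`.
#' @return a [S4Vectors::DataFrame] with `gene_id` and `provenance`
#'   (`"both"` for intersection members, `"manual_addition"` otherwise),
#'   sorted by gene id (input order never matters).
#' @examples
#' buildReliableSet(c("a", "b", "c"), c("b", "c", "d"), "a")
#' @export
buildReliableSet <- function(cyclersOurs, referenceList,
                             manualAdditions = character()) {
  cyclersOurs <- unique(as.character(cyclersOurs))
  referenceList <- unique(as.character(referenceList))
  manualAdditions <- unique(as.character(manualAdditions))
  orphan <- setdiff(manualAdditions, union(cyclersOurs, referenceList))
  if (length(orphan))
    stop("validation error: manual addition(s) rhythmic in neither ",
         "source: ", paste(orphan, collapse = ", "))
  both <- intersect(cyclersOurs, referenceList)
  genes <- sort(union(both, manualAdditions))
  DataFrame(gene_id = genes,
            provenance = ifelse(genes %in% both, "both",
                                "manual_addition"))
}
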