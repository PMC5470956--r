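# Fixed-period cosinor regression and circular acrophase statistics.

#' Fit a fixed-period cosinor model
#'
#' Least-squares fit of \eqn{y(t) = b + A \cos\{2\pi(t - p)/\mathrm{period}\}}
#' with the period held fixed. The fit uses the exact linear
#' reparameterisation
#' \eqn{y = b + \beta_1\cos(\omega t) + \beta_2\sin(\omega t)} solved in
#' closed form, then \eqn{A = \sqrt{\beta_1^2+\beta_2^2}} and
#' \eqn{p = (\mathrm{period}/2\pi)\,\mathrm{atan2}(\beta_2, \beta_1) \bmod
#' \mathrm{period}} — algebraically identical to the nonlinear
#' least-squares solution at fixed period, with no initialisation or
#' convergence tolerance. The amplitude is normalised nonnegative (a
#' negative solution maps to \eqn{p + 12 \bmod 24}).
#'
#' `zero_amplitude_p` is the p-value of the F test (2 numerator degrees of
#' freedom) of the cosinor against the intercept-only model, i.e. of
#' amplitude zero.
#'
#' Constant values yield a degenerate fit (`amplitude_A = 0`,
#' `acrophase_p = 0`, `degenerate = TRUE`) rather than an error; all
#' observation times identical is a singular design and errors.
#'
#' @param times observation times in hours (at least 4 observations at 3
#'   or more distinct times).
#' @param values expression values, same length as `times`.
#' @param period fixed period in hours (default 24).
#' @return a list with `mesor_b`, `amplitude_A`, `acrophase_p` (hours in
#'   \[0, period)), `rss`, `r_squared`, `zero_amplitude_p`, `n`,
#'   `degenerate`.
#' @examples
#' t6 <- c(2, 6, 10, 14, 18, 22)
#' fitCosinor(t6, 10 + 3 * cos(2 * pi * (t6 - 8) / 24))
#' @export
fitCosinor <- function(times, values, period = 24) {
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (any(!is.finite(values)) || any(!is.finite(times)))
    stop("times and values must be finite")
  if (length(values) < 4L || length(unique(times)) < 3L) {
    if (length(unique(times)) < 2L)
      stop("singular design: all observation times identical")
    stop("at least 4 observations at 3 or more distinct times required")
  }
  n <- length(values)
  if (length(unique(values)) == 1L) {
    return(list(mesor_b = values[1], amplitude_A = 0, acrophase_p = 0,
                rss = 0, r_squared = NA_real_, zero_amplitude_p = 1,
                n = n, degenerate = TRUE))
  }
  w <- 2 * pi / period
  X <- cbind(1, cos(w * times), sin(w * times))
  fit <- stats::lm.fit(X, values)
  beta <- fit$coefficients
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((values - mean(values))^2)
  A <- sqrt(beta[2]^2 + beta[3]^2)
  p <- if (A > 0) (atan2(beta[3], beta[2]) * period / (2 * pi)) %% period
       else 0
  Fstat <- ((tss - rss) / 2) / (rss / (n - 3))
  zp <- if (rss <= .Machine$double.eps * tss) .Machine$double.xmin
        else max(stats::pf(Fstat, 2, n - 3, lower.tail = FALSE),
                 .Machine$double.xmin)
  list(mesor_b = unname(beta[1]), amplitude_A = unname(A),
       acrophase_p = unname(p), rss = rss,
       r_squared = 1 - rss / tss, zero_amplitude_p = zp,
       n = n, degenerate = FALSE)
}

#' Cosinor fits for every gene of one condition
#'
#' @param ce a [CircadianExperiment-class].
#' @param cond `"sham"` or `"tumor"`.
#' @param period fixed period in hours.
#' @param useReplicates fit replicate-level observations (`TRUE`,
#'   default) or per-ZT means (`FALSE`).
#' @return a [S4Vectors::DataFrame], one row per gene, with the
#'   [fitCosinor()] fields plus `gene_id` and `condition`.
#' @export
cosinorByGene <- function(ce, cond, period = 24, useReplicates = TRUE) {
  stopifnot(methods::is(ce, "CircadianExperiment"))
  keep <- condition(ce) == cond
  if (!any(keep)) stop("condition '", cond, "' not present")
  ab <- abundance(ce)[, keep, drop = FALSE]
  tz <- zt(ce)[keep]
  if (!useReplicates) {
    grid <- sort(unique(tz))
    gn <- rownames(ab)
    ab <- vapply(grid, function(z)
      rowMeans(ab[, tz == z, drop = FALSE]), numeric(nrow(ab)))
    if (is.null(dim(ab))) ab <- matrix(ab, nrow = 1)
    rownames(ab) <- gn
    tz <- grid
  }
  # shared fixed design: solve all genes at once
  n <- length(tz)
  if (n < 4L || length(unique(tz)) < 3L)
    stop("at least 4 observations at 3 or more distinct times required")
  w <- 2 * pi / period
  X <- cbind(1, cos(w * tz), sin(w * tz))
  beta <- solve(crossprod(X), crossprod(X, t(ab)))   # 3 x genes
  fitted <- X %*% beta
  rss <- colSums((t(ab) - fitted)^2)
  rowMu <- rowMeans(ab)
  tss <- rowSums((ab - rowMu)^2)
  A <- sqrt(beta[2, ]^2 + beta[3, ]^2)
  p <- (atan2(beta[3, ], beta[2, ]) * period / (2 * pi)) %% period
  degenerate <- apply(ab, 1, function(v) length(unique(v)) == 1L)
  Fstat <- ((tss - rss) / 2) / (rss / (n - 3))
  zp <- pmax(stats::pf(Fstat, 2, n - 3, lower.tail = FALSE),
             .Machine$double.xmin)
  zp[rss <= .Machine$double.eps * tss] <- .Machine$double.xmin
  r2 <- 1 - rss / tss
  A[degenerate] <- 0
  p[degenerate] <- 0
  rss[degenerate] <- 0
  zp[degenerate] <- 1
  r2[degenerate] <- NA_real_
  DataFrame(gene_id = rownames(ab), condition = cond,
            mesor_b = unname(ifelse(degenerate, ab[, 1], beta[1, ])),
            amplitude_A = unname(A), acrophase_p = unname(p),
            rss = unname(rss), r_squared = unname(r2),
            zero_amplitude_p = unname(zp), n = n,
            degenerate = unname(degenerate))
}

#' Circular peak-time difference between two conditions
#'
#' Wraps the acrophase difference \eqn{\Delta = p_S - p_T} into
#' \eqn{(-12, 12]} hours: \eqn{\Delta = ((p_S - p_T + 12) \bmod 24) - 12},
#' with exact antiphase reported as +12 (boundary convention). Under this
#' sign convention a positive \eqn{\Delta} means the tumor peak occurs
#' earlier than the sham peak (phase advance).
#'
#' @param pSham,pTumor acrophases in hours, each in \[0, 24); vectorised.
#' @return numeric \eqn{\Delta} in \eqn{(-12, 12]} hours.
#' @examples
#' acrophaseDiff(6, 6)    # 0
#' acrophaseDiff(2, 14)   # 12 (antiphase)
#' acrophaseDiff(1, 22)   # 3
#' @export
acrophaseDiff <- function(pSham, pTumor) {
  if (any(pSham < 0 | pSham >= 24 | pTumor < 0 | pTumor >= 24,
          na.rm = TRUE))
    stop("domain error: acrophases must lie in [0, 24)")
  d <- ((pSham - pTumor + 12) %% 24) - 12
  d[!is.na(d) & d <= -12] <- 12
  d
}

#' Phase differences for paired cosinor fit tables
#'
#' @param fitsSham,fitsTumor per-gene fit tables from [cosinorByGene()]
#'   for the two conditions (matched on `gene_id`).
#' @return a [S4Vectors::DataFrame] with `gene_id`, `sham_acrophase`,
#'   `tumor_acrophase`, `delta` (hours in (-12, 12\]; `NA` when either
#'   fit is degenerate).
#' @export
phaseDifferences <- function(fitsSham, fitsTumor) {
  common <- intersect(fitsSham$gene_id, fitsTumor$gene_id)
  s <- fitsSham[match(common, fitsSham$gene_id), ]
  t <- fitsTumor[match(common, fitsTumor$gene_id), ]
  ok <- !s$degenerate & !t$degenerate
  delta <- rep(NA_real_, length(common))
  delta[ok] <- acrophaseDiff(s$acrophase_p[ok], t$acrophase_p[ok])
  DataFrame(gene_id = common, sham_acrophase = s$acrophase_p,
            tumor_acrophase = t$acrophase_p, delta = delta)
}

#' Classify an acrophase as day-time or night-time
#'
#' Under a 12:12 light/dark paradigm lights-off is ZT12; a gene peaking
#' in \[0, 12) is a day-time gene and one peaking in \[12, 24) a
#' night-time gene (half-open intervals; a peak at exactly ZT12 counts
#' as night).
#'
#' @param acrophase acrophase(s) in hours, each in \[0, 24). `NA`
#'   (degenerate fit) is refused as unclassifiable and returned as `NA`.
#' @return character vector of `"day_time"` / `"night_time"`.
#' @examples
#' classifyDayNight(c(6, 18, 12))  # day_time night_time night_time
#' @export
classifyDayNight <- function(acrophase) {
  if (any(acrophase < 0 | acrophase >= 24, na.rm = TRUE))
    stop("domain error: acrophase must lie in [0, 24)")
  ifelse(is.na(acrophase), NA_character_,
         ifelse(acrophase < 12, "day_time", "night_time"))
}
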