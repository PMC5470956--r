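# Per-timepoint two-condition comparison, fold-change scoring and the
# affected-gene tiering of the analysis pipeline.

.LOG2FC_THRESHOLD <- 0.585   # log2(1.5) to three decimals: "1.5-fold"
.PSEUDOCOUNT <- 0.5          # log-scale test only, never the reported FC

# Vectorised Welch two-sample t on log2(abundance + pseudocount).
# Returns p-values; NA where either group has < 2 replicates.
.welchLog2 <- function(matSham, matTumor, pseudocount = .PSEUDOCOUNT) {
  x <- log2(matSham + pseudocount)
  y <- log2(matTumor + pseudocount)
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2L || n2 < 2L) return(rep(NA_real_, nrow(x)))
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  # zero variance in both groups: the noiseless limit of the test is
  # p -> 0 for unequal means and p = 1 for equal means
  zv <- se2 == 0
  p[zv] <- ifelse(abs(m2 - m1)[zv] < 1e-12, 1, .Machine$double.xmin)
  unname(p)
}

#' Per-ZT differential comparison for every gene
#'
#' For each gene and each zeitgeber time, compares tumor against sham:
#' the log2 fold change is computed from the two group means
#' (tumor over sham) on genes passing [filterExpressed()] applied to
#' those means, and the p-value is a two-sided Welch test on
#' log2(abundance + 0.5). A gene x ZT result is `significant` when
#' p < `alpha` and the expression filter passed. Cells with fewer than
#' two replicates in either condition carry `p_value = NA` and are never
#' significant.
#'
#' @param ce a [CircadianExperiment-class].
#' @param alpha per-test significance threshold (default 0.05).
#' @return a [S4Vectors::DataFrame] with one row per gene x ZT:
#'   `gene_id`, `zt`, `mean_sham`, `mean_tumor`, `log2fc` (`NA` where the
#'   filter failed), `p_value`, `passed_filter`, `significant`.
#' @export
differentialByZT <- function(ce, alpha = 0.05) {
  stopifnot(methods::is(ce, "CircadianExperiment"))
  ztsS <- .conditionZts(ce, "sham")
  ztsT <- .conditionZts(ce, "tumor")
  grid <- intersect(ztsS, ztsT)
  if (!length(grid)) stop("no shared ZTs between conditions")
  ab <- abundance(ce)
  cond <- condition(ce); tz <- zt(ce)
  out <- lapply(grid, function(z) {
    ms <- ab[, cond == "sham" & tz == z, drop = FALSE]
    mt <- ab[, cond == "tumor" & tz == z, drop = FALSE]
    meanS <- unname(rowMeans(ms)); meanT <- unname(rowMeans(mt))
    passed <- filterExpressed(meanS, meanT)
    lfc <- rep(NA_real_, nrow(ab))
    lfc[passed] <- log2(meanT[passed] / meanS[passed])
    p <- .welchLog2(ms, mt)
    DataFrame(gene_id = rownames(ab), zt = z, mean_sham = meanS,
              mean_tumor = meanT, log2fc = lfc, p_value = p,
              passed_filter = passed,
              significant = !is.na(p) & p < alpha & passed)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$gene_id, res$zt), ]
  metadata(res)$zt_grid <- grid
  metadata(res)$alpha <- alpha
  res
}

#' Per-ZT comparison for a single gene and ZT
#'
#' Convenience accessor over [differentialByZT()] semantics for one
#' (gene, ZT) cell.
#'
#' @param ce a [CircadianExperiment-class].
#' @param gene gene id present in the experiment.
#' @param ztPoint a ZT present in both conditions.
#' @param alpha significance threshold.
#' @return a one-row [S4Vectors::DataFrame] as in [differentialByZT()].
#' @export
perZTTest <- function(ce, gene, ztPoint, alpha = 0.05) {
  if (!gene %in% rownames(abundance(ce)))
    stop("key error: gene '", gene, "' not in the experiment")
  grid <- intersect(.conditionZts(ce, "sham"), .conditionZts(ce, "tumor"))
  if (!ztPoint %in% grid)
    stop("key error: ZT ", ztPoint, " absent from the shared grid")
  res <- differentialByZT(ce[gene, ], alpha = alpha)
  res[res$zt == ztPoint, ]
}

#' Fold-change scores and ranking criteria per gene
#'
#' Summarises per-ZT differential results into the average-fold-change
#' ranking: `avg_abs_log2fc` is the mean over the ZT grid of |log2 fold
#' change|; `meets_avg_criterion` requires a more than 1.5-fold change on
#' average (|log2 FC| > 0.585, strict); `meets_peak_criterion` requires
#' some single ZT with |log2 FC| > 0.585 and p < 0.05;
#' `n_significant_zts` counts significant ZTs.
#'
#' @param diffResults output of [differentialByZT()]; every gene must
#'   cover the full ZT grid.
#' @return a [S4Vectors::DataFrame] with one row per gene.
#' @export
scoreGenes <- function(diffResults) {
  grid <- metadata(diffResults)$zt_grid
  if (is.null(grid)) grid <- sort(unique(diffResults$zt))
  d <- as.data.frame(diffResults[order(diffResults$gene_id,
                                       diffResults$zt), ])
  genes <- unique(d$gene_id)
  nz <- length(grid)
  if (nrow(d) != length(genes) * nz ||
      !all(d$zt == rep(sort(grid), length(genes))))
    stop("incomplete-profile error: every gene must cover the full ",
         "ZT grid exactly once")
  a <- matrix(abs(d$log2fc), ncol = nz, byrow = TRUE)
  p <- matrix(d$p_value, ncol = nz, byrow = TRUE)
  sig <- matrix(d$significant, ncol = nz, byrow = TRUE)
  avg <- rowMeans(a)                      # NA propagates: filtered cell
  peak <- rowSums(!is.na(a) & !is.na(p) &
                    a > .LOG2FC_THRESHOLD & p < 0.05) > 0
  DataFrame(gene_id = genes,
            avg_abs_log2fc = avg,
            n_significant_zts = as.integer(rowSums(sig)),
            meets_avg_criterion = !is.na(avg) & avg > .LOG2FC_THRESHOLD,
            meets_peak_criterion = peak)
}

#' Tier affected genes: non-circadian vs circadian impact patterns
#'
#' Non-circadian genes are partitioned into those significantly altered
#' at every ZT of the grid (`affected_all_zts`) and the rest (`other`).
#' Reliable cyclers are partitioned by the number of significant ZTs into
#' tiers `">=3"`, `"2"`, `"1"` and `"0"` (unaffected).
#'
#' @param scores per-gene scores from [scoreGenes()].
#' @param diffResults per-ZT results from [differentialByZT()].
#' @param reliableCyclers reliable-cycler table from [buildReliableSet()]
#'   or a character vector of gene ids.
#' @param nonCyclers character vector of non-circadian gene ids; must be
#'   disjoint from the reliable cyclers.
#' @return a list with `non_circadian` (DataFrame gene_id, tier),
#'   `circadian` (DataFrame gene_id, n_significant_zts, tier) and
#'   `counts` (named tier counts).
#' @export
tierGenes <- function(scores, diffResults, reliableCyclers, nonCyclers) {
  cyc <- if (is.character(reliableCyclers)) reliableCyclers
         else reliableCyclers$gene_id
  nonCyclers <- as.character(nonCyclers)
  overlap <- intersect(cyc, nonCyclers)
  if (length(overlap))
    stop("validation error: gene(s) in both cycler and non-cycler sets: ",
         paste(overlap, collapse = ", "))
  grid <- metadata(diffResults)$zt_grid
  if (is.null(grid)) grid <- sort(unique(diffResults$zt))

  nsig <- scores$n_significant_zts[match(nonCyclers, scores$gene_id)]
  nonTier <- ifelse(!is.na(nsig) & nsig == length(grid),
                    "affected_all_zts", "other")
  nonDF <- DataFrame(gene_id = nonCyclers, tier = nonTier)

  csig <- scores$n_significant_zts[match(cyc, scores$gene_id)]
  cTier <- ifelse(is.na(csig), "0",
                  ifelse(csig >= 3, ">=3", as.character(csig)))
  cDF <- DataFrame(gene_id = cyc, n_significant_zts = csig, tier = cTier)

  counts <- c(affected_all_zts = sum(nonTier == "affected_all_zts"),
              non_circadian_other = sum(nonTier == "other"),
              `cycler_>=3` = sum(cTier == ">=3"),
              cycler_2 = sum(cTier == "2"),
              cycler_1 = sum(cTier == "1"),
              cycler_0 = sum(cTier == "0"))
  list(non_circadian = nonDF[order(nonDF$gene_id), ],
       circadian = cDF[order(cDF$gene_id), ],
       counts = counts)
}
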