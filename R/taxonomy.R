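# Disruption-pattern taxonomy: one call per gene combining rhythmicity,
# cosinor and differential evidence.

#' Thresholds for the disruption decision tree
#'
#' @param phaseShiftMin smallest |delta| (hours) counting as a phase
#'   shift (default 2).
#' @param reversalMin smallest |delta| (hours) counting as a day-night
#'   reversal, i.e. within 3 h of perfect antiphase (default 9).
#' @param amplitudeRatioMin smallest amplitude ratio (larger over
#'   smaller) counting as an amplitude change (default 1.5).
#' @param zeroAmpAlpha significance level for the zero-amplitude F test
#'   used to confirm retained rhythm shape in step 5 (default 0.05).
#' @return a named list of thresholds.
#' @export
disruptionThresholds <- function(phaseShiftMin = 2, reversalMin = 9,
                                 amplitudeRatioMin = 1.5,
                                 zeroAmpAlpha = 0.05) {
  stopifnot(phaseShiftMin > 0, reversalMin > phaseShiftMin,
            amplitudeRatioMin > 1, zeroAmpAlpha > 0, zeroAmpAlpha < 1)
  list(phaseShiftMin = phaseShiftMin, reversalMin = reversalMin,
       amplitudeRatioMin = amplitudeRatioMin, zeroAmpAlpha = zeroAmpAlpha)
}

# The ordered decision tree for one gene. All inputs are scalars /
# small vectors already matched to the gene.
.callOne <- function(rhythmicSham, rhythmicTumor, delta, ampSham,
                     ampTumor, zeroPSham, zeroPTumor, nSig, lfcByZt,
                     th) {
  # estimated |delta| sits on a continuum; threshold comparisons carry a
  # small numeric slack so exact-boundary fits classify deterministically
  eps <- 1e-9
  absd <- if (is.na(delta)) NA_real_ else abs(delta)
  noPhaseEvidence <- is.na(absd) || absd < th$phaseShiftMin - eps
  evid <- sprintf("nsig=%d; delta=%s; rhythmic=%s/%s", nSig,
                  ifelse(is.na(delta), "NA", sprintf("%.2f", delta)),
                  rhythmicSham, rhythmicTumor)
  # (1) no differential signal and no phase signal
  if (nSig == 0L && noPhaseEvidence)
    return(list(category = "unaffected", evidence = evid))
  # (2) rhythm present in sham but lost in tumor
  if (rhythmicSham && !rhythmicTumor)
    return(list(category = "rhythm_lost", evidence = evid))
  bothRhythmic <- rhythmicSham && rhythmicTumor
  if (bothRhythmic && !is.na(absd)) {
    # (3) near-antiphase shift
    if (absd >= th$reversalMin - eps)
      return(list(category = "day_night_reversal", evidence = evid))
    # (4) moderate phase shift; delta = pS - pT > 0 means tumor peaks
    # earlier (advance)
    if (absd >= th$phaseShiftMin - eps)
      return(list(category = if (delta > 0) "phase_advance"
                             else "phase_delay", evidence = evid))
    # (5) same phase but changed amplitude, rhythm shape retained
    ratio <- max(ampSham, ampTumor) / max(min(ampSham, ampTumor),
                                          .Machine$double.eps)
    if (ratio >= th$amplitudeRatioMin - eps &&
        !is.na(zeroPSham) && !is.na(zeroPTumor) &&
        zeroPSham < th$zeroAmpAlpha && zeroPTumor < th$zeroAmpAlpha)
      return(list(category = "amplitude_change",
                  evidence = paste0(evid, sprintf("; amp_ratio=%.2f",
                                                  ratio))))
  }
  # (6) uniform change: differential signal with one consistent
  # direction across the day
  lfc <- lfcByZt[!is.na(lfcByZt)]
  if (nSig >= 1L && length(lfc)) {
    if (all(lfc > 0))
      return(list(category = "uniform_up", evidence = evid))
    if (all(lfc < 0))
      return(list(category = "uniform_down", evidence = evid))
  }
  # (7) residual
  list(category = "unaffected", evidence = evid)
}

#' Call a disruption category for every gene
#'
#' Combines the rhythmicity tests of both conditions, the paired cosinor
#' fits (for acrophase difference and amplitudes) and the per-ZT
#' differential evidence into exactly one category per gene, via an
#' ordered decision tree:
#'
#' 1. no significant ZT and no phase shift evidence: `unaffected`;
#' 2. rhythmic in sham, not in tumor: `rhythm_lost`;
#' 3. rhythmic in both, |delta| at least `reversalMin`:
#'    `day_night_reversal`;
#' 4. rhythmic in both, |delta| in \[`phaseShiftMin`, `reversalMin`):
#'    `phase_advance` when delta > 0 (tumor peak earlier) else
#'    `phase_delay`;
#' 5. rhythmic in both with unchanged phase but amplitude ratio at least
#'    `amplitudeRatioMin` (both zero-amplitude F tests significant):
#'    `amplitude_change`;
#' 6. at least one significant ZT with one consistent fold-change
#'    direction across the full day: `uniform_up` / `uniform_down`;
#' 7. otherwise `unaffected`.
#'
#' @param rhythmSham,rhythmTumor tables from [detectCyclers()] for the
#'   two conditions.
#' @param fitsSham,fitsTumor tables from [cosinorByGene()].
#' @param scores table from [scoreGenes()].
#' @param diffResults table from [differentialByZT()].
#' @param thresholds a [disruptionThresholds()] list.
#' @return a [S4Vectors::DataFrame] with one row per gene carrying all
#'   evidence: `gene_id`, `category`, `delta_hours`,
#'   `n_significant_zts`, `rhythmic_sham`, `rhythmic_tumor`,
#'   `day_night` (sham peak class), `evidence`.
#' @export
callDisruptions <- function(rhythmSham, rhythmTumor, fitsSham, fitsTumor,
                            scores, diffResults,
                            thresholds = disruptionThresholds()) {
  genes <- sort(Reduce(intersect,
                       list(rhythmSham$gene_id, rhythmTumor$gene_id,
                            fitsSham$gene_id, fitsTumor$gene_id,
                            scores$gene_id)))
  if (!length(genes))
    stop("incomplete-evidence error: no gene covered by every input")
  pd <- phaseDifferences(fitsSham, fitsTumor)
  lfcSplit <- split(diffResults$log2fc, diffResults$gene_id)
  if (!all(genes %in% names(lfcSplit)))
    stop("incomplete-evidence error: differential results missing for ",
         "some genes")
  iS <- match(genes, rhythmSham$gene_id)
  iT <- match(genes, rhythmTumor$gene_id)
  iFS <- match(genes, fitsSham$gene_id)
  iFT <- match(genes, fitsTumor$gene_id)
  iSc <- match(genes, scores$gene_id)
  iPd <- match(genes, pd$gene_id)
  rhyS <- rhythmSham$rhythmic[iS] %in% TRUE
  rhyT <- rhythmTumor$rhythmic[iT] %in% TRUE
  rows <- lapply(seq_along(genes), function(i) {
    call <- .callOne(rhyS[i], rhyT[i], pd$delta[iPd[i]],
                     fitsSham$amplitude_A[iFS[i]],
                     fitsTumor$amplitude_A[iFT[i]],
                     fitsSham$zero_amplitude_p[iFS[i]],
                     fitsTumor$zero_amplitude_p[iFT[i]],
                     scores$n_significant_zts[iSc[i]],
                     lfcSplit[[genes[i]]], thresholds)
  })
  dn <- ifelse(fitsSham$degenerate[iFS], NA_character_,
               classifyDayNight(fitsSham$acrophase_p[iFS]))
  DataFrame(gene_id = genes,
            category = vapply(rows, `[[`, "", "category"),
            delta_hours = pd$delta[iPd],
            n_significant_zts = scores$n_significant_zts[iSc],
            rhythmic_sham = rhyS, rhythmic_tumor = rhyT,
            day_night = dn,
            evidence = vapply(rows, `[[`, "", "evidence"))
}

#' Summarise disruption calls
#'
#' @param calls table from [callDisruptions()]; must be nonempty.
#' @return a list with `counts` (named category counts, summing to the
#'   number of genes) and `by_day_night` (category x day/night
#'   cross-tabulation on genes with a classifiable sham peak).
#' @export
summarizeCalls <- function(calls) {
  if (!nrow(calls)) stop("calls must be nonempty")
  cats <- c("unaffected", .EFFECTS[-1])
  cats[cats == "rhythm_loss"] <- "rhythm_lost"
  counts <- vapply(cats, function(k) sum(calls$category == k), 0L)
  ct <- table(category = calls$category, day_night = calls$day_night)
  list(counts = counts, by_day_night = ct)
}
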