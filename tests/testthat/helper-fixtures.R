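# Shared fixtures and independent oracles, built in code.

ZT6 <- c(2, 6, 10, 14, 18, 22)

# A tiny deterministic two-condition experiment: `nGenes` cosine genes,
# no noise, `reps` replicates per cell.
noiselessExperiment <- function(nGenes = 3, reps = 2,
                                mesor = 100, amp = 50, phase = 6) {
  tvec <- rep(ZT6, each = reps)
  mk <- function(p) outer(seq_len(nGenes), tvec, function(i, t)
    mesor + amp * cos(2 * pi * (t - p) / 24))
  ab <- cbind(mk(phase), mk(phase))
  rownames(ab) <- paste0("g", seq_len(nGenes))
  cond <- rep(c("sham", "tumor"), each = length(tvec))
  repl <- paste0("r", rep(seq_len(reps), length(ZT6)))
  colnames(ab) <- paste(cond, paste0("ZT", rep(tvec, 2)),
                        rep(repl, 2), sep = "_")
  CircadianExperiment(ab, condition = cond, zt = rep(tvec, 2),
                      replicate = rep(repl, 2))
}

# All permutations of a vector (brute-force oracle helper; n <= 7).
allPerms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in allPerms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

# Kendall concordance sum between two vectors (oracle, O(n^2) direct).
concordanceSum <- function(x, r) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + sign(x[j] - x[i]) * sign(r[j] - r[i])
  s
}

# Brute-force one-lag upper-tail p over all permutations of x.
bruteForceTailP <- function(x, ref) {
  sObs <- concordanceSum(x, ref)
  svals <- vapply(allPerms(x), concordanceSum, 0, r = ref)
  mean(svals >= sObs - 1e-9)
}

# A minimal per-ZT differential table for score/tier unit tests.
makeDiffTable <- function(log2fc, p, gene = "g1", grid = ZT6) {
  d <- S4Vectors::DataFrame(gene_id = gene, zt = grid,
                            mean_sham = 10, mean_tumor = 10,
                            log2fc = log2fc, p_value = p,
                            passed_filter = TRUE,
                            significant = p < 0.05)
  S4Vectors::metadata(d)$zt_grid <- grid
  d
}
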