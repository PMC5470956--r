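test_that("a pure cosine is perfectly concordant with its own lag", {
  # rounded so mathematically tied values (cos at symmetric ZTs) tie
  # exactly in floating point
  r <- jtkTest(round(cos(2 * pi * (ZT6 - 6) / 24), 9), ZT6)
  expect_equal(r$best_lag, 6)
  expect_equal(r$tau, 1)
  # frozen from the brute-force permutation oracle: the most concordant
  # arrangement has null mass 1/180, Bonferroni x 12 lags
  expect_equal(r$p_value, 12 / 180, tolerance = 1e-12)
  expect_false(r$degenerate)
})

test_that("a constant series is degenerate, never an error", {
  r <- jtkTest(rep(5, 12), rep(ZT6, each = 2))
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
  expect_true(is.na(r$tau))
})

test_that("the exact null matches brute-force permutation enumeration", {
  # single-replicate n = 6 series: the DP tail must equal the fraction
  # of all 720 permutations at least as concordant, for every lag
  set.seed(17)
  for (rep in 1:4) {
    x <- round(rnorm(6, 10, 3), 3)
    lagPs <- vapply(seq(0, 22, 2), function(L) {
      ref <- round(cos(2 * pi * (ZT6 - L) / 24), 9)
      bruteForceTailP(x, ref)
    }, 0)
    expected <- min(1, 12 * min(lagPs))
    got <- jtkTest(x, ZT6, exact = TRUE)$p_value
    expect_equal(got, expected, tolerance = 1e-10)
  }
  # frozen tail values from the oracle at the lag-6 reference
  # (groups {1,2,2,1}): P(S >= 13) = 1/180, P(S >= 9) = 11/180
  d <- circaDisrupt:::.jtkNullDistCached(c(1, 2, 2, 1))
  jv <- seq_along(d) - 1
  K <- choose(6, 2) - 2
  expect_equal(sum(d[jv >= (13 + K) / 2]), 1 / 180, tolerance = 1e-12)
  expect_equal(sum(d[jv >= (9 + K) / 2]), 11 / 180, tolerance = 1e-12)
})

test_that("exact and normal-approximation tails agree within 0.02", {
  # single-reference (un-adjusted) upper tails, n between 12 and 30
  set.seed(23)
  for (k in 1:40) {
    reps <- sample(2:5, 1)
    tz <- rep(ZT6, each = reps)
    x <- 10 + runif(1, 0, 12) * cos(2 * pi * (tz - runif(1, 0, 24)) / 24) +
      rnorm(length(tz), 0, 3)
    L <- sample(seq(0, 22, 2), 1)
    pe <- jtkTest(x, tz, lags = L, exact = TRUE)$p_value
    pn <- jtkTest(x, tz, lags = L, exact = FALSE)$p_value
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("tau stays in [-1,1] and p in (0,1] on random series", {
  set.seed(5)
  for (k in 1:30) {
    x <- rlnorm(12, 3, 1)
    r <- jtkTest(x, rep(ZT6, each = 2))
    expect_true(r$tau >= -1 && r$tau <= 1)
    expect_true(r$p_value > 0 && r$p_value <= 1)
  }
})

test_that("detection power is monotone in planted amplitude", {
  # median p over seeds decreases (never increases materially) as the
  # amplitude/noise ratio grows
  amps <- c(0, 2, 5, 10)
  medp <- vapply(amps, function(a) {
    ps <- vapply(1:25, function(s) {
      set.seed(1000 + s)
      tz <- rep(ZT6, each = 2)
      x <- 20 + a * cos(2 * pi * (tz - 8) / 24) * exp(rnorm(12, 0, 0.1)) +
        rnorm(12, 0, 1)
      jtkTest(x, tz)$p_value
    }, 0)
    median(ps)
  }, 0)
  expect_true(all(diff(medp) <= 1e-9))
  expect_lt(medp[4], 0.01)
})

test_that("noiseless rhythmic genes are detected and flat genes are not", {
  mix <- c(none = 0.5, uniform_up = 0, uniform_down = 0,
           phase_advance = 0.5, phase_delay = 0, amplitude_change = 0,
           rhythm_loss = 0, day_night_reversal = 0)
  ce <- simulateExperiment(SimulationConfig(nGenes = 60,
                                            fractionRhythmic = 0.5,
                                            noiseCV = 0, effectMix = mix,
                                            seed = 12))
  tr <- geneTruth(ce)
  res <- detectCyclers(ce, "sham", alpha = 0.05)
  m <- match(tr$gene_id, res$gene_id)
  tested <- !is.na(m)
  expect_true(all(res$rhythmic[m[tested & tr$rhythmic]]))
  expect_true(all(!res$rhythmic[m[tested & !tr$rhythmic]]))
  # alpha = 0 calls nothing rhythmic
  res0 <- detectCyclers(ce, "sham", alpha = 0)
  expect_equal(sum(res0$rhythmic), 0)
})

test_that("detectCyclers reports the expression filter and BH q-values", {
  ce <- simulateExperiment(SimulationConfig(nGenes = 50, seed = 14))
  res <- detectCyclers(ce, "sham")
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
  expect_setequal(c(res$gene_id, S4Vectors::metadata(res)$filtered_out),
                  rownames(ce))
  expect_error(detectCyclers(ce, "nope"), "not present")
})

test_that("the reliable set is intersection plus validated additions", {
  r <- buildReliableSet(c("a", "b", "c"), c("b", "c", "d"), "a")
  expect_setequal(r$gene_id, c("a", "b", "c"))
  expect_equal(r$provenance[r$gene_id == "a"], "manual_addition")
  expect_equal(r$provenance[r$gene_id == "b"], "both")

  r2 <- buildReliableSet("x", "x")
  expect_equal(as.data.frame(r2),
               data.frame(gene_id = "x", provenance = "both"))

  expect_error(buildReliableSet(c("a"), c("b"), "zzz"),
               "validation error")
})

test_that("the reliable set is invariant to input ordering and scales", {
  set.seed(2)
  ours <- sprintf("g%03d", sample(400, 340))
  ref <- sprintf("g%03d", sample(400, 340))
  manual <- sample(setdiff(union(ours, ref), intersect(ours, ref)), 3)
  a <- buildReliableSet(ours, ref, manual)
  b <- buildReliableSet(sample(ours), sample(ref), sample(manual))
  expect_identical(as.data.frame(a), as.data.frame(b))
  # intersection of 329 with 3 additions gives a 332-gene set
  ours2 <- sprintf("r%03d", 1:335)
  ref2 <- sprintf("r%03d", 7:400)   # overlap 329
  man2 <- c("r001", "r002", "r003")
  r3 <- buildReliableSet(ours2, ref2, man2)
  expect_equal(nrow(r3), 332)
  expect_equal(sum(r3$provenance == "manual_addition"), 3)
})
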