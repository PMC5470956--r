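onlyEffect <- function(which) {
  mix <- c(none = 0, uniform_up = 0, uniform_down = 0, phase_advance = 0,
           phase_delay = 0, amplitude_change = 0, rhythm_loss = 0,
           day_night_reversal = 0)
  mix[which] <- 1
  mix
}

test_that("noiseless cosine genes hit their peak and trough exactly", {
  cfg <- SimulationConfig(nGenes = 5, fractionRhythmic = 1, noiseCV = 0,
                          effectMix = onlyEffect("none"), seed = 2)
  ce <- simulateExperiment(cfg)
  tr <- geneTruth(ce)
  ab <- abundance(ce)
  for (i in seq_len(nrow(tr))) {
    # value at any sampled ZT equals the generative cosine mean
    for (z in c(2, 6, 18)) {
      expected <- tr$mesor[i] +
        tr$amplitude[i] * cos(2 * pi * (z - tr$acrophase[i]) / 24)
      got <- ab[i, condition(ce) == "sham" & zt(ce) == z]
      expect_equal(unname(got), rep(expected, 2), tolerance = 1e-12)
    }
  }
  # a gene with b=100, A=50, p=6 peaks at 150 and troughs at 50
  tvec <- rep(c(2, 6, 10, 14, 18, 22), each = 2)
  m <- 100 + 50 * cos(2 * pi * (tvec - 6) / 24)
  expect_equal(m[tvec == 6], c(150, 150))
  expect_equal(m[tvec == 18], c(50, 50))
})

test_that("day-night reversal plants an exactly antiphase tumor acrophase", {
  cfg <- SimulationConfig(nGenes = 4, fractionRhythmic = 1, noiseCV = 0,
                          effectMix = onlyEffect("day_night_reversal"),
                          seed = 3)
  ce <- simulateExperiment(cfg)
  tr <- geneTruth(ce)
  fits <- cosinorByGene(ce, "tumor")
  expect_equal(fits$acrophase_p, (tr$acrophase + 12) %% 24,
               tolerance = 1e-8)
  # e.g. sham acrophase 14 maps to tumor acrophase 2
  expect_equal((14 + 12) %% 24, 2)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- SimulationConfig(nGenes = 200, fractionRhythmic = 0.3, seed = 1)
  a <- simulateExperiment(cfg)
  b <- simulateExperiment(cfg)
  expect_identical(abundance(a), abundance(b))
  expect_identical(as.data.frame(geneTruth(a)),
                   as.data.frame(geneTruth(b)))
  # and a different seed changes the draw
  c2 <- simulateExperiment(SimulationConfig(nGenes = 200,
                                            fractionRhythmic = 0.3,
                                            seed = 2))
  expect_false(identical(abundance(a), abundance(c2)))
})

test_that("all simulated abundances are strictly positive", {
  ce <- simulateExperiment(SimulationConfig(nGenes = 300, noiseCV = 0.4,
                                            seed = 9))
  expect_true(all(abundance(ce) > 0))
})

test_that("effect categories are allocated exactly by largest remainder", {
  mix <- c(none = 0.35, uniform_up = 0.15, uniform_down = 0.1,
           phase_advance = 0.1, phase_delay = 0.1,
           amplitude_change = 0.08, rhythm_loss = 0.07,
           day_night_reversal = 0.05)
  ce <- simulateExperiment(SimulationConfig(nGenes = 97, effectMix = mix,
                                            seed = 4))
  got <- table(geneTruth(ce)$effect)
  # independent largest-remainder oracle
  raw <- 97 * mix
  base <- floor(raw)
  rem <- order(raw - base, decreasing = TRUE)
  base[rem[seq_len(97 - sum(base))]] <- base[rem[seq_len(97 - sum(base))]] + 1
  expect_equal(sum(base), 97)
  for (k in names(mix)) expect_equal(unname(got[k]), unname(base[k]))
})

test_that("lognormal noise is mean-preserving at the stated accuracy", {
  # law of large numbers: 10,000 replicates at noise_cv = 0.2 recover
  # the generative cell mean within 2% relative error
  cfg <- SimulationConfig(nGenes = 1, fractionRhythmic = 1, noiseCV = 0.2,
                          replicates = 10000L,
                          effectMix = onlyEffect("none"), seed = 8)
  ce <- simulateExperiment(cfg)
  tr <- geneTruth(ce)
  for (z in c(2, 14)) {
    vals <- abundance(ce)[1, condition(ce) == "sham" & zt(ce) == z]
    mu <- tr$mesor[1] + tr$amplitude[1] * cos(2 * pi * (z - tr$acrophase[1]) / 24)
    expect_lt(abs(mean(vals) - mu) / mu, 0.02)
    # and the coefficient of variation matches noiseCV
    expect_equal(stats::sd(vals) / mean(vals), 0.2, tolerance = 0.05)
  }
})

test_that("rhythm loss conserves abundance at the sham time-average", {
  cfg <- SimulationConfig(nGenes = 3, fractionRhythmic = 1, noiseCV = 0,
                          effectMix = onlyEffect("rhythm_loss"), seed = 5)
  ce <- simulateExperiment(cfg)
  tr <- geneTruth(ce)
  tumorVals <- abundance(ce)[, condition(ce) == "tumor", drop = FALSE]
  # flat in tumor, at the mean of the sham grid profile
  for (i in 1:3) {
    shamMean <- mean(abundance(ce)[i, condition(ce) == "sham"])
    expect_equal(unname(tumorVals[i, ]),
                 rep(shamMean, ncol(tumorVals)), tolerance = 1e-9)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(SimulationConfig(noiseCV = -0.1), "noiseCV")
  expect_error(SimulationConfig(ztGrid = c(2, 6, 10)),
               "under-determined")
  expect_error(SimulationConfig(ztGrid = c(2, 6, 6, 10)),
               "strictly increasing")
  badMix <- c(none = 0.5, uniform_up = 0.6, uniform_down = 0,
              phase_advance = 0, phase_delay = 0, amplitude_change = 0,
              rhythm_loss = 0, day_night_reversal = 0)
  expect_error(SimulationConfig(effectMix = badMix), "sum to 1")
})

test_that("truth invariants: flat genes have zero amplitude, amplitude below mesor, acrophase in [0,24)", {
  ce <- simulateExperiment(SimulationConfig(nGenes = 400, seed = 10))
  tr <- geneTruth(ce)
  expect_true(all(tr$amplitude[!tr$rhythmic] == 0))
  expect_true(all(tr$amplitude < tr$mesor))
  expect_true(all(tr$acrophase >= 0 & tr$acrophase < 24))
})
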