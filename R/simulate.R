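#' Configuration for the synthetic circadian experiment generator
#'
#' Captures the study design emulated by [simulateExperiment()]: a
#' two-condition (sham vs tumor) time course sampled at six zeitgeber
#' times over one day, a mixture of 24-h rhythmic and flat genes, and a
#' planted per-gene tumor effect drawn from the disruption phenotypes the
#' pipeline is built to recover.
#'
#' @param nGenes number of genes to simulate.
#' @param fractionRhythmic target fraction of rhythmic genes in \[0, 1\].
#'   Genes carrying phase, amplitude, rhythm-loss or reversal effects are
#'   rhythmic by necessity; if they already exceed the target the fraction
#'   is clamped upward and the remaining genes are flat.
#' @param ztGrid strictly increasing sampling times in hours, all in
#'   \[0, 24); at least 4 points are required so the cosinor stage is
#'   over-determined. Default `c(2, 6, 10, 14, 18, 22)`.
#' @param replicates replicates per condition x ZT cell. Default 2
#'   (sequencing-like design; use 6--9 for qPCR-like designs).
#' @param noiseCV coefficient of variation of the multiplicative
#'   (mean-preserving lognormal) noise; must be > 0 unless exactly 0 for
#'   noiseless checks. Default 0.2.
#' @param effectMix named proportions over the effect categories
#'   `r paste(.EFFECTS, collapse=", ")`; must sum to 1 (tolerance 1e-9).
#'   Gene counts per category are allocated deterministically by the
#'   largest-remainder rule.
#' @param effectSizes named list of planted effect magnitudes:
#'   `uniform` (log2 units, default 1), `phase` (hours, default 3),
#'   `amplitude` (multiplicative factor, default 0.5). Day-night reversal
#'   is always exactly 12 h and rhythm loss always zeroes the amplitude.
#' @param seed integer seed making the simulation fully reproducible.
#'
#' @return a `SimulationConfig` S4 object.
#' @export
SimulationConfig <- function(nGenes = 1000L,
                             fractionRhythmic = 0.3,
                             ztGrid = c(2, 6, 10, 14, 18, 22),
                             replicates = 2L,
                             noiseCV = 0.2,
                             effectMix = c(none = 0.3, uniform_up = 0.1,
                                           uniform_down = 0.1,
                                           phase_advance = 0.1,
                                           phase_delay = 0.1,
                                           amplitude_change = 0.1,
                                           rhythm_loss = 0.1,
                                           day_night_reversal = 0.1),
                             effectSizes = list(uniform = 1, phase = 3,
                                                amplitude = 0.5),
                             seed = 1L) {
  methods::new("SimulationConfig",
               nGenes = as.integer(nGenes),
               fractionRhythmic = fractionRhythmic,
               ztGrid = as.numeric(ztGrid),
               replicates = as.integer(replicates),
               noiseCV = noiseCV,
               effectMix = effectMix,
               effectSizes = effectSizes,
               seed = as.integer(seed))
}

#' @rdname SimulationConfig
#' @export
setClass("SimulationConfig",
         representation(nGenes = "integer", fractionRhythmic = "numeric",
                        ztGrid = "numeric", replicates = "integer",
                        noiseCV = "numeric", effectMix = "numeric",
                        effectSizes = "list", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (object@fractionRhythmic < 0 || object@fractionRhythmic > 1)
    msg <- c(msg, "fractionRhythmic must lie in [0, 1]")
  g <- object@ztGrid
  if (length(g) < 4L)
    msg <- c(msg, "under-determined design: ztGrid needs at least 4 points")
  if (any(diff(g) <= 0) || any(g < 0 | g >= 24))
    msg <- c(msg, "ztGrid must be strictly increasing within [0, 24)")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be positive")
  if (object@noiseCV < 0)
    msg <- c(msg, "invalid config: noiseCV must be nonnegative")
  mix <- object@effectMix
  if (!setequal(names(mix), .EFFECTS))
    msg <- c(msg, sprintf("effectMix must name exactly: %s",
                          paste(.EFFECTS, collapse = ", ")))
  else if (abs(sum(mix) - 1) > 1e-9 || any(mix < 0))
    msg <- c(msg, "effectMix proportions must be nonnegative and sum to 1")
  if (!all(c("uniform", "phase", "amplitude") %in% names(object@effectSizes)))
    msg <- c(msg, "effectSizes must name uniform, phase and amplitude")
  if (length(msg)) msg else TRUE
})

# Largest-remainder apportionment of n items over proportions p.
.largestRemainder <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# Cosine mean profile of the generative model.
.cosineMean <- function(t, mesor, amplitude, acrophase, period = 24) {
  mesor + amplitude * cos(2 * pi * (t - acrophase) / period)
}

# Draw per-gene generative parameters and planted effects (deterministic
# category allocation, seeded parameter draws).
.drawTruth <- function(config) {
  n <- config@nGenes
  mix <- config@effectMix[.EFFECTS]
  counts <- .largestRemainder(n, mix)
  effect <- rep(.EFFECTS, counts)
  # effects that only exist on a rhythmic background
  needRhythm <- effect %in% c("phase_advance", "phase_delay",
                              "amplitude_change", "rhythm_loss",
                              "day_night_reversal")
  nTarget <- round(config@fractionRhythmic * n)
  rhythmic <- needRhythm
  free <- which(!needRhythm)
  extra <- max(0L, nTarget - sum(needRhythm))
  if (extra > 0L && length(free))
    rhythmic[free[seq_len(min(extra, length(free)))]] <- TRUE

  mesor <- stats::rlnorm(n, meanlog = log(50), sdlog = 0.6)
  relAmp <- stats::runif(n, 0.3, 0.7)
  amplitude <- ifelse(rhythmic, relAmp * mesor, 0)
  acrophase <- ifelse(rhythmic, stats::runif(n, 0, 24), NA_real_)
  acrophase[!rhythmic] <- 0

  es <- config@effectSizes
  effectSize <- numeric(n)
  effectSize[effect %in% c("uniform_up", "uniform_down")] <- es$uniform
  effectSize[effect %in% c("phase_advance", "phase_delay")] <- es$phase
  effectSize[effect == "amplitude_change"] <- es$amplitude
  effectSize[effect == "day_night_reversal"] <- 12

  DataFrame(gene_id = sprintf("gene%04d", seq_len(n)),
            mesor = mesor, amplitude = amplitude, acrophase = acrophase,
            rhythmic = rhythmic, effect = effect, effect_size = effectSize)
}

# Tumor-condition generative parameters implied by a planted effect.
.applyEffect <- function(truth, ztGrid) {
  b <- truth$mesor; A <- truth$amplitude; p <- truth$acrophase
  s <- truth$effect_size
  up <- truth$effect == "uniform_up"
  dn <- truth$effect == "uniform_down"
  b[up] <- b[up] * 2^s[up]
  b[dn] <- b[dn] * 2^(-s[dn])
  adv <- truth$effect == "phase_advance"
  del <- truth$effect == "phase_delay"
  p[adv] <- (p[adv] - s[adv]) %% 24
  p[del] <- (p[del] + s[del]) %% 24
  amp <- truth$effect == "amplitude_change"
  A[amp] <- A[amp] * s[amp]
  rev <- truth$effect == "day_night_reversal"
  p[rev] <- (p[rev] + 12) %% 24
  loss <- truth$effect == "rhythm_loss"
  if (any(loss)) {
    # sham time-average on the sampling grid, conserving total abundance
    avg <- vapply(which(loss), function(i) {
      mean(.cosineMean(ztGrid, truth$mesor[i], truth$amplitude[i],
                       truth$acrophase[i]))
    }, 0)
    b[loss] <- avg
    A[loss] <- 0
  }
  list(mesor = b, amplitude = A, acrophase = p)
}

#' Simulate a two-condition circadian expression experiment
#'
#' Generates a sham/tumor gene x sample abundance matrix from the
#' fixed-period generative model
#' \eqn{y(t) = b + A \cos\{2\pi(t - p)/24\}} with gene-specific mesor
#' \eqn{b}, amplitude \eqn{A} and acrophase \eqn{p}, planted tumor
#' effects, and mean-preserving lognormal multiplicative noise: each
#' abundance is \eqn{\mu(t)\,e^{\varepsilon}} with
#' \eqn{\varepsilon \sim N(-\sigma^2/2, \sigma^2)} and
#' \eqn{\sigma^2 = \log(1 + \mathrm{CV}^2)}, so the expected value equals
#' the generative mean and the coefficient of variation equals `noiseCV`.
#'
#' Planted tumor effects: `uniform_up`/`uniform_down` scale the mesor by
#' \eqn{2^{\pm s}}; `phase_advance`/`phase_delay` shift the acrophase by
#' \eqn{\mp s} hours (mod 24); `amplitude_change` multiplies the
#' amplitude by a factor; `rhythm_loss` zeroes the amplitude and sets the
#' tumor mesor to the sham time-average on the grid; `day_night_reversal`
#' shifts the acrophase by exactly 12 h.
#'
#' @param config a [SimulationConfig()].
#' @return a [CircadianExperiment-class] whose `rowData` holds the planted
#'   ground truth (one row per gene: mesor, amplitude, acrophase, rhythmic
#'   flag, effect category, effect size); retrieve it with [geneTruth()].
#' @examples
#' ce <- simulateExperiment(SimulationConfig(nGenes = 50, seed = 7))
#' table(geneTruth(ce)$effect)
#' @export
simulateExperiment <- function(config) {
  methods::validObject(config)
  if (config@noiseCV < 0) stop("invalid config: noiseCV must be nonnegative")
  withSeed(config@seed, {
    truth <- .drawTruth(config)
    tum <- .applyEffect(truth, config@ztGrid)
    nz <- length(config@ztGrid)
    reps <- config@replicates
    tvec <- rep(config@ztGrid, each = reps)
    sigma2 <- log(1 + config@noiseCV^2)

    mk <- function(b, A, p) {
      mu <- outer(seq_along(b), seq_along(tvec),
                  function(i, j) .cosineMean(tvec[j], b[i], A[i], p[i]))
      if (sigma2 > 0) {
        eps <- matrix(stats::rnorm(length(mu), -sigma2 / 2, sqrt(sigma2)),
                      nrow = nrow(mu))
        mu <- mu * exp(eps)
      }
      mu
    }
    shamM <- mk(truth$mesor, truth$amplitude, truth$acrophase)
    tumM <- mk(tum$mesor, tum$amplitude, tum$acrophase)

    ab <- cbind(shamM, tumM)
    rownames(ab) <- truth$gene_id
    cond <- rep(c("sham", "tumor"), each = nz * reps)
    ztv <- rep(tvec, 2)
    repl <- rep(paste0("r", rep(seq_len(reps), times = nz)), 2)
    colnames(ab) <- paste(cond, paste0("ZT", ztv), repl, sep = "_")
    CircadianExperiment(ab, condition = cond, zt = ztv, replicate = repl,
                        rowData = truth)
  })
}

#' Evaluate code with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package operations do not perturb user
#' randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
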