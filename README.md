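# circaDisrupt

Profiling how a systemic perturbation rewires a circadian transcriptome,
from a two-condition zeitgeber-time course.

## What problem this solves

Peripheral organs run daily gene-expression programs. A systemic insult
— the motivating case is a transplanted mammary tumor acting remotely on
the liver — can disturb that program in qualitatively different ways:
a gene may be uniformly up- or down-regulated all day, its peak may move
earlier or later, its oscillation may dampen, vanish, or even flip to
the opposite half of the day ("day–night reversal"). Given a gene ×
sample abundance matrix (FPKM-like scale) with a sample sheet
(condition ∈ {sham, tumor}, zeitgeber time ZT ∈ {2, 6, 10, 14, 18, 22},
replicate), `circaDisrupt` produces one audited disruption call per gene
and every intermediate table a reviewer would want.

The package is aimed at chronobiologists and computational biologists
analysing two-condition circadian time courses (bulk RNA-seq or
qPCR-style panels), and ships a seeded synthetic-data generator with
planted per-gene ground truth so the whole pipeline is testable end to
end.

## The methods at its core

- **Rhythm detection** — a JTK-style test: Kendall's tau-b between the
  observed series and fixed-period cosine references
  cos{2π(t − lag)/24} scanned over peak lags every 2 h; the one-sided
  tail of the concordance count is computed **exactly** (dynamic
  programming over the permutation null, ties handled via the
  Jonckheere–Terpstra interleaving distribution) for up to 30
  observations, Bonferroni-adjusted over lags, then
  Benjamini–Hochberg across genes.
- **Cosinor regression** — least squares for
  y(t) = b + A·cos{2π(t − p)/24} at fixed 24-h period via the exact
  linear reparameterisation (no iterative optimisation), giving mesor
  b, amplitude A and acrophase p; phase differences are wrapped
  circularly, Δ = p_S − p_T ∈ (−12, 12], with Δ > 0 meaning the tumor
  peak comes earlier.
- **Per-ZT differential ranking** — log2(mean_tumor/mean_sham) on genes
  passing the expression filter (both means > 0 and at least one ≥ 1),
  Welch tests on log2(abundance + 0.5), and the fold-change criteria:
  average |log2 FC| > 0.585 (more than 1.5-fold on average) and the
  single-ZT peak criterion (|log2 FC| > 0.585 with p < 0.05).
- **Disruption taxonomy** — an ordered decision tree combining all of
  the above into one of: unaffected, uniform_up/down,
  phase_advance/delay, amplitude_change, rhythm_lost,
  day_night_reversal (thresholds: 2 h, 9 h, 1.5×; all configurable).

See the methods vignette
(`vignettes/circadian-disruption-profiling.Rmd`) for the models,
assumptions, parameter defaults and known limitations.

## A worked example

```r
library(circaDisrupt)

# 400 genes, 3 replicates per condition x ZT, planted effect mixture
ce <- simulateExperiment(SimulationConfig(nGenes = 400, seed = 7,
                                          replicates = 3L))
ce
#> CircadianExperiment: 400 genes x 36 samples
#>   sham   18 samples, ZT {2,6,10,14,18,22}, 3 replicates/cell
#>   tumor  18 samples, ZT {2,6,10,14,18,22}, 3 replicates/cell
#>   planted ground truth in rowData (see geneTruth())

# run the full pipeline from TSV inputs
d <- tempfile(); dir.create(d)
writeExpressionMatrix(ce, file.path(d, "matrix.tsv"),
                      file.path(d, "sheet.tsv"))
tr <- geneTruth(ce)
writeGeneList(tr$gene_id[tr$rhythmic], file.path(d, "reference.txt"))
res <- runPipeline(pipelineConfig(file.path(d, "matrix.tsv"),
                                  file.path(d, "sheet.tsv"),
                                  file.path(d, "reference.txt"),
                                  file.path(d, "out")))
res$summary$counts
#>         unaffected         uniform_up       uniform_down      phase_advance
#>                141                 38                 38                 37
#>        phase_delay   amplitude_change        rhythm_lost day_night_reversal
#>                 36                 12                 60                 38
```

The counts reconcile with the 400 planted genes (120 none + 40 per
effect): uniform and phase effects are recovered nearly gene for gene;
at this small design (3 replicates, noise CV 0.2) about two-thirds of
the halved-amplitude genes lose their tumor rhythm call entirely and
are reported as `rhythm_lost` — the evidence column of
`disruption_calls.tsv` records why. One planted reversal gene looks
like this:

```r
as.data.frame(res$calls[res$calls$gene_id == "gene0361", ])
#>    gene_id           category delta_hours n_significant_zts rhythmic_sham
#> 1 gene0361 day_night_reversal     11.9181                 5          TRUE
#>   rhythmic_tumor day_night                                evidence
#> 1           TRUE  day_time nsig=5; delta=11.92; rhythmic=TRUE/TRUE
```

Lower-level entry points do one thing each: `jtkTest()`,
`detectCyclers()`, `buildReliableSet()`, `differentialByZT()`,
`scoreGenes()`, `tierGenes()`, `fitCosinor()`, `acrophaseDiff()`,
`classifyDayNight()`, `callDisruptions()`, `exportDoublePlot()`. A thin
command-line wrapper over `simulateExperiment()` and `runPipeline()` is
in `inst/scripts/circa-disrupt.R`.

```r
fitCosinor(c(2, 6, 10, 14, 18, 22),
           10 + 3 * cos(2 * pi * (c(2, 6, 10, 14, 18, 22) - 8) / 24))
#> mesor_b 10, amplitude_A 3, acrophase_p 8  (exact recovery)
```

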