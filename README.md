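# iridyn — intron retention dynamics from read coverage

Intron retention (IR) — an intron surviving into the mature transcript —
is pervasive in senescing and aging cells, and retained transcripts tend
to be degraded faster than spliced ones, so rising retention can quietly
dial a gene's steady-state expression down. `iridyn` is an R package for
quantifying and classifying that process from bulk RNA-seq coverage, for
anyone studying splicing dynamics across a time course (e.g. a
replicative-senescence series) or between two conditions (e.g. a
splicing-factor knockdown vs control).

The core statistic is the **intron retention index**,

```
IRI = mean read depth over the intron
      ------------------------------------------------
      pooled mean depth over the flanking exon segments
```

computed only on regions shared by *every* annotated isoform of a gene,
with a coverage-completeness filter (≥ 50% of intron bases covered), a
range filter (introns with IRI > 1 anywhere are discarded), and a
retention cutoff of 0.1. Per-intron trajectories `X = (X1…Xn)` over an
ordered design are labelled by sequential rules — `no_IR` if
`max(X) < 0.1`, `stable_IR` if `max(X) − min(X) < 0.1`, `up_IR`/`down_IR`
if the Pearson correlation with the monotone reference
`L = (0, …, 1)` exceeds ±0.7, otherwise `discarded`; two-condition
designs use `ΔIRI` with a pooled t-test instead. Downstream modules
relate retention changes to expression fold changes (per-class contrasts
and an 8-bin trend), compare sequence features between classes, and
screen RNA-binding proteins and candidate target introns by binding
density and expression criteria. A synthetic-data module generates gene
models, genome sequence, per-base Poisson coverage, and binding sites
from a degradation-coupled generative model (decay factor γ), so every
stage is testable against known ground truth.

## Worked example

Simulate a small 5-time-point × 3-replicate series (40 genes, γ = 5) and
run the full pipeline:

```r
library(iridyn)
cfg <- sim_config(n_genes = 40)
sim <- simulate_dataset(cfg, seed = 7)
res <- run_pipeline(models = sim$genome$models, tracks = sim$tracks,
                    design = sim$design, sites = sim$sites)
res
#> pipeline_result (timeseries)
#>   introns annotated: 112
#>   filter: kept=112, dropped_iri_gt1=0, dropped_missing=0
#>   labels: no_IR=53, stable_IR=17, up_IR=7, down_IR=17, discarded=18
#>   8-bin trend rho: -0.548
```

All 112 shared introns were quantifiable in every sample; the classifier
partitions them into the five labels, and the negative 8-bin trend says
genes whose retention rose tended to drop in expression — the
degradation coupling built into the simulation. One of the `up_IR`
introns (`G021:I1`) shows the kind of trajectory rule 3 accepts:

```r
round(unlist(subset(as.data.frame(res$classification),
                    label == "up_IR")[1, paste0("X", 1:5)]), 3)
#>    X1    X2    X3    X4    X5
#> 0.053 0.092 0.143 0.214 0.313
```

Its IRI rises monotonically from 5% to 31% (correlation with the
monotone reference ≈ 1), and its range 0.26 clears the 0.1 change
cutoff.

Real data enter the same way: `parse_annotation()` reads GTF or refFlat,
`read_bedgraph_track()` reads per-sample bedGraph coverage,
`load_binding_sites()` reads BED, and `run_pipeline(bundle_dir = ...)`
consumes a directory holding all of them (see
`write_fixture_bundle()` for the expected layout).

## Analysis workflow

The `analysis/` scripts run the study end to end on the default
synthetic dataset and write small tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # dataset + ground truth (bundle in scratch/)
Rscript analysis/02_quantify.R     # IRI matrix, filters, calibration
Rscript analysis/03_classify.R     # labels + confusion vs ground truth
Rscript analysis/04_associate.R    # expression contrasts, 8-bin trend, features
Rscript analysis/05_screen_rbp.R   # RBP screen + target-intron screen
```

The methods vignette
(`vignettes/intron-retention-dynamics.Rmd`) documents the model, every
threshold, the generative defaults and their rationale, and known
limitations.

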