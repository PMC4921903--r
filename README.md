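# tfactivity

Transcription-factor (TF) activity inference and two-condition coherence
analysis for short time-course transcriptomics.

## What problem this solves

When a bacterial culture is perturbed — for example by dissolved CO gas —
and profiled over minutes (a grid such as 0, 2.5, 5, 10, 20, 40, 80 min),
hundreds of genes change at once. Most of that regulation is channelled
through a few dozen transcription factors whose DNA-binding *activity* is
not directly measurable. `tfactivity` infers those latent activity
profiles by combining the expression matrix with regulon annotation
(TF → target edges with optional activation/repression signs, as exported
from RegulonDB or EcoCyc), and then compares each TF's response across two
conditions with a coherence statistic. It is aimed at microbial systems
biologists analysing chemostat or batch time courses.

The model is a linear-Gaussian latent-variable model: for gene *g* and
timepoint *t*,

```
y_gt = mu_g + sum_m X_gm * b_gm * c_mt + e_gt,    e_gt ~ N(0, sigma^2)
```

where `y` is the log2 ratio to the pre-treatment sample, `X` the binary
regulon connectivity, `b` sign-constrained regulatory weights and `c` the
latent TF activities, given a Gaussian random-walk prior over the irregular
sampling grid. Inference is by Gibbs sampling (forward-filter
backward-sampling for each activity profile; compiled inner loop) with
full posterior uncertainty and split-chain convergence diagnostics.

Two conditions are compared per TF by the coherence statistic:

* profile difference `d = 1 - |Pearson r|` of the two activity profiles
  (kinetics), and
* magnitude difference `m = | ||a|| - ||b|| |` of their Euclidean norms
  (amplitude),

with 95% credible intervals from paired posterior draws, the conventional
rule that TFs whose `|r|` interval half-width exceeds ±0.15 are flagged as
omitted, and quadrant labels (near-origin = similar in both respects,
upper-left = same shape at different amplitude, right half = changed
kinetics).

The package also provides the standard fold-change bookkeeping (two-fold
up / half down calls with inclusive boundaries, fraction-of-genome-changed,
per-functional-category percentages, per-gene time strips), small
closed-form phenotype computations (percentage growth inhibition,
siderophore halo statistic, phosphorylated-regulator fraction), a
synthetic-data generator with known ground truth, and a YAML-driven
`run_pipeline()` that orchestrates everything reproducibly.

## Worked example

Simulate the designed three-TF benchmark — one TF responds identically in
both conditions, one keeps its shape at 3× amplitude, one changes kinetics
— fit each condition, and compare:

```r
library(tfactivity)

scen <- quadrant_scenario_config(seed = 42)
sim  <- simulate_tfa_data(scen)          # network, truth, exprA, exprB

fitA <- tfa(sim$expr$A, sim$network, seed = 42)
fitB <- tfa(sim$expr$B, sim$network, seed = 43)
fitA
#> TF activity model fit (A)
#> 35 genes, 3 TFs, 7 timepoints; 4000 posterior draws in 2 chain(s)
#> Posterior-mean noise sd: 0.294

activity_profile(fitA, "tf01")
#>   minute   mean   lo95 hi95
#> 1    0.0 0.0055 -0.499 0.50
#> 2    2.5 0.4906 -0.046 1.03
#> 3    5.0 1.1483  0.626 1.69
#> 4   10.0 2.1344  1.612 2.66
#> 5   20.0 1.1307  0.617 1.66
#> 6   40.0 0.2674 -0.256 0.80
#> 7   80.0 0.1570 -0.376 0.68

coherence_table(fitA, fitB, m_threshold = 1.0, seed = 42)
#>     tf profile_difference magnitude_difference omitted    quadrant
#> 1 tf01             0.0077                0.079   FALSE  lower-left
#> 2 tf02             0.0152                2.265   FALSE  upper-left
#> 3 tf03             0.6253                0.551   FALSE lower-right
```

Reading the output: the estimated noise sd (0.294) recovers the generating
value 0.3; `tf01`'s posterior-mean activity traces the true transient pulse
(peak at 10 min, amplitude ≈ 2) with 95% bands; and the coherence table
recovers the designed structure — `tf01` near the origin (identical
response), `tf02` upper-left (same kinetics, `d ≈ 0`, but a large norm gap
from the 3× amplitude), `tf03` in the right half (`d = 0.63`, changed
kinetics, matched amplitude). `plot(fitA)` draws the activity profiles with
credible bands and `plot_coherence(tab)` the labelled scatter.

Real data enter the same way through `read_expression_table()` (TSV, gene
ids then minute-labelled columns of log2 ratios) and
`read_regulon_table()` (TSV: `tf`, `gene`, optional `sign`), and the whole
analysis can be driven from a YAML config with `run_pipeline()`.

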