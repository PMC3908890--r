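# nfapin

Noise-filtered active protein interaction networks (NF-APIN) from
time-course gene expression, with protein-complex detection.

Static protein interaction networks (PINs) pool interactions observed
across many conditions, so clustering them mixes complexes that never
coexist in the cell. `nfapin` builds a *dynamic* network instead: one
subnetwork per time point of a time-course expression experiment,
keeping an interaction only when both proteins are *active* at that
time. Before that, it removes the noisy genes that contaminate
expression arrays. The package is aimed at systems-biology analyses of
cyclic time courses (e.g. the yeast metabolic cycle: 3 successive
cycles of 12 time points) combined with a PPI download (DIP-style edge
list) and a benchmark complex catalogue (CYC2008-style).

## Method

**1. Time-dependence screen.** Each profile `x_1..x_M` is fitted by an
AR(p) model

    x_m = b0 + b1 x_{m-1} + ... + bp x_{m-p} + e_m,   m = p+1..M

and by the nested constant model `x_m = b0 + e_m` on the same window.
With ML residual variances s² (AR) and s²_c (constant), the
likelihood-ratio statistic

    F = ((M - 2p - 1) / p) (s²_c / s² - 1)

is referred to `F(p, M - 2p - 1)`; orders `p = 1..6` are tried and a
gene is called **time-dependent** when any order's p-value falls below
0.01.

**2. Noise filter.** A gene is noise when it is time-independent *and*
its mean over all `M` points is small (default: below 0.5, the value
the top-15%-of-lowest-means rule yields on the yeast data). Noisy genes
are removed.

**3. Activity calling.** Cycles are averaged pointwise to one
`T`-point profile per gene; with mean `u` and standard deviation
`sigma`, each gene's activity threshold is

    Active_threshold = u + k sigma (1 - F),   F = 1 / (1 + sigma²)

with `k = 2.5` by default (`k = 3` recovers the classical three-sigma
rule; a global fixed threshold of 0.7 reproduces the
common-threshold construction). A protein is active at `t` when its
value strictly exceeds its threshold.

**4. Dynamic network.** For each time point, the subnetwork keeps the
static interactions whose two proteins are co-active (isolated nodes
dropped).

**5. Complexes.** Each subnetwork is clustered with Markov clustering
(expansion/inflation flow simulation); per-time clusters are pooled and
merged across time at overlap score `OS >= 0.8`; predictions are scored
against the benchmark with `OS(A,B) = |A∩B|²/(|A||B|)` at the
conventional `OS >= 0.2`, reporting Sn, Sp and f-measure (complex-wise
Brohée convention or plain matched fractions).

## Worked example

Everything below is synthetic and seeded, so it reproduces exactly. The
generator plants 10 protein complexes (dense subgraphs whose member
genes share an activation window) in a 300-gene expression matrix plus
a background PIN, then the pipeline is asked to find them:

```r
library(nfapin)
spec  <- synth_spec(seed = 2026)
bench <- gen_benchmark(spec)
cfg   <- pipeline_config(expression = bench$expression, pin = bench$pin,
                         benchmark = bench$complexes,
                         metric_mode = "match_fraction")
run   <- run_pipeline(cfg, quiet = TRUE)
print(run)
#> nfapin pipeline run
#>   genes screened: 300 (22.0% time-dependent), kept after noise filter: 264
#>   active (gene, time) pairs: 328
#>   subnetworks: 12 (mean 15.2 nodes, 37.2 edges)
#>   predicted complexes after merge: 11
#> complex prediction report (match_fraction, OS >= 0.2)
#>   predicted: 11   known: 10   matched known: 10 (exact: 9)
#>   Sn = 1.000   Sp = 0.909   f-measure = 0.952
```

Reading: 22% of profiles screened time-dependent; 36 of the remaining
time-independent genes had means below 0.5 and were dropped as noise;
thresholding at `k = 2.5` left 328 active (gene, time) pairs, giving 12
sparse subnetworks; MCL plus cross-time merging predicted 11 complexes,
matching all 10 planted ones (9 exactly), for an f-measure of 0.95.

The same pipeline runs on real data from files:

```sh
exec/nfapin run --expression expr.tsv --pin dip_edges.tsv \
    --benchmark cyc2008.tsv --out results/
exec/nfapin sweep --expression expr.tsv --pin dip_edges.tsv \
    --benchmark cyc2008.tsv --k-from 0 --k-to 3 --k-by 0.1
```

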