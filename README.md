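# chronoprio

Multi-omics prioritization of circadian rhythm (CR) related genes in
cancer.

Disrupted circadian rhythms are an emerging factor in tumorigenesis, but
evidence for any individual clock gene is scattered across heterogeneous
data types: pan-cancer alteration catalogues, protein–protein
interactomes, prognostic survival scans, and causal networks linking
proteins to cancer hallmark phenotypes. `chronoprio` is an R package for
systems-biology researchers who want to combine those four evidence
layers into a single, reproducible per-gene prioritization — and to test
every stage of that pipeline against synthetic data with known planted
structure.

## The CR-cancer score

Each gene is scored in four layers:

| layer      | per-gene value                                   | better |
|------------|--------------------------------------------------|--------|
| alteration | mean alteration frequency *f* (events / cohort size, averaged over cohorts) | higher |
| network    | degree centrality in the confidence-filtered (> 0.9) CR–driver interactome | higher |
| prognosis  | minimum log-rank p among unfavorable maximally separated Kaplan–Meier splits | lower |
| hallmark   | minimum directed shortest-path distance to any of nine cancer hallmark phenotypes | lower |

Within a layer, values are rank-normalized: with N ranked genes and
average-rank ties, score = (N − rank)/(N − 1) ∈ [0, 1]. Layer scores are
averaged per gene (missing layers excluded), the averages are
rank-normalized once more, and genes with integrated score strictly
greater than 0.9 — exactly the top decile — are flagged **essential**.
Overall survival of patients altered vs unaltered in the essential genes
is then compared by Kaplan–Meier medians (log-log 95% CIs) and the
log-rank test.

The Mann–Whitney U test (tie-corrected, exact enumeration for small
samples), Kaplan–Meier estimator with Greenwood variance, log-rank test
and BFS shortest paths are implemented in the package and cross-checked
in the test suite against `stats::wilcox.test`, the `survival` package,
`igraph`, and brute-force oracles.

## Worked example

The package ships a desk-scale synthetic study: 40 CR genes (3 CCC,
12 CCG, 25 NMCRE), 30 driver proteins, four cohorts of 500 patients, and
one gene (`CRG001`) planted with a multi-layer cancer signal (alteration
rate multiplier 30, log hazard ratio 1.1, guaranteed high-confidence
driver interactions, direct hallmark links).

```r
library(chronoprio)
cfg <- default_sim_config(seed = 1)
res <- run_pipeline(cfg)
#> alterations: 8410 calls -> 1 genes above cutoff 0.105
#> network: 614 edges -> 54 nodes retained
#> prognosis: 1 unfavorable gene(s)
#> hallmarks: 37 of 40 proteins reach a phenotype
#> integration: 4 essential gene(s)

head(res$scores[order(-res$scores$integrated_score), ], 5)
#>    gene alteration   network prognosis hallmark integrated_score essential_flag
#>  CRG001  1.0000000 1.0000000      1.00    0.875        1.0000000           TRUE
#>  CRG005  0.8974359 0.7857143      0.85    0.875        0.9743590           TRUE
#>  CRG009  0.7435897        NA        NA    0.875        0.9487179           TRUE
#>  CRG024  0.5641026 0.9464286        NA    0.875        0.9230769           TRUE
#>  CRG011  0.5384615 0.9464286        NA    0.875        0.8974359          FALSE
```

The planted gene tops every layer and is flagged essential; the other
flagged genes are the remainder of the top decile (4 of 40 genes). `NA`
means a gene contributed no evidence in that layer (no retained
interactome edge, never unfavorable) and is excluded from its mean rather
than penalized.

```r
res$survival$table
#>      group    n median_os   ci_low  ci_high
#>    altered 1174  28.27073 25.31468 29.65947
#>  unaltered  826  58.76450 54.24962 64.48916
res$survival$test$p_value
#> [1] 3.266839e-39
```

The metastatic cohort is simulated with group medians of 30 vs 55
months; the Kaplan–Meier estimates recover them within Monte-Carlo error
and the log-rank test separates the groups decisively.

`res$tally` recomputes every headline count and percentage (total
patients, per-category gene counts, selected/unfavorable/reachable/
essential set compositions) from the emitted tables;
`run_pipeline(cfg, outdir = "...")` writes all layer outputs as
tab-delimited tables plus a JSON run manifest, and
`simulate_inputs(cfg, outdir)` writes the raw synthetic input tables for
use with the individual layer functions (`alteration_layer()`,
`network_layer()`, `prognosis_layer()`, `hallmark_layer()`).

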