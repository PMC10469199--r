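---
title: "Methods: multi-omics prioritization of circadian rhythm genes in cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics prioritization of circadian rhythm genes in cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(chronoprio)
```

# The scientific problem

Circadian rhythm (CR) related genes — canonical clock components (CCC),
clock-controlled genes/proteins (CCG/CCP), and genes mediating the neural
mechanisms of circadian rhythmicity and its entrainment (NMCRE) — are
increasingly implicated in tumorigenesis. `chronoprio` implements a
prioritization pipeline that scores each CR gene in four independent
evidence layers and integrates the scores into a single "CR-cancer score"
per gene, flagging the top decile as *essential*:

1. **Alteration layer.** Per-patient genomic/transcriptomic alteration
   calls (mRNA up/down, CNV amplification/deep deletion, fusion, driver
   mutation) are counted per gene and cohort, normalized by cohort size
   into frequencies $f$, and genes whose mean $f$ exceeds the gene-set
   average are selected; the split is validated by a Mann–Whitney U test
   and alteration types are compared one-vs-rest under a Bonferroni family
   of $m = 6$.
2. **Network layer.** A weighted protein–protein interactome is filtered
   to high-confidence edges (confidence strictly $> 0.9$); CR proteins
   with at least one such edge to a cancer driver are retained together
   with those drivers, and degree centrality is computed on the extracted
   subnetwork.
3. **Prognosis layer.** Per gene, patients are split into low/high
   expression groups at each candidate cutoff on a percentile grid; the
   cutoff with the smallest Kaplan–Meier log-rank p wins ("maximally
   separated" analysis), and the gene is flagged *unfavorable* when the
   high-expression group survives worse and $p < 0.001$.
4. **Hallmark layer.** On a signed directed causal graph whose sinks are
   nine cancer hallmark phenotypes, each protein's distance score is the
   minimum number of directed edges to each phenotype (signs carried but
   ignored for traversal); per-phenotype means use reachable proteins
   only, and phenotype pairs are compared under a Bonferroni family of
   $\binom{9}{2} = 36$.

Within each layer, gene values are rank-normalized to $[0,1]$:
with $N$ ranked genes and average-rank ties,
$\mathrm{score} = (N - \mathrm{rank})/(N - 1)$, so the best gene scores 1
and the worst 0. Directions: higher mean $f$ and higher degree are better;
smaller unfavorable log-rank p and smaller minimum hallmark distance are
better. Finally, patients altered vs unaltered in the essential genes are
compared by Kaplan–Meier medians (log-log 95% CIs) and the log-rank test.

# Integration policy

How the four layer scores combine into one prioritization is genuinely
open: thresholding each layer, averaging, or ranking the average are all
compatible with a "top 10% (cutoff > 0.9)" rule. We default to
**rank-then-cut**: the per-gene arithmetic mean of non-missing layer
scores is itself rank-normalized, so the strict cutoff $> 0.9$ selects
exactly the top decile regardless of the score distribution, making
"score > 0.9" and "top 10%" coincide by construction. The raw-mean policy
(`policy = "raw_mean"`), a `min` combiner and zero-filling of missing
layers are exposed as alternatives; the chosen policy is recorded in the
run manifest. Genes absent from a layer (no interactome edge, never
unfavorable, unreachable from every phenotype) are NA in that layer and
excluded from the mean by default, because genes can be strong in some
layers only and zero-filling would conflate "no evidence" with "worst
evidence".

# Event counting

An alteration *event* is one distinct (patient, gene, alteration type)
triple: a patient carrying two alteration types in one gene contributes
two events. Per-type counting is the only reading consistent with
type-level mean frequencies (each type having its own mean $f$), even
though "at least one pathogenic alteration in a patient's gene" could
also be read per patient-gene. Gene x cohort combinations without events
count as $f = 0$ in every mean, so rarely altered genes are not inflated
by averaging over fewer cohorts. The selection cutoff is strict (`>`),
as is the 0.9 confidence cutoff and the 0.9 essentiality cutoff.

# The synthetic-data generator

The generator produces every pipeline input with the statistical
structure the analysis assumes, so all stages are testable without
external downloads. It emulates:

* **Cohorts and alteration calls.** Independent Bernoulli draws per
  patient x gene x type at type-specific base rates (mRNA down 0.028,
  mRNA up 0.019, CNV amplification 0.009, CNV deep deletion 0.003,
  driver mutation 0.0026, fusion 0.0003 — the per-type mean frequencies
  of the pan-cancer study). Planted genes multiply every base rate
  (clamped at 1 with a warning).
* **Interactome.** Distinct undirected pairs sampled uniformly without
  self-loops; confidences uniform on $[0.15, 1]$ (roughly the spread of
  string-database combined scores), so about 12% of edges survive the
  0.9 filter.
* **Causal graph.** Each directed protein-protein and protein-phenotype
  pair wired independently at density 0.03 with a random sign; phenotypes
  are sinks.
* **Survival.** Exponential proportional hazards,
  $h = h_0 e^{\beta z}$, with $z$ a standardized expression value or an
  altered indicator. The exponential baseline is chosen for its closed
  form (median $= \ln 2 / h$), enabling analytic checks of the KM median
  estimator. Censoring is independent exponential, calibrated so a
  fraction `censor_rate` (default 0.3) of baseline patients is censored.
  Defaults: baseline median 55 months; altered-group log hazard ratio
  $\log(55/30)$, i.e. group medians of 55 vs 30 months; altered fraction
  0.59.

One master seed fixes everything; each generator derives a sub-stream
seed by hashing its name into the seed, so adding a generator never
perturbs another's draws.

**Planted signals span all four layers.** A gene that is "essential" in
this framework is, by construction of the integration, a gene that ranks
highly in several layers at once. A plant confined to the alteration and
hazard layers leaves the gene's network and hallmark standing random, and
its integrated score then straddles the null top decile — recovery would
hinge on luck rather than signal. The default configuration therefore
plants one gene (`CRG001`) consistently: alteration rate multiplier 30,
log hazard ratio 1.1, fifteen guaranteed high-confidence driver
interactions, and a direct edge to every hallmark phenotype. This mirrors
what a genuinely cancer-essential CR gene looks like across the four
evidence sources.

**What the generator does not emulate.** Mutational signatures,
copy-number segment structure, expression count distributions,
patient-level correlation between layers (each gene's prognostic cohort
is independent), cohort-specific survival baselines, and the curated
content of real interactome or causal-network databases. Passing tests
therefore demonstrate that the pipeline recovers planted structure under
its stated statistical assumptions — not that those assumptions hold for
any particular public dataset.

# Numerical choices

* **Mann–Whitney U.** U from average ranks; exact two-sided p by
  enumeration over group assignments when the smaller group has at most 8
  observations *and* $\binom{n_1+n_2}{n_1} \le 2\times 10^5$ (unconditional
  enumeration explodes when the other group is large); otherwise the
  normal approximation with tie-corrected variance and continuity
  correction. When all pooled values are identical the test is degenerate
  and returns $p = 1$ with a warning.
* **Kaplan–Meier.** Greenwood variance; median = first time
  $S(t) \le 0.5$ (NA when never reached); median CI from the first
  crossings of the pointwise log(-log) confidence band
  (Brookmeyer–Crowley style). These conventions match
  `survival::survfit(conf.type = "log-log")`, which the test suite uses
  as an independent oracle.
* **Best-separation scan.** Percentile grid 20–80% in steps of 5 (the
  common best-expression-cutoff practice); ties in p go to the lower
  cutoff; degenerate splits are skipped; constant expression yields an NA
  result with a warning. The scanned minimum p is reported unadjusted, so
  its null distribution is anti-conservative — the suite bounds the null
  flag rate by calibration rather than correcting the p, because the
  0.001 threshold is applied to the scanned p by convention.
* **Unfavorable direction** compares the two KM curves at the largest
  time observed in both groups: robust to crossing tails and
  deterministic.
* **Ties and ordering.** Cohort rankings break ties alphabetically;
  rank scores use average ranks so tied genes share a score; all written
  tables are sorted by their leading columns with 6-significant-digit
  floats and `NA` sentinels, making outputs byte-reproducible.
* **Rounding.** Printed percentages use round-half-away-from-zero; gene
  set shares get one decimal, per-category compositions are integers.

# Problem sizes used by the test suite

The shipped study configuration is a deliberate desk-scale version of the
full study: 40 CR genes (3 CCC, 12 CCG, 25 NMCRE — the 17:59:130
proportions), 30 non-CR driver proteins, four cohorts of 500 patients, a
600-edge interactome and 500-patient prognostic cohorts per gene. At this
scale one full pipeline run takes about two seconds, so the recovery
suite can afford 100 independent seeds, the null calibrations 1,000 to
20,000 replicates, and the oracle equivalences hundreds of random graphs.
The study-scale arithmetic (10,918 patients over 32 cohorts; 206 genes
as 17 + 59 + 130) is exercised directly on the shipped reference tables,
where only arithmetic — not simulation — is involved.

# Known limitations

* The prognosis layer treats each gene's survival cohort as independent;
  real per-patient expression matrices induce correlated scans.
* Categories overlap with the driver flag: a CR protein that is also a
  driver is reported under its CR category with the flag retained, and
  group summaries therefore need not sum to 100%.
* The hallmark layer reduces a protein's nine distances to their minimum
  for ranking; a per-phenotype variant would rank proteins within each
  phenotype separately.
* Gene symbols are compared case-sensitively after whitespace stripping;
  no alias resolution is attempted.
* The Methods-vs-Results ambiguity in the hallmark vocabulary (DNA
  repair/glycolysis vs genome instability/energetics) is resolved by
  shipping both as presets (`hallmark_phenotypes("methods")` /
  `("results")`), with `"results"` the default.

# A minimal end-to-end run

```{r, eval = FALSE}
cfg <- default_sim_config(seed = 1)
res <- run_pipeline(cfg, outdir = "chronoprio_run")
res$essential              # essential gene symbols (top decile)
res$survival$table         # altered vs unaltered KM medians + 95% CIs
res$tally                  # every headline count and percentage
```
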