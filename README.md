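# devvar

Differential expression-**variability** screening for age-grouped
transcriptome studies.

Developing brain tissue shows more heterogeneous gene expression across
individuals than adult tissue. Genes behind that heterogeneity have the same
*mean* in children and adults but a larger *variance* in childhood — a
pattern differential-expression tools cannot see. devvar screens a
probe-by-sample expression matrix for exactly this pattern and carries the
result through the downstream questions a study must answer: is the excess
variance just developmental regulation in disguise, which functions are
over-represented, and does the pattern replicate in an independent dataset
and on an independent platform?

## The statistic at the core

Subjects are split at an age cutoff (default 15 y) into young and old
groups. After preprocessing (detection filter, global offset + log2,
quantile normalization, technical-replicate averaging, sex centering),
probes are ranked by pooled variance and the top 5% are tested one-sidedly:

    H0: sigma²_young / sigma²_old <= 1
    F  = s²_young / s²_old  ~  F(n_young - 1, n_old - 1)

with upper-tail p-values, Benjamini–Hochberg FDR and Storey pFDR q-values
side by side (significance at `q_pfdr < 0.25` by default), plus two
distribution-free summaries over the tested probes: the fraction with
`sd_young > sd_old` and a paired Wilcoxon signed-rank test. A quadratic
age-trajectory F-test (joint 2-df test of `age + age²` adjusting for sex and
developmental delay) separates genuine inter-individual variability from
ordinary developmental regulation, and hypergeometric over-representation
runs against two reference universes (all present genes; top-variance
genes). A permutation diagnostic quantifies the selection bias that the
variance pre-filter induces under unbalanced group sizes.

## Worked example

Everything below is synthetic: the generator plants differential-variability
genes (group SD ratio 3), quadratic age trajectories, and sex effects into a
40-array / 37-subject design (29 young, 8 old, 3 subjects in duplicate) and
keeps the ground truth.

```r
library(devvar)

study <- simulate_expression_study(sim_config(n_probes = 20000, seed = 17))
prep  <- preprocess_study(study$matrix, study$samples)
fit   <- dv_screen(prep$matrix, prep$samples)   # top 5%, pFDR < 0.25
summary(fit)
#> Differential-variability screen summary
#>   probes tested:        950
#>   group sizes:          29 young / 8 old
#>   SD greater in young:  64.3%
#>   signed-rank p:        0.00208
#>   estimated pi0:        1.000
#>   probes below q threshold:
#>     q < 0.05  BH: 586    pFDR: 586
#>     q < 0.1   BH: 604    pFDR: 604
#>     q < 0.25  BH: 609    pFDR: 609
```

950 probes (5% of the 19,000 that survive the detection filter) enter the
test; 64.3% have a larger standard deviation among the young subjects — a
signed-rank p of 0.002 against the paired null — and 609 are called
significantly more variable in childhood at pFDR < 0.25. The trajectory
screen then shows none of those calls is explained by a smooth age trend:

```r
sig  <- fit$table$probe_id[fit$table$significant]
traj <- screen_age_regulated(prep$matrix, prep$samples, probes = sig)
sum(traj$developmentally_regulated)
#> [1] 0
```

`plot(fit)` draws the paired SD-difference boxplot. With gene sets and a
probe→gene map, `enrichment_report(fit, sets, map)` produces the dual
expected-versus-observed tables, and `run_pipeline(study_config(...))`
executes the whole chain from a YAML config or simulation block, writing
result CSVs plus a manifest that pins every parameter and the seed. A thin
CLI wraps the same functions: `inst/cli/devvar simulate|run`.

## Scope

devvar consumes preprocessed or raw intensity matrices as plain TSV (plus
optional detection p-values), metadata TSV, GMT gene sets and a two-column
probe→gene map. Array image processing, CEL-file preprocessing, probe
re-annotation and ontology retrieval are out of scope; annotations are
supplied as files.
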