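---
title: "Screening for differential expression variability between age groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for differential expression variability between age groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devvar)
```

## The question

Most transcriptome comparisons ask whether a gene's *mean* expression differs
between groups. devvar asks a different question: whether the *variance* of a
gene's expression across individuals differs. The motivating setting is brain
development — cortical tissue from children shows more dynamic, heterogeneous
expression than adult tissue, and genes whose inter-individual variance is
larger in childhood are candidates for involvement in developmental
plasticity. A difference in variance is invisible to differential-expression
machinery: a gene can have the same mean in both groups while being tightly
regulated in one and widely dispersed in the other.

## The model and the screen

Let $x_{gi}$ be the log2 expression of probe $g$ in subject $i$, and split
subjects at an age cutoff (15 years by default) into a *young* and an *old*
group of sizes $n_y$ and $n_o$. For each probe the screen computes the
unbiased group variances $s^2_y$ and $s^2_o$ and tests

$$H_0: \sigma^2_y / \sigma^2_o \le 1
\quad\text{with}\quad
F_g = s^2_y / s^2_o \sim F(n_y - 1,\; n_o - 1)$$

using the upper tail of the F distribution, so the p-value accounts for the
unequal degrees of freedom of the two variance estimates. Under normality
within each group this is the exact likelihood-ratio test for a variance
ratio; it is, by the same token, sensitive to heavy tails, which is one
reason the screen also reports two distribution-free summaries over the
tested probes:

* the fraction of probes with $s_y > s_o$ (ties count as not greater), and
* a Wilcoxon signed-rank test on the paired differences $s_y - s_o$.

Multiplicity is handled two ways, side by side: Benjamini–Hochberg q-values
(`q_bh`), and Storey positive-FDR q-values (`q_pfdr`) in which the null
proportion $\hat\pi_0$ is estimated on the grid
$\lambda \in \{0, 0.05, \dots, 0.95\}$ by a cubic smoothing spline (df = 3)
evaluated at $\lambda = 0.95$ and clamped to $(0, 1]$; q-values are
$\hat\pi_0$ times the BH values. The significance flag defaults to
`q_pfdr < 0.25`; both the flavour and the cutoff are arguments.

### The variance pre-filter and its selection bias

Before testing, probes are ranked by pooled variance across *all* subjects
and the top fraction (5% by default, or an explicit `top_k`) is retained.
This concentrates the test on probes with meaningful inter-individual
dispersion, but it is not innocuous: conditioning on high pooled variance
when the groups are unbalanced (29 vs 8 here) tilts the null distribution of
the proportion-greater statistic above one half, because the larger group
contributes more weight to the pooled variance. `permutation_null_proportion()`
quantifies this by permuting age labels and re-running the selection and
proportion; under a global null with the 29/8 design and a top-5% filter the
permutation null centers near 0.55–0.58 rather than 0.50, while balanced
unfiltered designs center at 0.50. Interpret the headline proportion against
that permutation null, not against 0.5.

## Preprocessing

`preprocess_study()` enforces the canonical order, and each step writes a
provenance record:

1. **Detection filter.** A probe is kept if its detection p-value is at or
   below 0.1 in at least `min_individuals` *unique subjects* (a subject
   counts as detected if any of its replicate arrays is detected; an
   all-replicate rule is available). `min_individuals` defaults to half the
   subjects, rounded down; studies replicating a published configuration
   can pin it explicitly (e.g. 16).
2. **Offset and log2.** One global constant $c = 1 - \min(x)$ shifts the
   whole matrix so its smallest intensity is exactly 1 before log2; $c$ may
   be negative. A single global constant (rather than per-column offsets)
   preserves between-sample contrasts.
3. **Quantile normalization** on the log2 values. Every column is mapped
   onto the reference distribution of row means of column-sorted values;
   ties within a column receive the mean of the reference values at their
   tied ranks, so tied inputs stay tied. The transform is idempotent and
   equalizes column sums.
4. **Technical replicate averaging.** Replicate arrays of a subject are
   averaged (arithmetic mean) into one column keyed by subject; covariates
   must agree across replicates.
5. **Sex adjustment.** Per probe, the male mean is subtracted from male
   samples and the female mean from female samples, leaving each level
   centered at zero without touching within-level variances. An `unknown`
   code forms its own level, so a study without sex metadata degrades to
   overall centering — and the screen can skip the step entirely
   (`adjust_sex = FALSE`), the usual choice for external replication
   datasets lacking sex information.

## Excluding developmental trajectories

Greater childhood variance could be an artifact of ordinary developmental
regulation: a gene following a steep age trajectory looks hypervariable in
any age-heterogeneous group. `screen_age_regulated()` fits, per probe,

$$x_i = \beta_0 + \beta_1 a_i + \beta_2 a_i^2 + \beta_3\,\mathrm{sex}_i +
\beta_4\,\mathrm{delay}_i + \varepsilon_i$$

with age centered before squaring (the F-test is invariant to affine age
recoding), and tests the joint age contribution against the reduced model
without $a, a^2$: $F = \frac{(SSE_r - SSE_f)/2}{SSE_f/(n-5)}$ on
$(2, n-5)$ df. The two age columns are tested jointly — a gene is
"developmentally regulated" if age explains its expression in any quadratic
shape. Probes flagged at `q_pfdr < 0.25` are candidates for exclusion from
the variability interpretation. Constant expression yields $p = 1$ by
convention; constant nuisance covariates (e.g. no delayed subjects) are
dropped from the design with a message, while collinear age terms (constant
age) are an error. Missing delay flags are imputed as `FALSE` with a
warning, keeping the screen total.

## Enrichment with two reference universes

Significant probes are collapsed to unique gene ids and tested for
over-representation in flat gene sets with the hypergeometric upper tail,
$P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$, reporting the
chance-expected count $nK/N$ next to the observed count. The test runs
twice: against all genes present after filtering, and against the genes of
the top-variance subset. The second universe asks a sharper question — is
the young-variable subset enriched *among already-variable genes* — and both
are recomputed from their own $N$ and $K$, never rescaled from one another.
Terms are flat sets (no ontology graph); the report keeps rows at
`q <= 0.1` by default.

## Replication and cross-platform validation

`replicate_screen()` reruns the screen semantics on an external,
already-preprocessed dataset with the sex step disabled.
`expected_overlap()` compares an observed cross-study intersection with the
$|A||B|/N$ chance expectation for a user-supplied shared-gene universe
(the universe size is an explicit input: it depends on the platform pair and
is not guessable from the sets). `fisher_exact_2x2()` is the exact
conditional test with the point-probability two-sided rule and the sample
odds ratio $ad/bc$; both nesting conventions of a focal-set-vs-database
table are easily expressed, and the package computes either.
`correlate_platforms()` correlates per-sample measurements across platforms
(Spearman by default, flagging $p < 0.05$), the standard check of microarray
signal against qPCR $-\Delta Ct$ values, with the convention
$-\Delta Ct = Ct_{\mathrm{reference}} - Ct_{\mathrm{target}}$ so the value
increases with target expression.

## What the simulator emulates — and what it does not

`simulate_expression_study()` generates the design the screen targets:
29 young (ages uniform on [0.5, 14.5]) and 8 old ([15, 53]) subjects, three
of them arrayed in duplicate (40 arrays, 37 unique samples), probes drawn
from classes — null, differentially variable (group SD ratio
`variance_ratio`, default 3), developmentally regulated (concave quadratic
trajectories peaking in childhood with amplitude 0.75–1.5 log2 units), sex
effects (±0.5–1.5 log2), or mixtures. Signals become raw intensities as
$2^x$ plus half-normal background; expressed probes get detection p-values
uniform on [0, 0.05], unexpressed ones uniform on [0, 1]. One RNG stream is
consumed in a fixed order (probe parameters, sample covariates, noise,
detection), so a seed pins the whole study. Choices the data do not dictate
were fixed once: ages uniform within their ranges, sex Bernoulli(0.5) per
subject, developmental delay at rate 0.2, adult log2 SD 0.3, technical SD
0.1 — values typical of intensity-scale expression arrays of this design.

The simulator does **not** model probe-level bead replicates, spatial or
batch artifacts, correlated gene modules, or mean–variance coupling. Passing
tests therefore demonstrate the statistical machinery under the stated
generative model, not robustness to every pathology of real arrays.

Two interactions discovered with the simulator are worth knowing:

* **Quantile normalization redistributes asymmetric signal.** When a
  sizeable fraction of genes moves with age in one direction, forcing all
  samples onto a common distribution leaks a small age-dependent shift into
  every gene: in a simulation with 10% strong trajectories, null genes show
  ~10% of age-model p-values below 0.05 versus ~4% without normalization.
* **Trajectory genes compete for the top-variance list.** A steep age
  trajectory produces large pooled variance without a group variance *ratio*,
  so under defaults the top-5% list mixes both classes and the
  proportion-greater statistic varies noticeably between seeds. This is
  precisely the confound the quadratic exclusion step addresses.

## Numerical conventions

* Unbiased ($n-1$) variances throughout; `top_k = round(fraction * n)` with
  lexicographic probe-id tie-breaking at the selection boundary.
* Degenerate variance ratios: $s^2_o = 0, s^2_y > 0 \Rightarrow p = 0$;
  both zero $\Rightarrow p = 1$; flagged either way.
* Signed-rank: zeros dropped; exact distribution for up to 25 untied
  nonzero pairs, else normal approximation with continuity and tie
  corrections; all-zero differences give $p = 1$ with a note.
* Fisher two-sided p sums point probabilities $\le$ the observed table's
  (with the customary $1 + 10^{-7}$ tolerance).
* $\hat\pi_0$ clamping means Storey q-values never exceed 1 and are never
  scaled by a nonpositive null proportion.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise the screen at 10,000
probes for null calibration and power (against the closed form
$P(F_{28,7} \ge F_{\mathrm{crit}}/\rho)$), 20,000 probes for the end-to-end
pipeline demonstration, 4,000 probes for planted-truth recovery, and 300
permutations for the selection-bias diagnostic — sizes at which every
Monte-Carlo comparison has standard error well inside its asserted
tolerance.

## Known limitations

* The F-test's normality assumption is untested by the screen itself;
  heavy-tailed expression would inflate the variance ratio's tails.
  Distribution-free alternatives (Levene, Brown–Forsythe) are deliberately
  out of scope.
* Storey's $\hat\pi_0$ is unstable for very small p-value sets (tens of
  tests); BH is reported alongside for exactly that reason.
* Enrichment treats gene sets as flat and independent; ontology structure
  and term overlap are ignored.
* The published headline counts of the motivating study (71% of 1,095
  probes, 337 significant, replication at 78%/529) depend on the deposited
  data and the original pFDR estimator; the pipeline exposes the exact
  configuration (detection 0.1/16, top-k 1095, cutoff 15 y, q < 0.25)
  needed to attempt them, but they are not reproducible from synthetic
  data.
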