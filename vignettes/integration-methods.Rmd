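---
title: "Statistical integration of miRNA and mRNA differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical integration of miRNA and mRNA differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlink)
```

## The problem

MicroRNAs repress their target mRNAs, so a miRNA that is dysregulated in
disease should leave a footprint of *anti-correlated* targets: genes whose
expression moves opposite to the miRNA. `mirlink` turns miRNA and mRNA
differential-expression (DE) evidence plus a user-supplied target map into
per-pair or per-miRNA calls of impaired regulation, and ships the
simulation benchmark used to compare the candidate statistics.

Two study designs require two different machineries:

* **Paired** — miRNA and mRNA profiled on the same samples. Candidate
  (DE-miRNA, target DEG) pairs are tested for one-sided anti-correlation
  across samples.
* **Unpaired** — different cohorts. No sample-level correlation exists, so
  each DE-miRNA is tested for association between its target set and the
  set of genes differentially expressed in the opposite direction.

## Paired mode: simple and partial correlation

For a candidate pair, `correlate()` computes Pearson or Spearman
correlation, one-sided for negative association, with
`t = rho * sqrt(df / (1 - rho^2))` against a Student-t null (`df = n - 2`,
reduced by one per adjustment covariate for partial variants). Spearman is
Pearson on mid-tie ranks; the partial variants residualize on an
intercept + group design before correlating (for Spearman: rank first,
then residualize — the standard partial-Spearman construction).

The reason partial correlation exists here is Simpson's paradox: a
disease affects thousands of genes through miRNA-independent routes, so a
DE-miRNA and a DE gene shift *together* at the group level and look
anti-correlated even when they are conditionally independent. Partialing
out the group label removes exactly that component.

`integrate_paired()` enumerates candidate pairs (target-map pairs whose
miRNA and gene are both significant and measured), adjusts p-values over
the tested pairs (BH by default, Storey q-values optionally) and calls
pairs with `rho < -0.5` and adjusted p `< 0.1` — the thresholds the
paired case studies in this field typically use, and our defaults.

The one-sided alternative is the default because the biology specifies a
direction (repression); a two-sided mode is available via the
`alternative` argument.

## Unpaired mode: directional association tests

`build_contingency()` classifies the measured-gene universe by
(target of the miRNA?) × (DEG in the direction opposite to the miRNA?).
The universe is every measured gene — not the genome — so detection bias
does not inflate enrichment. Three one-sided tests are offered:

* `fisher_one_sided()` — exact hypergeometric upper tail;
* `fisher_midp()` — Lancaster mid-P, counting half the observed table's
  probability, which reduces the conservativeness of the discrete tail;
* `boschloo()` — Boschloo's unconditional exact test: the one-sided
  Fisher p is used as the ordering statistic, and the p-value is the
  maximum over a nuisance grid (1001 points on [0, 1], endpoints
  included) of the probability of an outcome at least as extreme under
  independent binomial rows. It is uniformly at least as powerful as
  Fisher's test, and the implementation exploits the monotonicity of the
  Fisher statistic in the second row's count so that universes with
  thousands of genes remain fast.

Mid-P is implemented for Fisher only; applying it to Boschloo as well
would double-correct the same discreteness.

Because the test is per-miRNA, miRNAs with no measured targets or with a
zero log2 fold change cannot be tested; they are reported, flagged, and
excluded from the multiplicity correction so they do not dilute FDR.

## Expression-level comparators

Two set tests operate on the mRNA cohort's expression directly, with the
tested direction opposite to the miRNA's fold change:

* `rotation_set_test()` — a self-contained rotation test in the ROAST/fry
  family: each gene is projected onto the complement of the intercept,
  the first coordinate spanning the group contrast; a rotation replaces
  that coordinate with the projection onto a random unit vector *shared
  across genes*, preserving inter-gene correlation. The statistic is the
  mean directional z; `p = (1 + #{S_b >= S}) / (B + 1)`, so p-values have
  granularity `1/(B+1)` and are exactly reproducible under a seed. This
  is a Monte-Carlo construction with the same hypotheses as the analytic
  fry shortcut, not a numerical clone of it.
* `camera_test()` — a competitive comparison of in-set versus out-of-set
  z statistics with a variance inflation factor
  `VIF = 1 + (m - 1) * rho_bar`, where `rho_bar` is the mean inter-gene
  correlation of group-centered residuals (`estimate_setcorr()`,
  truncated to [0, 1)).

Ordinary pooled-variance t statistics feed both tests; empirical-Bayes
moderation would shift numbers slightly but not the benchmark's
qualitative comparisons, and is out of scope.

## Multiplicity

`bh_adjust()` implements the Benjamini-Hochberg step-up rule.
`storey_qvalue()` scales it by an estimate of the null proportion:
`pi0(lambda) = #{p > lambda} / (m (1 - lambda))` on a lambda grid,
smoothed by a cubic smoothing spline with 3 degrees of freedom and read
off at the largest lambda, clamped to `[1/m, 1]`. Storey's estimator
presumes a roughly uniform null; the choice between BH and q-values is
left to the user (every integration function takes `adjust =`), matching
how the method is applied judgmentally per dataset in practice. Fewer
than 20 p-values fall back to `pi0 = 1` (= BH) with a warning.

## Over-representation analysis

`ora()` tests a hit list (e.g. genes in called pairs) against GMT gene
sets by the hypergeometric upper tail — the same kernel as the one-sided
Fisher test, a fact the test suite checks by exact equivalence — with BH
across sets and a minimum intersected set size of 2.

## The simulator: a stated world

`simulate_study()` generates a paired two-group study in which the truth
is known, used both as the benchmark engine and as ground truth for
integration tests. Its defaults are a single frozen "stated world"; every
number below is a declared modelling choice, not a fitted quantity, and
the benchmark's published-scale results are only meaningful relative to
this world.

On the log2 scale, with group indicator `I`:

* 100 miRNAs, 2000 genes, 10 samples per group; baselines uniform on
  [4, 12].
* 20% of miRNAs are differentially expressed (`delta` uniform on [1, 2],
  random sign). 40% of those are *influential*: half of their 50 targets
  (sampled without replacement; claimed by at most one miRNA) are truly
  repressed. The remaining DE-miRNAs change expression without
  downstream effect — the true negatives of the per-miRNA benchmark;
  without them every categorical method would score a trivial F1.
* A truly affected target follows
  `y = mu_g - beta * h(x - mu_x) + noise`, `beta` uniform on [0.7, 1.7].
  The default dose-response `h` is the *rank* coupling: the centered
  miRNA signal is replaced by its sample ranks, rescaled to the signal's
  spread. This is a monotone curve that saturates in the extremes by
  construction, encoding the view that repression tracks the ordering of
  miRNA abundance rather than its log-scale magnitude; it is the reason
  rank-based (Spearman) statistics outperform moment-based ones in this
  world, consistent with the non-linearity of real miRNA-target
  dose-response. Linear, tanh-saturating and raw-scale-exponential
  couplings are available via `coupling =`.
* Noise is sd-matched Student-t with 3 degrees of freedom (miRNA sd 0.5,
  gene sd 0.85) — expression data have occasional outlying samples, and
  Gaussian noise (`*_df = Inf`) understates them.
* Confounding has two channels. A **disease program** gives 60% of the
  remaining genes a strong group effect (uniform on [2.5, 4.5], random
  sign): the miRNA-independent transcriptional response. Coincidences
  between program genes and DE-miRNA targets produce marginally
  anti-correlated false pairs, and the program raises the DEG baseline
  that competitive association tests correct for. A **targeted channel**
  gives 40% of each DE-miRNA's unaffected targets a mild anti-mimicking
  effect (uniform on [1.05, 1.55]) plus a weak within-group
  co-fluctuation with the miRNA (rho 0.18) — genes sharing upstream
  regulators with the miRNA. These effects usually reach DEG
  significance in the full paired cohort but not in a half-size unpaired
  cohort, which is what differentiates the test families: self-contained
  rotation tests aggregate the sub-threshold shifts and over-call,
  competitive exact tests do not.

What a green benchmark run does establish: the relative behavior of the
statistics under group-level confounding, non-linear coupling and
heavy-tailed noise, and their FDR calibration under the null variants.
What it does not establish: performance on count-level data (no
negative-binomial layer), batch effects, more than two groups, real
target-map error structure, or any claim about a specific disease.

## The benchmark

`run_paired_benchmark()` repeats: simulate → Welch-t DE on both matrices
(`welch_de()`, BH, features kept at adjusted p < 0.05) → integrate each
correlation method over candidate pairs → score calls against the truly
affected pairs restricted to the tested candidates. F1 uses the
case-study call rule; AUPRC ranks by raw p-value (threshold-free,
step-integrated average precision with pessimistic tie handling).
`run_categorical_benchmark()` does the analogue after an unpaired split
(`split_unpaired()`, disjoint balanced halves), with a miRNA counted as a
true positive iff it is a simulated DE-miRNA with at least one truly
affected target. Empirical FDR curves are recorded at nominal levels
0.01/0.05/0.1/0.2 from the `padj < level` rule alone (the rho cut is a
separate filter and would only lower FDR). The default 100 replicates
keep a benchmark run in minutes; the reference scale of 500 is available
by setting `reps`.

At the frozen defaults, 100 replicates give mean F1 ≈ 0.80 and mean
AUPRC ≈ 0.88 for partial Spearman and mean AUPRC ≈ 0.78 for simple
Spearman (the acceptance script recomputes these from scratch), with
partial Spearman above partial Pearson in essentially every replicate —
the orderings, not the absolute values, are the robust product of the
benchmark.

## Numerical choices and edge cases

* Correlation at `|rho| = 1` returns p of exactly 0 or 1 instead of the
  unstable t transform; constant vectors (after residualization) yield
  `rho = NA`, `p = 1` and a warning, never an exception.
* Boschloo's nuisance maximization uses a uniform grid (default 1001
  points) with ties in the ordering statistic resolved at absolute
  tolerance 1e-12; the rejection-region boundary is located by binary
  search, which requires (and the tests verify) monotonicity of the
  Fisher statistic in the non-target DEG count.
* Rotation z statistics are clamped to |z| <= 8 to keep degenerate genes
  finite; genes with zero residual variance get z = 0 with a warning.
* BH is invariant to input order; Storey q-values equal BH scaled by
  pi0, so they can never exceed BH.
* Output ordering is deterministic everywhere (lexicographic pair order;
  miRNA input order in unpaired mode); all simulation randomness flows
  from a single seed, and per-replicate seeds are `seed + rep`.

## Known limitations

* The DE step inside the benchmark is a plain Welch t-test; real
  analyses should supply limma/edgeR/DESeq2 results via
  `read_de_table()`.
* Identifier matching is exact and case-sensitive; no miRBase version
  reconciliation.
* Missing values in expression matrices are rejected rather than
  imputed.
* In the stated world the small-sample penalty of partial correlation at
  5 samples per group is visible for partial Pearson but not partial
  Spearman, whose rank coupling advantage already dominates there; the
  sample-size sweep asserts the Pearson-family contrast only.
* The unpaired split halves both cohorts, so the categorical benchmark's
  absolute F1 depends on cohort size as much as on the tests; only
  within-run comparisons are meaningful.
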