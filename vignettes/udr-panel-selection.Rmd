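---
title: "Methods: UDR-based exosomal miRNA panel selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: UDR-based exosomal miRNA panel selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(udrpanel)
```

## The problem and the score

Distinguishing early-stage (I–II) non-small cell lung cancer from benign
pulmonary nodules is the clinically hard case: both present as indeterminate
nodules on CT, and biopsy carries real risk. Serum exosomal miRNAs are a
candidate non-invasive readout. A single miRNA rarely separates the groups
well, so the package scores *panels*: given up-regulated members $U$
($N = |U|$) and down-regulated members $D$ ($M = |D|$) with linear
expression $E(f, s)$,

$$\mathrm{UDR}(s) =
  \frac{\tfrac{1}{N}\sum_{f \in U} E(f,s)}
       {\tfrac{1}{M}\sum_{f \in D} E(f,s)}.$$

Both directions push the score the same way in cases, and the ratio cancels
any sample-level multiplicative factor, which is the main nuisance in serum
qPCR data. Panels are compared by the AUC of their UDR scores for the
early-stage-vs-benign contrast.

**Expression scale.** "Expression level" must be strictly positive for the
ratio to make sense, and ΔCt can be negative. We therefore compute UDR on
linear relative expression: $2^{\Delta Ct}$ for qPCR (one PCR cycle is one
doubling, so ΔCt is a log2 abundance) and $\mathrm{CPM} + 1$ for counts.
`udr_score(type = "log")` provides a log-scale variant (difference of mean
log2 expressions) for sensitivity analysis; it is also the variant with a
closed-form population AUC used as a test oracle (below).

**Missing members.** A sample missing any panel member is skipped and
logged, not imputed; an averaged-over-available-members rule would silently
change the estimand of the score. This is deliberate and conservative.

## The filtering cascade

Defaults in `udr_config()` encode one specific, auditable cascade:

| parameter | default | units | role |
|---|---|---|---|
| `prevalence_stage1` / `prevalence_stage2` | 0.50 / 0.45 | zero fraction | drop features with zero counts in *strictly more* than this fraction of samples, two passes |
| `edge_fc_min` | 2.0 | log2 | count-test hit needs \|log2 FC\| strictly above this |
| `edge_p_max`, `mw_p_max` | 0.05 | — | raw two-sided p cutoffs (strict) for the two discovery arms |
| `val_fc_min` | 1.5 | linear ratio | validation fold-change gate, inclusive |
| `val_p_max` | 0.05 | — | validation rank-sum cutoff (strict) |
| `parsimony_epsilon` | 0.02 | AUC | band below the best AUC within which smaller panels win |
| `undetermined_max` | 0.5 | fraction | missing-rate above which a validation marker is "undetermined" |
| `pseudocount` | 1 | CPM | keeps the linear scale strictly positive |

Notes on the deliberately asymmetric inequalities. Prevalence and the
discovery FC/p gates are strict ("greater than 50%", "\|log2 FC\| > 2"),
matching the cascade's stated wording. The validation FC gate is
*inclusive* (≥ 1.5): validated marker lists in this field include markers
whose printed fold change is exactly 1.5, which implies the underlying
comparison was made on unrounded values where an exactly-at-threshold print
still passes; with strict comparison such a marker could never validate.
Because both comparisons act on continuous estimates, the choice only
matters in the measure-zero exact-tie case, but it is recorded in the
output metadata.

Since 0.45 < 0.50, the two prevalence passes are mathematically one 0.45
pass; the package still runs both so the per-stage log (feature counts
before/after every filter) matches the two-step audit trail convention.
This equivalence is property-tested.

**Stage-consistency rule.** After intersecting the two discovery arms,
features are dropped unless the pooled stages-I–IV-vs-benign contrast also
reaches p < 0.05. Whether "stages I–IV against benign" means the pooled
group or each stage separately is genuinely ambiguous; we default to pooled
(`stage_rule = "pooled"`) because per-stage ALL-must-pass is far stricter
than any per-stage sample size here can support, and expose
`stage_rule = "per_stage"` as a switch.

**Literature candidates** are configuration data (default
miR-497-5p, miR-21-5p, miR-205-5p), appended after the set operations,
deduplicated and tagged; an entry absent from the measured universe warns
but is kept, so a panel run cannot silently lose a prespecified marker.

## Statistical primitives

**Mann–Whitney U** (`mann_whitney`). $U$ counts pairs with the case value
higher, ties counting half. For $n_1 + n_2 \le 12$ without ties the p-value
is exact (the full permutation null of $U$; two-sided as the probability of
a $U$ at least as far from $n_1 n_2 / 2$ as observed). Otherwise the normal
approximation with midrank tie correction and continuity correction is
used. The exact branch is verified in tests against brute-force enumeration
of all $\binom{n_1+n_2}{n_1}$ assignments, and the approximate branch
against the reference implementation in base R.

**Exact conditional NB test** (`exact_nb_test`). The discovery count arm is
a transparent exact test rather than a re-implementation of a specific
package: under the null of equal relative abundance, the group-1 total
given the feature's overall total $s$ is Binomial$(s, N_1/(N_1+N_2))$ in
the Poisson limit ($N_g$ = summed library size); with common dispersion
$\phi$ each group total is moment-matched to a negative binomial with size
$N_g^2 / (\phi \sum_s l_s^2)$ (exact for equal within-group library sizes,
where the conditional distribution is also free of the nuisance mean) and
the conditional law is enumerated, with a $\pm 40$-SD enumeration window
once $s$ exceeds 20{,}000 (mass outside is far below double precision).
Two-sided p doubles the smaller tail, capped at 1 — the standard convention
for exact tests; note this differs from the symmetric-distance convention
of the exact rank-sum branch, where the null is symmetric anyway.
Dispersion is a pooled method-of-moments estimate
($\max(0, (s^2-\bar m)/\bar m^2)$ per feature on depth-scaled counts,
median across expressed features). This substitution means p-values will
not bit-match TMM/CML-based tools; tests check close agreement with edgeR's
exact test on equal library sizes and correct type-I behaviour (the
fraction of null p-values below 0.05 is within 0.05 ± 0.02 over 1000
simulated null features at dispersion 0.2). The interface isolates the test
so a different backend could be swapped in.

**ROC/AUC** (`roc_auc`). AUC via the rank (Mann–Whitney) identity, with the
curve built by threshold sweep; the trapezoidal area of the curve equals
the rank AUC exactly and both routes are compared in tests, plus a
cross-check against pROC. The 95% CI is a stratified bootstrap percentile
interval (2000 resamples, seeded); the interval is clamped to contain the
point estimate, which matters only in degenerate resampling regimes. No
analytic (DeLong-type) interval is offered, because the CI method behind
reported intervals in this field's tooling is typically unstated; bootstrap
is explicit and reproducible.

**Per-marker ROC orientation.** Markers are reported with AUC ≥ 0.5: the
raw AUC (case scored by ΔCt directly) is computed first and the score sign
flipped when it falls below 0.5, recording the orientation
(`case_high`/`case_low`) and the raw AUC alongside. Orienting by group
means instead can, in rare heavy-tailed configurations, still yield an
oriented AUC below 0.5, so the AUC-based flip is used to make the "never
below 0.5" contract unconditional.

**Cohort summary** (`cohort_summary`). Counts and one-decimal percentages
per variable for whole/benign/NSCLC; age compared by rank-sum (the test
behind published Table-1 age p-values is typically unstated — the choice is
flagged in the `test` column), 2×2 categorical variables by chi-squared
with continuity correction, switching to Fisher's exact test when any
expected cell is below 5; stage and histology tabulated within NSCLC only.
`cohort_demographics()` reconstructs the per-group margins of the
motivating study's two cohorts (76 discovery / 75 validation samples);
only margins are fixed — the joint assignment across variables is
arbitrary, which is sufficient for every marginal percentage and 2×2 test.

## Panel search

`enumerate_panels` enumerates all $(2^N-1)(2^M-1)$ direction-respecting
panels and is used whenever that count is ≤ 4096 (the six-marker space of
the motivating design has 31 panels). `backward_search` is the scalable
alternative: from the full panel, repeatedly remove the single member
(keeping $N, M \ge 1$) whose removal gives the largest AUC, stopping when
no removal strictly increases AUC. Ties are broken by the
lexicographically smallest feature id, making the path deterministic.
Greedy elimination is not optimal; a property test asserts the exhaustive
optimum always dominates the backward-search endpoint. `select_optimal`
formalizes "high AUC with few members": keep panels within
`parsimony_epsilon` of the best AUC, order by size, then AUC, then member
order. The 0.02 default is our choice of "statistically indistinguishable
at these cohort sizes" — at 20 vs 35 samples the AUC standard error is an
order of magnitude larger — and it reproduces the expected preference of
compact 3–4 marker panels over a full 6-marker panel whose AUC is a few
points lower.

Directions are fixed from the validation contrast before the search; the
search never flips a marker's direction, only drops members.

## The synthetic-cohort generator

`gen_qpcr_cohort` draws, for feature $f$ and sample $s$,
$Ct(f,s) = Ct_{spike} - (\mathrm{baseline}_f + \mathrm{effect}_f \cdot
\mathbb{1}[\text{case}] + \mathcal N(0, \sigma_f))$, so planted effects are
additive on the ΔCt (log2) scale — the standard reading of qPCR shifts.
`gen_ngs_cohort` draws library sizes uniformly from `libsize_range`
(default 0.5–2 million, serum small-RNA depth territory), normalizes
baselines to proportions, and draws negative-binomial counts (Poisson at
dispersion 0) with structural zeros at `zero_prob`. Effects may differ
between early (I–II) and late (III–IV) stages so the stage-consistency rule
can be exercised with early-only signals. Every feature draws from its own
stream derived from `(seed, feature_id)`, so adding a feature never
perturbs the others — this keeps fixtures stable and is itself tested.

Calibration helpers close the loop between planted truth and observable
performance: `calibrate_effect_from_auc` returns
$\beta = \sqrt 2\,\sigma\,\Phi^{-1}(A)$, the equal-variance normal shift
with population AUC exactly $A$; `calibrate_effect_from_p` inverts the
normal approximation of the rank-sum z for a target p. Within-group
standard deviations are free parameters (no serum-cohort variance estimates
are published to emulate); every fixture states its $\sigma$.

What the generator does *not* emulate: hemolysis and other pre-analytic
artefacts, correlated miRNA co-regulation (features are independent given
the design), amplification-efficiency differences between assays,
batch/plate effects, and sequencing-specific biases upstream of the count
matrix. Passing tests therefore demonstrate correctness of the machinery
and calibration under a clean generative model, not clinical performance
on real serum cohorts.

## Numerical and degenerate-input choices

- Missing expression values are empty cells in the TSV format; an
  undetermined qPCR well maps to missing, and a marker whose missing rate
  exceeds 50% in either contrast group is reported `undetermined` (the
  published phenomenon has no published rule; the threshold is ours).
- A feature with zero counts in both groups is `flat` with p = 1, not an
  error; constant scores give AUC 0.5 with a `degenerate` flag.
- Exact-test tie tolerance: comparisons against the null distribution use a
  $10^{-12}$ slack so floating-point representation of half-integer U
  statistics cannot drop boundary outcomes.
- `expr_matrix` enforces scale invariants at construction (integral
  non-negative counts, strictly positive linear values), so downstream code
  can assume them.
- All RNG use is scoped: functions taking a `seed` save and restore the
  caller's `.Random.seed`.

## Problem sizes used by the test suite

The suite simulates at sizes chosen to make each check sharp but cheap:
calibration round-trips at 5000 + 5000 samples (AUC standard error ≈ 0.004
against a ±0.01 assertion), the closed-form log-UDR oracle at
$10^4$ per group, planted-recovery and elimination runs at 100 seeds with
the motivating cohort sizes (35 benign / 20 early-stage) or 100 + 100, and
null-calibration batches of 50–1000 features. One published-scale check is
read carefully: a *single* null marker's AUC at 200 + 200 samples has
standard error ≈ 0.029, so a ±0.02 assertion can only bind the *mean* AUC
over a batch of null markers (50 here, SE ≈ 0.004); the test states this.

## Known limitations

- The exact NB test approximates group sums as negative binomial under
  unequal within-group library sizes (moment matching); edgeR-style
  quantile adjustment would be needed for bit-level comparability.
- Backward search is greedy; with strongly correlated members it can miss
  the optimal subset (the exhaustive route is preferred up to 4096 panels).
- `validate_candidates` filters on raw p-values by design (the cascade is a
  screening procedure, not a confirmatory analysis); Benjamini–Hochberg is
  available via `adjust_p = TRUE` but off by default.
- No cross-validation or train/test machinery: discovery and validation
  cohorts are evaluated separately, mirroring the workflow the package
  implements, and panel AUCs evaluated on the cohort that selected them are
  optimistically biased — an inherent property of the workflow, not a bug
  in the implementation.
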