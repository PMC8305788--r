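---
title: "Methods: prognosis-conditioned dependency networks and network-based drug screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prognosis-conditioned dependency networks and network-based drug screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

This vignette is the package's own account of the models it implements,
the tunable parameters, the numerical decisions taken where the design was
genuinely open, and what the synthetic benchmark does and does not show
about real data.

## Cohort model and binarization

The pipeline starts from a genes-by-samples expression table (FPKM-like,
nonnegative), a clinical table (survival days, vital status, ER/PR/HER2
receptor status, administered drugs), and a healthy-control expression
table.

**Expression** is binarized per gene at its median across all samples.
The split rule is *strictly greater than the median maps to 1*; values
exactly at the median map to 0. The strict rule is one of two defensible
readings of a "higher or lower than the median" split and is kept as the
deterministic default; `binarize_expression(ties = "weak")` flips the
at-median assignment for sensitivity analysis. With all-distinct values
the strict rule puts exactly `floor(S/2)` samples in the high class.

**Prognosis** is binarized at a survival horizon: death within the horizon
is high-risk (1), survival past the horizon — dead or alive — is low-risk
(0). The presets pair the horizons with the damping constants used
downstream: `bc` (1825 days, d = 0.85), `ov` (1200 days, d = 0.30),
`gbm` (400 days, d = 0.30). Patients censored alive before the horizon
carry no usable label; they are excluded from network construction but
retained in the clinical table for downstream survival evaluation. This
treats early censoring the same as missing survival, the only exclusion
rule stated for the original cohorts.

**Subtypes** follow the receptor-status rule: luminal A (ER+, PR±,
HER2−), luminal B (ER+, PR±, HER2+), HER2+ (ER−, PR−, HER2+), TNBC (ER−,
PR−, HER2−). PR is ignored for the luminal classes but required negative
for HER2+/TNBC, exactly as the rule is printed; every other pattern
(missing markers, ER− PR+) is `Unclassified` and drops out of subtype
screens.

## The dependency network

For binary vectors the plug-in conditional mutual information, in bits,
is

$$\widehat{\mathrm{CMI}}(A;P\mid B) \;=\; \sum_{a,p,b}
\frac{n(a,p,b)}{N}\,\log_2\!\frac{n(a,p,b)\,n(b)}{n(a,b)\,n(p,b)},$$

with empty cells contributing nothing and the estimate clamped at zero.
The quantity asks: once gene B's state is known, how informative is gene
A about the prognostic label P? An edge A → B (stored as `source`,
`target`, meaning "A's prognostic information depends on B") is retained
when the pair's CMI is significant against an **empirical null**: CMI
values of ordered gene pairs drawn uniformly at random with replacement
(`cmi_null()`, default 10,000 draws at this package's desk scale; the
full-scale analysis the method derives from used a million). Significance
is a one-sided z-test on that null's mean and standard deviation with
threshold p < 1e-5.

Three decisions here were genuinely open:

* **How the null draws map to pairs.** Whether the original million null
  values reused pairs or permuted the risk label is not documented.
  `cmi_null()` samples ordered pairs with replacement by default and
  offers `permute_risk = TRUE`; neither option is claimed to be the
  original behaviour.
* **The z-test is anticonservative.** Under independence the scaled CMI
  estimate is approximately chi-squared with 2 degrees of freedom — right
  skewed — so a normal tail on its mean and standard deviation calls
  roughly 0.5% of independent pairs at nominal p < 1e-5 (and about 1.7%
  at p < 1e-3). The z-test is retained because it is the method's defined
  behaviour, and the property tests assert the empirically correct
  calibration bounds rather than the nominal ones. On cohorts that
  actually contain dependency signal, the random-pair null is itself
  contaminated by the dependent pairs, which widens the null and raises
  the effective calling threshold — in practice this suppresses the
  false calls (the planted-edge benchmark below recovers all planted
  edges with no false positives). A `method = "permutation"` escape
  hatch scores edges by the empirical tail proportion instead.
* **Node universe.** `build_network()` keeps *every scanned gene* as a
  node, including genes with no significant edge. The ranking stage then
  operates over the full gene universe (isolated genes settle at
  `(1 − d) f_j`), which matches the scale of the original networks
  (~19,000 genes, i.e., essentially the whole transcriptome) and keeps
  drug-target enrichment well-defined for targets outside the connected
  part.

Cost is O(G²·S) for the all-pairs scan; the implementation vectorizes
over sources for each conditioning gene, and a 60-gene, 200-sample scan
runs in well under a second.

## Directed GeneRank

Gene scores iterate

$$r_j^{(n)} = (1-d)\,f_j + d \sum_i \frac{w_{ij}\, r_i^{(n-1)}}{\deg_i},
\qquad r^{(0)} = f,$$

stopping when the one-norm of the change falls below `eps` (default
1e-5; the worked examples and oracle tests use 1e-12). Interpretation:
each gene passes its current importance, split equally, to the genes it
depends on — importance accumulates on genes that many prognosis-relevant
genes depend on.

* **The degree convention.** The defining text of the modified algorithm
  calls `deg_i` both "row sum of the w actually used" and "how many nodes
  depend on i", which conflict. The default (`degree_mode = "out"`) takes
  deg_i = Σ_j w_ij — the row sum of the adjacency actually used — which
  makes each column of the propagation operator sum to at most one, so
  the iteration is a contraction with factor d and convergence for d < 1
  is guaranteed. `degree_mode = "in"` flips the reading for sensitivity
  analysis; no claim is made about the original authors' intent.
* **Damping.** `(1 − d)` weights the prior; d = 0.85 in the
  breast-cancer preset (the classic PageRank value) and d = 0.30 in the
  ovarian/glioblastoma presets.
* **Initial vector.** r⁰ = f by default (the defining recurrence is
  silent); `init = "uniform"` is available. Since the iteration is a
  contraction the fixed point is unique and the choice affects only the
  iteration count.
* **Prior normalization.** f enters as-is (absolute fold-change). The
  original undirected formulation max-normalizes the prior;
  `normalize_f = TRUE` restores that, off by default. Normalization
  rescales all scores equally and leaves ranks unchanged.
* **Dangling nodes** (deg = 0) emit nothing — there is no uniform
  teleportation term, matching the literal recurrence. Scores therefore
  need no renormalization and stay nonnegative for nonnegative f.
* `max_iter` defaults to 1000; hitting it flags `converged = FALSE` in
  `glance()` rather than failing.

The per-patient prior is $f_j = |\log_2\frac{x_j + pc}{\bar c_j + pc}|$
against the mean control profile, with pseudocount `pc = 1` (FPKM-scale
data; guards zeros). Whether the original fold-change was a linear or a
log ratio is not stated; the log form is the default because it treats
up- and down-regulation symmetrically, and `method = "ratio"` provides
the linear variant. `top_fraction(ranked, 0.05)` reproduces the "top 5%"
selection (948 of 18,960 genes at full scale).

## Drug scoring and evaluation

**KS enrichment.** `ks_enrichment()` compares target versus non-target
rank positions with the one-sided two-sample statistic
$D^+=\sup_x[F_{\text{targets}}(x)-F_{\text{others}}(x)]$ and the
asymptotic tail $p = \exp(-2 (D^+)^2 mn/(m+n))$. The one-sided
*two-sample* form on rank positions is the standard target-set enrichment
reading of an otherwise underspecified "Kolmogorov–Smirnov test"; the
statistic agrees with `stats::ks.test(..., alternative = "greater")`
(cross-checked in the tests). The suitability threshold `alpha = 0.05` is
the conventional default; the original per-patient threshold is not
printed anywhere.

**Treatment split.** A patient's treatment effect is the *minimum* KS p
over administered drugs; patients below the cohort median form the
properly treated group. `survival_compare()` reports the log-rank p
(via `survival::survdiff`) and the hazard ratio of improperly versus
properly treated with its 95% CI from a univariate Cox fit
(`survival::coxph`); the original estimator behind the reported hazard
ratios is not named, and partial likelihood is the standard choice.

**Subtype screen.** Per drug and subtype, a one-sided exact binomial
upper tail $P(X \ge k \mid n, p_0)$ with $p_0$ the cohort-wide effective
rate (`stats::pbinom`). No multiple-testing correction is applied, matching
the source tables; a Benjamini–Hochberg column can be added by the caller
with `p.adjust`.

**Consistency rule.** A predicted-versus-clinical record is consistent
iff the predicted and trial subtype sets overlap and the combination was
efficacious, or they are disjoint and it was non-efficacious. The rule is
an inference — no formal definition accompanies the published tally —
but it reproduces all 14 packaged classifications (11 consistent, 78.6%).

## Median-effect synergy analysis

`median_effect_fit()` least-squares fits
$\log_{10}\frac{fa}{1-fa} = m(\log_{10} D - \log_{10} D_m)$, reporting
Dm (median-effect dose), m (sigmoidicity), and the plot correlation r.
Log base 10 is fixed for reproducible r values (the base cancels in Dm
and m). Points with fa exactly 0 or 1 have no logit and are excluded
with a count — the handling of such points in the original tables is
unknown. `dose_for_effect()` inverts the curve;
`combination_index()` implements the classic mutually exclusive CI
$D_1/D_{x1} + D_2/D_{x2}$ (the nonexclusive cross-term variant sits
behind `exclusive = FALSE`) and the dose-reduction indices
$DRI_i = D_{xi}/D_i$. `ci_fa_table()` scores a measured fixed-ratio
mixture point-by-point, keeping undefined rows flagged rather than
dropping them.

The published CI tables for the four validated combinations were
produced by CompuSyn from full dose–response data that is not published;
this package reproduces the method, not those exact numbers, and the
packaged IC50 table is the only measured synergy input shipped.

## The synthetic benchmark

`simulate_cohort()` generates the study conditions every end-to-end test
runs under. Defaults: 60 genes, 200 tumour and 30 control samples, 3
planted dependency pairs (6 ordered edges) at strength 0.9, subtype mix
373:99:37:116 (the composition of the reference breast-cancer cohort),
4-subtype driver modules of 5 genes shifted 4-fold, 12 drugs (4
effective, one per subtype, 5 targets each), horizon 1825 days, log-normal
background noise (sdlog 0.4). These sizes keep the full pipeline — scan,
null, ranking, drug screen — under a minute on one core while leaving
wide signal margins documented by the tests.

**Why the planted dependencies are XOR-shaped.** The chain rule gives
the identity
$I(A;P\mid B) - I(B;P\mid A) = I(A;P) - I(B;P)$:
a pair can only be *asymmetrically* dependent in the conditional sense to
the extent the two genes differ marginally. But any marginal dependence
I(A;P) > 0 makes *every* ordered pair (A, X) significant — the
conditional signal does not localize. The generator therefore plants
dependencies with zero marginals and maximal conditional signal: the risk
label agrees with gene A's state with probability (1 + strength)/2 when
gene B is high and disagrees with the same probability when B is low.
Both orientations of the pair then carry equal conditional information —
which is why planted edges come in orientation pairs and
`n_planted_edges` must be even — the marginal I(A;P) is exactly zero, and
non-planted pairs stay at the null. At the default strength the planted
CMI is ≈ 0.65 bits against a calling threshold of ≈ 0.13 bits, so
recovery is complete with no false positives.

Other generator mechanics: planted genes follow a well-separated
two-component log-normal so the median split recovers the latent state;
survival days are exponential with hazard increasing in the number of
active driver genes, truncated to the horizon side the risk label
dictates, so prognosis binarization recovers the planted label exactly;
every patient carries the same-size driver module of their subtype, which
keeps driver count from confounding the risk label; administered drugs
mix the patient's subtype-effective drug with random picks.

**What passing these tests does not show.** The generator emulates none
of: negative-binomial count noise or library-size effects, correlated
background co-expression, batch effects, realistic censoring patterns,
subtype-unbalanced driver penetrance, or drugs with partially overlapping
target sets. Success on the benchmark demonstrates correctness of the
computation and recoverability under the planted mechanism, not
performance on real cohorts.

## Numerical choices and degenerate inputs

* CMI is clamped at 0 against rounding; zero-count cells contribute 0.
* A constant risk vector aborts null construction ("degenerate null").
* Tie-breaks: gene ranking is descending score, then lexicographic id;
  drug ordering is ascending p, then drug id; both deterministic.
* The treatment split uses *strictly below* the median; all-equal
  effects yield an empty properly treated group and a warning.
* `split_treated_groups` / `survival_compare` abort with explanatory
  messages on single-patient or zero-event groups.
* All stochastic outputs (generator, null draws, benchmarks) are pure
  functions of their seed via `withr::with_seed`.
* Problem sizes used by the shipped tests: networks up to 50 nodes for
  the GeneRank-vs-solve property (200 instances), 1000 random triples for
  the CMI oracle, the default 60 x 200 cohort for end-to-end recovery,
  and 500 patients per arm for hazard-ratio recovery.

## Known limitations

* The all-pairs scan is quadratic in genes; transcriptome-scale runs need
  the variance-based gene cap or batching (not included at desk scale).
* The normal z-test inherits the anticonservatism discussed above; use
  the permutation method when calibrated edge-level error rates matter.
* Combination target sets are plain unions; dose interactions at the
  target level are out of scope.
* Per-patient network rewiring (personalized topologies) is not
  implemented; one network serves the whole cohort.
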