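---
title: "Methods: from compost-amendment multi-omics tables to a causal skeleton"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from compost-amendment multi-omics tables to a causal skeleton}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compostsem)
```

`compostsem` chains five inference stages — univariate screening,
association-rule feature selection, covariance-structure (SEM) modeling,
causal mediation analysis, and Bayesian linear non-Gaussian acyclic model
(LiNGAM) comparison — into one reproducible analysis of a two-arm
(control vs compost) field experiment profiled across plant compartments,
soil chemistry and the soil microbiome. This vignette is the package's
account of the underlying models, their assumptions, the tunable
parameters, and the numerical decisions taken where the design was
genuinely open.

## Univariate screening

Every feature (metabolite intensity, taxon relative abundance, color
fraction) is compared between arms by a fixed cascade:

1. Shapiro–Wilk on each group; the gate is p < 0.05 *per group*. A constant
   group, where normality is undefined, is treated as failing the gate.
2. Both groups Gaussian → two-sided F test on the variances at 0.05,
   selecting the pooled-variance t test (F-test p ≥ 0.05) or the Welch
   t test.
3. Otherwise the two-sided Wilcoxon rank test for *independent* samples.
   Field designs of this kind have no pairing between arms, so the
   independent-sample rank test is the default and a paired signed-rank
   variant is exposed behind `paired = TRUE` for genuinely paired layouts.
   Tie handling and the exact-vs-normal-approximation switch follow
   `stats::wilcox.test` (exact for small tie-free samples, midranks with a
   normal approximation otherwise).

p-values are banded as **significant** (p < 0.05), **trend**
(0.05 ≤ p < 0.20, right-open) or none. The trend band exists because
per-group replication in field experiments is ~5–6; effects worth
follow-up rarely clear 0.05 there. No multiple-testing correction enters
the banding — screening mirrors per-feature reporting — but a
Benjamini–Hochberg column is emitted alongside as supplementary output.

Degenerate input rule: when *all* values in both groups are identical the
comparison carries no information and is reported as p = 1 with a
`degenerate` flag. Two groups that are each constant but different are not
degenerate — they are perfectly separated — and take the rank-test branch.

The categorical taste survey uses Pearson χ² without continuity
correction, with df = (r−1)(c−1) taken from the *declared* table
dimensions: a scored-but-unused category still belongs to the survey
design, so zero-marginal rows/columns contribute nothing to the statistic
(flagged by a warning) but are not silently dropped from df.

## Association rules

Features are discretized against the pooled median (`median_split`;
tertiles available) and each treated sample carries the item `compost`.
Rules `{compost} → {feature=level}` get exact support, confidence and
lift = confidence / support(consequent). Defaults `min_support = 0.2`,
`min_confidence = 0.5` are chosen so that a ~10–12-sample experiment can
still produce non-degenerate rules (at support 0.2 a rule must cover at
least 2–3 samples); both are configurable. Only compost-anchored rules are
mined by default because the screening question is treatment-directed;
full pairwise single-item mining is available via `antecedent = NULL`.
Feature selection keeps consequents with lift strictly above 1 (or top-k),
so independent features (lift exactly 1) are never selected.

## The SEM engine

Models are recursive path models among *observed* variables (the study's
diagrams contain no latent constructs; composite scores such as a total
amino-acid pool enter as observed columns). With coefficient matrix B and
disturbance covariance Ψ (diagonal unless covariances are declared), the
implied covariance is Σ(θ) = (I−B)⁻¹ Ψ (I−B)⁻ᵀ, and estimation minimises
the Wishart ML discrepancy

F_ML(θ) = ln|Σ(θ)| + tr(S Σ(θ)⁻¹) − ln|S| − p.

Numerical choices:

* **Optimizer**: BFGS with numerical gradients, convergence `reltol`
  1e−12 on F_ML, from a ladder of five deterministic starts — OLS-seeded
  path coefficients (for a recursive model with diagonal Ψ this start *is*
  the analytic optimum, so it normally converges immediately), a neutral
  start (B = 0, variances = diag(S)), and ± perturbations. Later starts run
  only if the incumbent fails to converge, or all five under
  `starts = "all"`; `starts = "neutral"` forces a pure optimization route,
  which the test suite uses to cross-check the minimizer against
  equation-wise OLS.
* Non-positive-definite Σ(θ) during search is repelled by a finite barrier
  rather than an error, so quasi-Newton steps can recover.
* **Standard errors** come from the inverse numerical Hessian of
  (n−1)/2 · F_ML.
* Negative disturbance-variance estimates are not constrained during the
  search but flagged (`heywood`).
* The χ² statistic uses the (n−1) Wishart convention, matching the
  dominant SEM-software convention behind the usual index formulas.

The seven-index battery: χ² and its upper-tail p; CFI and TLI against the
independence baseline (free variances, zero covariances — its discrepancy
has the closed form Σ log S_ii − ln|S|); RMSEA; SRMR with residuals
standardized by *sample* standard deviations (the residual is a data-scale
quantity, so the data's scale is the natural unit); GFI and AGFI. At
df = 0 (saturation) TLI, RMSEA and AGFI are undefined and reported as
`NA` markers, never as numbers.

## Candidate enumeration and ranking

`enumerate_candidates()` generates every DAG over the pool with the
treatment exogenous (optionally order-restricted or edge-capped); a pool of
4 variables yields 200 candidates. Pools above 6 variables are refused
without an explicit cap — exhaustive enumeration is the method, and its
combinatorics are the guard.

**Ranking rule.** How seven indices become one choice is not standardised
anywhere; the package's declared default (`parsimonious_fit`) is:

1. Screen candidates against the conventional adequacy cutoffs
   CFI ≥ 0.95, RMSEA ≤ 0.08, SRMR ≤ 0.08.
2. Among adequate candidates, prefer fewer free parameters; break ties by
   the mean of the per-index ranks (indices rounded to 3 decimals, their
   reporting precision), then lexicographic model text.
3. Non-adequate candidates follow by mean rank; saturated candidates
   (df = 0, indices undefined) after all testable ones; non-converged last.

The reason parsimony leads *within* the adequate set rather than serving
only as a tie-break: any superset of a well-fitting model also fits, and
its SRMR/GFI/χ²-p are closer to perfection *by construction* (extra
parameters absorb sampling noise), so a pure index vote systematically
selects over-parameterised models and is not selection-consistent — in
simulation from a known 4-variable structure the raw mean-rank vote
recovers the generating model essentially never, while the
parsimonious-fit rule recovers it reliably (see
`tests/testthat/test-acceptance.R`). The pure vote remains available as
`method = "mean_rank"`, as do RMSEA- and CFI-primary variants.

## Causal mediation analysis

For each treatment → mediator → outcome 2-path of the winning model the
linear models m = α₀ + a·t + ε and y = β₀ + c′·t + b·m + ε are fitted by
least squares (no treatment×mediator interaction: all variables are
continuous and the design two-arm). `n_sims` (default 1000) coefficient
vectors are drawn from the normal approximation of the sampling
distribution; per draw ACME = a·b, ADE = c′, total = ACME + ADE exactly.
Points are medians, CIs percentile 2.5/97.5 without bias correction.

Caveats encoded in the implementation:

* Degenerate regressions (constant treatment, collinear design, residual
  variance zero to machine precision — residual sd below ~1e−10 of the
  data sd) produce a `calculable = FALSE` result with a reason, not an
  exception, mirroring "ACME not calculable" reporting.
* The textbook noiseless limit (ACME → a·b) requires the *mediator* noise
  to dominate the outcome noise: if the mediator is exactly a function of
  the binary treatment, t and m are collinear in the outcome model and the
  ACME/ADE split is unidentified even though the total effect is exact.

## BayesLiNGAM

All DAGs over at most 4 variables are enumerated (3 variables → 25 DAGs,
4 → 543; the hard cap keeps full enumeration honest — larger winning models
are analysed as treatment-anchored sub-pools). Columns are standardized;
for each variable given its parents, a linear model with a free
two-component Gaussian-mixture disturbance is fitted to the MAP under
vague priors — N(0, 2) on coefficients and component means, half-normal(2)
on component sds, uniform on the weight — from five deterministic starts,
and the family's marginal likelihood is approximated by the Laplace method.
A DAG's score is the sum over its families (cached per family across
DAGs); a uniform prior over DAGs gives the posterior, and each directed
edge's marginal probability is the posterior mass of the DAGs containing
it (top 6 reported).

Two numerical refinements matter in practice:

* **Degenerate-mixture regions.** For near-Gaussian disturbances the
  mixture MAP is weakly identified (components overlap; the weight
  direction is almost flat) and the Laplace determinant there is noisy —
  enough to make the *non-identifiable* Gaussian case appear decisive in
  one arbitrary direction. Each family score is therefore the larger of
  two regional Laplace evaluations: at the unrestricted mixture MAP and at
  the Gaussian-collapsed submodel (μ₁ = μ₂, s₁ = s₂, well-conditioned).
  With Gaussian data the collapsed branch dominates in both orientations
  and the two scores tie, as they should; with genuinely non-Gaussian
  disturbances the mixture branch dominates and identifiability is
  untouched.
* **Atomic columns.** The binary treatment has a two-point distribution; an
  unfloored mixture would drive a component sd, and the density, to
  infinity. Component sds are parameterised s = 0.01 + exp(·) on the
  standardized scale.

Identifiability comes from non-Gaussianity: with uniform disturbances the
correct orientation of a strong edge wins the score comparison; with
Gaussian disturbances both orientations receive equal scores and posterior
mass splits — the method declines to orient, by design.

## The synthetic-data module

`ground_truth_sem()` + `generate_from_sem()` draw linear-SEM samples with
the treatment as a fixed, balanced 0/1 design column (population variance
1/4) and disturbances from one of four families, each standardized to unit
variance then scaled by the declared variance: Gaussian; uniform (excess
kurtosis −1.2); Laplace (+3); and a two-component Gaussian mixture (means
±1, sd 0.5, equal weights, standardized; excess kurtosis ≈ −1.29). The
mixture is the default in the presets because it is strongly non-Gaussian
yet symmetric — exactly the condition LiNGAM needs.

Presets name their variables after the field study's panels (Cmp the
compost arm; leaf amino acids/flavonoids/DPPH activity; root
phenylalanine/carotenoids/2-aminoadipate; a *Paenibacillus*-like genus and
soil amino-acid/nitrogen metabolites) with path coefficients 0.5–0.8 on
the standardized scale and unit disturbance variances: strong,
field-plausible effects that a ~12-sample screen can at least flag as
trends. Default group sizes are 6 (the November harvest had n = 6, the
February one n = 5); everything is configurable.

`generate_taxa()` draws Dirichlet compositions whose concentrations are
multiplied by per-taxon treatment multipliers in the treated arm;
`generate_carrot_image()` fills an ellipse on a white board with clipped
Gaussian noise around a mean RGB; `generate_taste_counts()` draws
multinomial rater counts per arm. All generators are pure functions of
(config, seed).

What the generators do *not* emulate — and hence what green tests do not
show about real data: no measurement error structure or batch effects in
the metabolite panels, no compositional coupling between the taxa table
and the SEM variables (the preset's genus node is a free SEM variable, not
a row-sum-constrained proportion), no sequencing depth or zero inflation,
no spatial field layout, and linear relations throughout.

## Color and microbiome quantities

A pixel is background iff min(R, G, B) ≥ 250 (white-board assumption);
the per-image "rate" of a channel is its intensity sum over the foreground
divided by the total intensity of all three channels there, so the three
fractions close to 1 and are invariant to common rescaling. The
alternative dominant-channel count mode is provided because the original
quantification is not pinned down; both are declared, neither asserted as
the original. Taxa screening retains taxa with p < 0.1 (same cascade as
metabolites, reused for consistency) and maximum relative abundance
> 0.001 — the "mean abundance" variant sits behind `filter = "mean"`.
Alpha diversity is Shannon entropy (nats) and observed-taxa counts;
tree-based metrics are out of scope.

## Problem sizes used by the test suite

The suite validates operating characteristics at sizes chosen to make the
checks sharp but cheap: Monte-Carlo implied-covariance agreement at 10⁶
draws (±0.01), chain-coefficient recovery at n = 10⁴ (±0.05),
selection-consistency over 50 datasets of n = 5000, mediation null
coverage and LiNGAM orientation over 50 seeds at n = 500–1000, and
screening calibration with 2000 null features / 500 null taxa. The
acceptance script reruns the same computations at 10–20 seeds per rate so
a full reproduction stays around a minute.

## Known limitations

* Observed variables only: no latent measurement models, mean structures,
  missing-data FIML, or ordinal SEM.
* Exhaustive enumeration caps pools at 6 variables (SEM) and 4 (LiNGAM);
  larger problems need pre-selection, which is what the association stage
  is for.
* The quasi-Bayesian mediation assumes linearity and no
  treatment–mediator interaction; no sensitivity analysis for
  sequential-ignorability violations is provided.
* Laplace approximations, not full integration, back the LiNGAM scores;
  posterior probabilities should be read as rankings, not calibrated
  probabilities.
* The screening stage reports unadjusted per-feature p-values by design;
  the BH column is supplementary.
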