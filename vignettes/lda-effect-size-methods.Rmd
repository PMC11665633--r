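---
title: "LDA effect-size biomarker discovery: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LDA effect-size biomarker discovery: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldamarker)
```

## The problem and the method

Microbiome differential-abundance analysis asks which taxa (or genes,
pathways, OTUs) differ between two biological conditions, and how strongly.
The LDA effect size approach answers this in two stages: nonparametric
screening establishes *which* features differ, and a linear discriminant
analysis converts the surviving features' between-class separation into an
*effect size* on the abundance scale, so that features can be ranked by
biological magnitude rather than by p-value.

Given a feature-by-sample table of relative abundances, per-sample class
labels with exactly two levels, and optional subclass labels, the pipeline
is:

1. **Per-sample rescaling.** Every sample column is closed to a fixed total
   (default $10^6$, i.e. counts per million). Input may be proportions or
   counts; the pipeline is invariant to per-sample scale.
2. **Degenerate-feature filtering.** All-zero features, constant features,
   and exact duplicate rows are removed before any statistics are computed,
   so that (a) multiplicity corrections do not count unusable features and
   (b) the within-class scatter stays invertible without the random-noise
   injection used by older implementations. Collinear features in practice
   are those rarely or never observed.
3. **Kruskal–Wallis screen.** For each feature the tie-corrected H statistic
   across the two classes is referred to $\chi^2_1$; features with
   (optionally adjusted) $p < \alpha_{KW}$ (default 0.05) are retained.
   Constant features short-circuit to $p = 1$.
4. **Strict Wilcoxon subclass screen.** When subclass labels exist, every
   pairing of a subclass stratum in the reference class with a stratum in
   the other class is tested by the standardized rank-sum statistic
   $z = (W - E[W]) / \sqrt{\operatorname{Var}[W]}$ (tie-corrected variance,
   no continuity correction). A feature survives only when *every*
   comparison is significant at $\alpha_W$ (default 0.05) **and** all
   z-scores share one sign — the "strict" multiclass strategy. A feature
   with no valid stratum pair falls back to the class-level decision.
5. **Direct full-data LDA.** With $S_w$ the pooled within-class scatter of
   the surviving features and $\mu_0, \mu_1$ the class mean vectors
   (reference class is 0), the discriminant direction is
   $w \propto S_w^{-1}(\mu_1 - \mu_0)$, unit-normalized. The between-class
   gap of discriminant scores is $\Delta_{LD} = |w^\top(\mu_1 - \mu_0)|$.
6. **Effect size and score.** In the default *projection* mode the absolute
   raw effect of feature $i$ is $\Delta_{LD}\,|w_i|$; the *averaged*
   compatibility mode uses $(|\mu_{1,i}-\mu_{0,i}| + \Delta_{LD}|w_i|)/2$.
   The sign is that of $\mu_{1,i}-\mu_{0,i}$. The reported LDA score is
   $\operatorname{sign} \cdot \log_{10}|\text{effect}|$, and features with
   $|\text{score}| \ge$ `lda_threshold` (default 2.0, inclusive) are
   returned in descending score order (ties broken by feature id).

The whole path contains no random number generation: repeated runs on
identical input are byte-identical, and the pipeline neither reads nor
writes the global RNG state.

## Parameters that matter

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `kruskal_threshold` | 0.05 | probability | class-screen significance level |
| `wilcox_threshold` | 0.05 | probability | per-comparison subclass significance |
| `lda_threshold` | 2.0 | log10 scaled abundance | at the default scale, 2.0 corresponds to a raw effect of 100 per million |
| `adjust_method` | `"none"` | p.adjust family | corrections applied across features (KW) and within each feature's comparisons (Wilcoxon); `"none"` mirrors common practice, BH/holm/... available for feature-rich inputs |
| `effect_mode` | `"projection"` | — | matches the method's stated definition; `"averaged"` provided for compatibility (see below) |
| `scale_constant` | 1e6 | per-sample total | makes the threshold-2.0 ↔ effect-100 correspondence hold |

Screen comparisons use strict `<` on the (adjusted) p-value; the score
threshold uses inclusive `≥`. The reference (negative-score) class defaults
to the first class level encountered in the metadata, deterministically and
without locale-dependent sorting, and is configurable.

## The two effect-size modes

The method's verbal definition — the absolute difference between the two
classes' LDA discriminant scores, scaled by the unit-normalized
coefficients — is the projection form $\Delta_{LD}|w_i|$ and is the
default. Published implementations additionally average this with the
per-feature class-mean difference; that combination is available as
`effect_mode = "averaged"`. The difference matters: the projection form
distributes one *global* separation quantity across features by coefficient
magnitude, so features that survive screening by chance can inherit
substantial scores when LDA's whitening assigns them large coefficients;
the averaged form anchors each feature partly to its own mean difference.
Neither form guarantees that truly differential features outrank all
chance survivors by score — an intrinsic property of coefficient-based
scoring worth keeping in mind when interpreting ranked lists (and the
reason the score threshold is a magnitude filter, not an error-rate
control).

## What the synthetic generator emulates — and what it does not

`generate_synthetic()` draws i.i.d. log-normal latent abundances
(`meanlog = 0`, `sdlog = 1` by default — a realistic per-taxon dispersion
for rank-based analyses, fixed once), multiplies spiked features by
`fold_change` in their enriched class (directions alternate), injects
structural zeros at the `sparsity` rate among non-spiked features only (so
ground truth stays well-defined), and closes each sample to proportions.
Optional subclass structure splits each class evenly into strata and applies
a per-feature multiplicative stratum shift shared across classes, so the
strict screen is exercised without destroying the spiked signal.

Deliberately **not** emulated: per-feature baseline abundance heterogeneity
(real communities span orders of magnitude; under heterogeneity, absolute
effect sizes are dominated by abundant taxa regardless of fold change),
taxon–taxon correlation beyond compositional closure, sequencing-depth
variation, and count noise. A green test on this generator therefore
establishes the pipeline's statistical behavior under a clean compositional
world — it does not establish ranking performance on real communities.

Note one consequence of closure worth knowing: after per-sample rescaling
the *full* feature set is exactly collinear (rows sum to a constant), so a
discriminant fit over all features is singular by construction. The
pipeline fits LDA on the screen survivors only; fitting on all features
with post-hoc restriction was rejected for exactly this reason.

## Numerical choices

* **Scatter solve.** `solve(S_w, d, tol = 1e-10)`; if numerically singular,
  the error names the features beyond the numerical rank of $S_w$ (QR with
  the same tolerance) instead of perturbing the data with noise.
* **Score transform.** Exactly $\operatorname{sign}\cdot\log_{10}|raw|$,
  not $\log_{10}(1+|raw|)$. Raw effects of exactly 0 are excluded before
  the transform; since the default threshold excludes $|raw| < 100$, the
  $|raw| < 1$ sign pathology cannot reach reported output.
* **Asymptotic p-values.** Both screens use asymptotic references with tie
  correction, matching the stock implementations they mirror. Against an
  exact permutation enumeration over all two-group splits with total
  $n \le 10$, the tie-corrected variance formula agrees with the
  brute-force variance exactly (to 1e-10), while the worst-case absolute
  deviation of the asymptotic two-sided p-value from the exact enumeration
  p-value is large at these sizes and is documented here (measured against
  the enumeration oracle):

  | total n | untied data | heavily tied (near-binary) |
  |---|---|---|
  | 4 | 0.23 | 0.32 |
  | 6 | 0.19 | 0.54 |
  | 8 | 0.14 | 0.51 |
  | 10 | 0.11 | 0.49 |

  The suite asserts agreement within 0.24 (untied) and 0.55 (tied) at
  $n \le 10$; these are properties of the normal/χ² approximation itself,
  not implementation slack, and they shrink as n grows. With groups of
  ≥ 20 the approximation error is negligible for screening purposes.
* **Bootstrap reference estimator.** `bootstrap_lda()` reproduces, for
  comparison experiments only, the subsample-averaging strategy the direct
  fit replaces: unit coefficient vectors from 2/3-subsamples (without
  replacement, ≥ 2 samples per class, bounded retries) are sign-aligned to
  the direct fit and averaged. Averaging unit vectors shrinks the norm of
  the mean below 1 by the replicate dispersion, so convergence to the
  direct fit is assessed on the renormalized *direction*. Convergence can
  only be measured against a stable target: on well-conditioned fits
  (few features, clear effects) the direction deviation at 2000 iterations
  is ~1%, while on ill-conditioned fits the direct coefficients themselves
  are unstable — which is the phenomenon that motivates direct estimation
  in the first place.
* **Seeding.** Every stochastic operation (`generate_synthetic`,
  `bootstrap_lda`, `stability_experiment`) takes an explicit seed and runs
  in a private RNG stream that saves and restores the caller's
  `.Random.seed`; nothing in the package sets a global seed.

## Design choices where the design was open

* **Two classes exactly.** Multi-class one-against-all strategies are out
  of scope; "two or more conditions" is resolved as two classes with
  optional subclasses.
* **Cross-class stratum pairs.** The subclass screen compares every
  (stratum within reference class) × (stratum within other class) pair:
  sign consistency across class-straddling comparisons is what the strict
  strategy tests. Same-class stratum pairs are not compared.
* **Empty subclass labels are an error**, not a silent stratum: the screen
  has no semantics for unlabelled strata, and silent grouping would change
  rank statistics.
* **Missing abundance cells are an error** for the same reason — the
  method has no missing-data semantics, and silent imputation would change
  ranks.
* **LDA on survivors only** (see the closure note above).
* **Output ordering** is descending score with lexicographic tie-break:
  deterministic and matches barplot layout.

## Known limitations

* The number of features entering LDA must stay below the number of
  samples minus two; richer survivor sets make $S_w$ singular and raise a
  descriptive error. Tighten the screen thresholds or enable `adjust_method`
  for feature-rich inputs.
* A feature that perfectly separates the classes with zero within-class
  variance makes $S_w$ singular on that coordinate; such features are
  reported in the error rather than scored.
* Scores measure abundance-scale magnitude; they are not monotone in
  statistical evidence, and chance survivors of the screens can receive
  sizable scores (see the effect-mode discussion).
* The asymptotic screens are anti-conservative for groups smaller than ~5
  samples; with such designs an exact test would be preferable, but is out
  of scope.
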