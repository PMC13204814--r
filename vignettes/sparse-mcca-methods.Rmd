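---
title: "Sparse multiple CCA for multimodal brain-behavior data: models, choices, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse multiple CCA methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the model and
its assumptions, the tunable parameters and their defaults, the design
decisions that were genuinely open, what the synthetic-data generator
does and does not emulate, and the numerical details that determine edge
behavior. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The analysis problem

The pipeline targets a common multimodal design: a small cohort (the
reference layout is 24 subjects) described by three aligned variable
blocks — 19 biological variables (mean fractional anisotropy of 18 white
matter tract instances plus the EEG individual alpha peak frequency), 3
demographic variables (age, binary sex, education), and 6 behavioral
variables (mean, intra-subject SD, and skewness of reaction times in a
simple and a complex GO/NO-GO task). With 28 variables against 24
subjects, classical canonical correlation is ill-posed, so the model is
the penalized-matrix-decomposition (PMD) form of sparse multiple CCA:
maximize the summed pairwise bilinear objective
$\sum_{i<j} w_i^\top X_i^\top X_j w_j$ under per-block constraints
$\lVert w_i\rVert_2 \le 1$ and $\lVert w_i\rVert_1 \le c_i$. The
within-block metric is the identity (covariance-style cross-products, no
whitening); the reported "canonical correlation" per block pair is the
Pearson correlation of the realized score vectors $X_i w_i$, which is
what practitioners tabulate.

Assumptions worth making explicit: linear block relations; exchangeable
subjects (permutation inference depends on this and on nothing
distributional); complete cases (assembly raises a hard error on missing
values rather than imputing, since the target design analyzed a complete
sample); and standardization of every column except binary sex, whose
0/1 coding is deliberately preserved. That last convention has a
consequence users should know: an unstandardized Bernoulli column enters
the cross-products with scale $\sqrt{p(1-p)} \approx 0.5$, so its
covariance with any score is intrinsically shrunk by half relative to a
standardized variable carrying the same correlation. At n = 24 this
makes sex measurably easier to displace by a lucky noise variable than a
continuous variable with the same planted loading. We preserve the
convention (it is the field's) rather than "fixing" it, and the
stability benchmark therefore plants its demographic signal on age, so
that it measures the stability rule rather than this scale handicap.

## The solver

Each block update solves $\max_w v^\top w$ over the intersection of the
L2 ball and the L1 ball, with $v_i = \sum_{j\ne i} C_{ij} w_j$. The
solution is $w = S(v, d)/\lVert S(v, d)\rVert_2$ with soft-threshold
level $d$ found by bisection — the smallest $d \ge 0$ making
$\lVert w\rVert_1 \le c$. Bisection runs to machine-level interval width
(200 halvings cap) and falls back to the one-hot maximizer in the
measure-zero case of exact ties at the maximum. Since every update is an
exact argmax, the objective is non-decreasing across sweeps; sweeps are
cyclic in the declared block order (biological, demographic, behavioral)
and stop when the maximum elementwise weight change drops below `tol`
(default 1e-6) or after `maxIter` sweeps (default 25, the reference
magnitude for this family of solvers; the oracle-equivalence checks use
much tighter settings, which the arguments expose).

**Initialization.** The objective is non-convex, and single-start
coordinate ascent can converge to a non-global fixed point — visibly so
at extreme sparsity, where the iteration lives on the one-hot lattice.
The default initialization is therefore deterministic and multi-start:
the leading right singular vector of each block (sign-fixed), plus
`extraStarts` one-hot starts per non-leading block at its strongest
coordinates, ranked by combined squared cross-covariance; the solution
with the highest objective is kept. For two blocks at $c = 1$ the
one-hot starts cover every column basin, which is why the solver
provably agrees with exhaustive search there. The cost is a few extra
cheap ascents per dimension.

**Dimensions.** Successive dimensions deflate every pair,
$C_{ij} \leftarrow C_{ij} - (w_i^\top C_{ij} w_j) w_i w_j^\top$. The
number of dimensions is a user decision; the package reports the
cumulative average squared pairwise correlation and the stability
indices as retention evidence, and deliberately has no automatic
stopping rule. Canonical signs are indeterminate, so a fixed convention
is applied per dimension: exhaustive sign flips (block 1 fixed positive)
maximizing the sum of pairwise score correlations, then a global flip
making the largest-magnitude weight of block 1 positive. Penalties are
held fixed across dimensions, matching the reference analysis in which
the tuned budgets were identical in both dimensions.

## Penalty tuning

The per-block budgets $c_i \in [1, \sqrt{p_i}]$ control support size
(roughly $c^2$ effective nonzeros). `tunePenalties()` scores each
candidate by $z = (t_{\mathrm{obs}} - \bar t_{\mathrm{null}})/
s_{\mathrm{null}}$, where $t = \sum_{i<j} \operatorname{atanh}(r_{ij})$
on dimension 1 and the null comes from independently row-permuting every
block (default 1000 permutations; Fisher's transform stabilizes the
variance of the summed correlations). Ties break toward the smallest
budgets, an interpretability preference. The default grid is 8 geometric
values per block spanning $[1, \sqrt{p}]$ combined by aligned index; a
full Cartesian product sits behind a flag because the aligned grid is
what keeps tuning desk-scale. Tuning maximizes evidence of cross-block
covariance — not support recovery; the recovery benchmarks therefore fix
penalties at the planted sparsity level instead of tuning per replicate.

## Permutation inference

All tests share one engine: refit the full configuration on B datasets
whose blocks are independently row-shuffled, recording pairwise score
correlations and weights per permutation. Empirical p-values use the
add-one convention $p = (1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$,
never exactly zero. Correlations are compared by absolute value
(two-sided; canonical sign is meaningless), with Bonferroni correction
across the three block pairs ($0.05/3 \approx 0.017$).

Per-variable weights use the max-z (maxT) familywise correction:
$z_v = |w_{\mathrm{obs},v}|/s_{\mathrm{null},v}$ compared with the
permutation distribution of the familywise maximum, family = block per
dimension. Two design points deserve record:

* **Sign handling of null weights.** Aligning each permuted fit's signs
  to the observed solution looks natural but conditions the null spread
  on the observed weights — variables with large observed weights get
  their null sd preferentially shrunk — and in null simulations this
  inflated the familywise error several-fold. Null weights therefore
  keep the solver's canonical sign convention, which is a deterministic
  function of each fit alone; exchangeability is preserved and the
  measured familywise error sits at its nominal level.
* **A calibrated but conservative screen.** Under the null, a sparse
  unit-norm fit always concentrates weight ~0.5–0.9 on a few variables,
  and rarely-selected variables have tiny null sd, so the null
  familywise maximum of $z$ is heavy-tailed and stochastically
  comparable to any signal-weight $z$ attainable at n = 24. The
  corrected test controls familywise error well but has little power to
  flag individual variables at desk scale; planted variables do attain
  systematically larger $z$ than noise variables (tested), and support
  claims at this sample size should lean on the stability analysis. The
  variable with sd-null zero gets $z = \infty$ if its observed weight is
  nonzero, else 0 — a documented edge rule.

Penalties are tuned once and reused, not re-tuned, inside permutation
loops: the test evaluates the fitted configuration, and re-tuning per
permutation would mix tuning variability into the fit null.

## Leave-one-out stability

Each of the n refits drops one subject and re-standardizes the reduced
sample from scratch, so the held-out subject contributes nothing to the
fold's centers and scales (no leakage); penalties stay fixed (re-tuning
per fold would conflate tuning and fit stability). The inclusion
fraction of a variable is the share of folds with a nonzero weight
(magnitude above 1e-10); classification uses the dual thresholds:
stable-nonzero above 0.75, stable-zero below 0.25, unstable between.
Both thresholds are arguments, and the stricter 0.15 variant sometimes
used to reject a further dimension is obtainable by setting them — the
package reports, it does not auto-stop. The per-dimension mean loading
correlation averages, over folds, the Pearson correlation between the
concatenated fold weights (per-block sign-aligned to the full fit, since
fold signs may flip) and the full-fit weights.

## Behavioral features

Trial logs (subject, task, trial, GO flag, response flag, RT) reduce to
per-subject moments over correct GO responses inside a response window.
The window defaults to 100–1000 ms — the stimulus was on for 500 ms with
a 500 ms blank, and no explicit cutoff is published, so both ends are
arguments; 100 ms is a conventional anticipation cutoff. Skewness is the
bias-adjusted Fisher–Pearson $G_1 = \sqrt{n(n-1)}/(n-2)\cdot
m_3/m_2^{3/2}$, the definition mainstream statistics software uses at
these sample sizes; a constant sample returns skewness 0 with a
degenerate flag, and fewer than three usable responses is an error
because skewness is undefined. Commission errors are responses on NO-GO
trials, omissions are missed GO trials, and the 2×2 error-contingency
test is the Pearson chi-square with df = 1 (Yates correction off by
default, exposed as a flag, because the published statistic for this
comparison cannot be reproduced from the published totals under either
convention — the suite checks our implementation against a direct
$\sum(O-E)^2/E$ oracle instead).

## The synthetic-data generator

The generator emulates the study conditions so that every downstream
stage is testable without the restricted data: 24 subjects by default,
500 trials per task, 25% GO stimuli in the complex task (the simple
task's GO fraction is unpublished; the default mirrors 0.25 and is an
argument), sex Bernoulli(10/24) as 0/1, commission rate 0.5% and
omission rate 1.7% back-derived from the published error means. RTs are
ex-Gaussian — normal(mu, sigma) plus exponential(tau) — because that
family reproduces the published positive skewness (about 1.1 simple, 1.4
complex) with a controllable third moment; the per-task defaults are
obtained by moment inversion of the published per-subject summaries
(e.g., complex: mu ≈ 357, sigma ≈ 39, tau ≈ 76 ms).

Cross-block structure is planted through latent factors: dimension d has
$f_d = \lambda_d \tilde s + \sigma_d g_d$, where $\tilde s$ is
standardized sex (this is how a loading on a binary column is realized —
a factor mean shift by group), and each continuous variable adds
$\beta_{vd} f_d$ before independent Gaussian noise. Two latent
dimensions loading on both sex make the factors correlated — a faithful
property of the emulated pattern, and the reason perfect support
separation is unattainable even in population in the full emulation.
Generated columns are affinely rescaled so sample mean and sd match the
published marginal table exactly (correlations are unchanged by this);
the education marginal is a synthetic default (years, mean 14, sd 3)
because none is published. Behavioral summaries can be planted directly
at the block level (exact control of effect sizes) or pushed through
trial simulation: per-subject target moments are inverted to ex-Gaussian
parameters (feasible skewness clamped to (0.05, 1.9)), trials simulated,
then re-summarized — this path exercises the behavioral-features module
end to end. Everything is deterministic given the seed, with independent
substreams per (subject, task) and per pipeline stage, so stages can be
re-run in isolation.

What the generator does **not** emulate: measurement error structure of
tractography (spatially correlated FA noise, crossing-fiber bias),
non-Gaussian marginals beyond the affine match, task-order effects,
heteroscedastic RT noise across subjects, or any nonlinearity. Passing
tests on this generator therefore demonstrate correctness of the
machinery and behavior under an idealized linear factor model — not
robustness to those real-data features.

## Validation design and problem sizes

The suite and `scripts/acceptance.R` compute, among others: solver
agreement with the dense SVD oracle (100 random two-block instances) and
with exhaustive one-hot search at $c=1$ (20 tiny instances);
L1-projection agreement with an iterated dense grid search (1000 random
vectors); permutation-test calibration on 200 global-null study-layout
datasets at B = 200 with the reference budgets (3.15, 1.25, 1.77);
two-dimension support recovery over 50 replicates at n = 200 (and its
degradation at n = 24 — small-sample instability is expected and is
reported, not hidden) with benchmark budgets (2.3, 1, √2) fixed at the
planted sparsity level; the stability dual-threshold rule over 50
study-scale replicates with one strong planted dimension (loadings 0.8,
noise sd 0.5); ex-Gaussian moment recovery from 50,000 trials; and
byte-identical pipeline determinism. These sizes are the package's
validation choices: large enough for the binomial error of a rate
estimate over 200 replicates (~±0.015) to resolve the calibration bands,
small enough to run routinely.

## Known limitations

* Per-variable max-z inference is calibrated but conservative at n = 24
  (see above); stability selection is the workhorse for support claims.
* The aligned-index tuning grid cannot represent penalty combinations
  off its diagonal; use `cartesian = TRUE` when blocks need genuinely
  independent budgets.
* Deflation does not enforce score orthogonality across dimensions;
  correlated planted factors yield partially mixed supports by design.
* The binary sex convention (unstandardized) halves that column's
  effective covariance scale; comparisons of its weight against
  standardized columns' weights inherit that asymmetry.
* Complete cases only; no imputation, winsorization, or covariate
  residualization.
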