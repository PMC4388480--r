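---
title: "Co-orientational order: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-orientational order: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coorient)
```

## The model

All orientations handled by this package are axial: a measurement θ and
θ + π describe the same structure. A single construct K (a set of
pseudo-vectors $k_i = (\cos\theta_i, \sin\theta_i)$) is summarized by its
mean order tensor and orientational order parameter (OOP)

$$\mathbb{T}_K = 2\,\langle k k^{T} \rangle - \mathbb{I}, \qquad
\mathrm{OOP}_K = \max \mathrm{eig}(\mathbb{T}_K),$$

which is 0 for an isotropic field and 1 for a perfectly aligned one. In
double-angle form the independent tensor entries are simply
$t_{xx} = \langle\cos 2\theta\rangle$ and
$t_{xy} = \langle\sin 2\theta\rangle$, and for a traceless symmetric 2×2
matrix the spectrum is closed form:
$\lambda_{\max} = \sqrt{t_{xx}^2 + t_{xy}^2}$ with the director at angle
$\tfrac{1}{2}\,\mathrm{atan2}(t_{xy}, t_{xx})$. The package evaluates the
tensor exclusively through these identities — no iterative eigensolver, no
solver nondeterminism, and exact pseudo-vector symmetry since
$\cos 2(\theta+\pi) = \cos 2\theta$.

For two index-paired constructs P and Q the relative-angle field

$$f_i = (p_i \cdot q_i,\; |p_i \times q_i|)
      = (\cos(\beta_i - \alpha_i),\; \sin(\beta_i - \alpha_i))$$

is itself a field of unit vectors, and the co-orientational order
parameter (COOP) is the maximal eigenvalue of *its* mean order tensor. It
measures only the consistency of the relative angle: rotating either field
by a constant, flipping any subset of pseudo-vectors by π, or swapping P
and Q leaves it unchanged (these invariances are enforced by randomized
property tests at tolerance 1e-12). A field compared with itself gives
COOP = 1 identically, since every $f_i = (1, 0)$.

### Bounds, normalization, regimes

Two analytic arrangements anchor the interpretation:

* independent constructs give
  $\mathrm{COOP}_u = \mathrm{OOP}_P \cdot \mathrm{OOP}_Q$;
* "one construct equals the other plus independent random noise" gives
  $\mathrm{COOP}_c = \min(\mathrm{OOP}) / \max(\mathrm{OOP})$.

Neither is a hard extreme. A spatially structured mixture of correlation
modes (half the tissue parallel, half perpendicular) drives the COOP to 0
while $\mathrm{COOP}_u > 0$ — the anti-correlated regime,
`gen_anticorrelated_pair()`. A rank-matched (sorted) pairing drives the
COOP above $\mathrm{COOP}_c$ — the ultra-correlated regime,
`gen_ultracorrelated_pair()`. The normalized COOP
$(\mathrm{COOP} - \mathrm{COOP}_u)/(\mathrm{COOP}_c - \mathrm{COOP}_u)$
maps the regimes to $<0$, $0$, $1$, $>1$.

Corner conventions follow the framework's stated range behavior:
`coop_correlated(0, 0)` is 1 (the normal range is the whole of $[0,1]$)
while `coop_correlated(x, 0)` with $x>0$ is 0 (the normal range does not
exist). When $\mathrm{COOP}_c - \mathrm{COOP}_u < 10^{-9}$ the
normalization is reported as `NA` with regime `"degenerate"`: a vanished
normal range is a property of the inputs, and silently returning ±Inf
would propagate into downstream averages. Regime classification compares
against the bounds at a fixed tolerance of 1e-6; the framework defines
regimes only by position relative to the bounds, so some tolerance is
unavoidable, and an ultra-correlated flag is advisory — a COOP
significantly above $\mathrm{COOP}_c$ means the parameter's assumptions
deserve re-examination, not that a stronger kind of correlation was
certified.

### The mean inter-construct angle

The director of the relative-angle tensor determines θ₀ only up to the
four-fold ambiguity $\{\theta_0, -\theta_0, \pi-\theta_0, \theta_0-\pi\}$.
`director_to_angle()` resolves it with a branch rule driven by a reference
director (the director itself, or the director-of-directors when averaging
across samples): references within π/4 of the vertical use the arccos
branch and report in $[0, \pi)$; otherwise the arcsin branch reports in
$[-\pi/2, \pi/2]$. Centering the reporting range on the reference is what
makes multi-sample averaging wrap-safe: directors at −5°, 0°, +5° average
to 0°, never through 90°. We read the branch rule as acting on the
director's x component (arccos) and y component (arcsin); the reference
convention does not fix this unambiguously and this reading is our
interpretation. The reported angle is counter-clockwise from P to Q under
mathematical axes (y up); under raster-image axes (y down) the identical
number is the clockwise angle, which is the convention used when
discussing stained-image results.

`multi_sample_angle_stats()` refuses nothing but warns below an overall
director order of 0.2 (default): when the per-sample COOP directors are
nearly isotropic the branch choice, and hence the mean angle, is
arbitrary.

## Error propagation and power analysis

Treating the two OOP estimates as independent and normal with a common
standard deviation σ_OOP, the delta method gives

$$\sigma_{\mathrm{COOP}_u} = \sqrt{\mathrm{OOP}_Q^2\sigma_P^2
  + \mathrm{OOP}_P^2\sigma_Q^2},$$

and for the correlated bound (branch with the larger OOP in the
denominator, here $\mathrm{OOP}_P > \mathrm{OOP}_Q$)

$$\sigma_{\mathrm{COOP}_c} = \sqrt{
  \left(\tfrac{\mathrm{OOP}_Q}{\mathrm{OOP}_P^2}\right)^2 \sigma_P^2 +
  \left(\tfrac{1}{\mathrm{OOP}_P}\right)^2 \sigma_Q^2}.$$

The derivative has a kink at equal OOPs; both branches coincide there and
that common value is used. Both formulas are tested against central-
difference numeric differentiation on random points.

`bound_separation_test()` asks whether a study could tell the two bounds
apart: a two-sample t statistic for $H_0: \mathrm{COOP}_u =
\mathrm{COOP}_c$ with per-group size N and the propagated standard
deviations. The test flavor was a genuinely open choice — "two sample
t-test" admits pooled or Welch variance. We use **Welch with Satterthwaite
degrees of freedom**: the two groups have structurally different
variances (the correlated bound amplifies error by $1/\mathrm{OOP}$), a
pooled variance is therefore inappropriate on statistical grounds, and
numerically the Welch form reproduces the reference operating point (a
maximum tolerable error of 0.18 at $\mathrm{OOP}_P = \mathrm{OOP}_Q =
0.60$, N = 4, α = 0.05) where the pooled form gives ≈ 0.21. The test
suite pins this against `stats::t.test` on samples constructed to have
exactly the propagated moments.

`max_tolerable_error()` inverts the test by bisection on σ_OOP over
$[10^{-6}, 2]$ to absolute tolerance 1e-4 (the p-value is monotone in σ).
`min_sample_size()` inverts it over N by doubling to bracket the smallest
significant size followed by integer bisection — equivalent to a linear
scan with early exit but vectorizable over a whole OOP grid — with a cap
of 10⁶ before reporting `Inf` (coinciding bounds genuinely require an
infinite sample). Cells where both OOPs are exactly 0 have no defined
correlated-bound error and return `NA`. `power_surface()` tabulates both
quantities over a square OOP grid; at the default 0.01 spacing the full
surface takes seconds because the bisections run vectorized over all
cells at once.

One caveat worth recording: because the bisection returns the *largest σ
that still rejects*, the exact operating point is σ* ≈ 0.1795 (printed as
0.18 at two decimals). At the literal value 0.18 the Welch p-value at
N = 4 is marginally above 0.05, so the round-trip identity
`min_sample_size(oop_p, oop_q, max_tolerable_error(...)) = n` holds with
the bisection value, not with its two-decimal rounding.

## Synthetic generators: what they emulate

The generators are first-class, tested code reproducing each validation
regime:

| generator | regime | expected COOP |
|---|---|---|
| `gen_aligned()` + rotation | both perfectly organized | 1 exactly |
| `gen_aligned()` vs `gen_isotropic()` | order vs disorder | 0 |
| two `gen_isotropic()` draws | independent isotropic | 0 |
| `gen_isotropic()` + constant | correlated isotropic | 1 exactly |
| `gen_uncorrelated_pair()` | independent, mid-range OOPs | $\mathrm{OOP}_P\mathrm{OOP}_Q$ |
| `gen_correlated_pair()` | noise-coupled | $\min/\max$ |
| `gen_anticorrelated_pair()` | two-mode mixture | 0, below $\mathrm{COOP}_u$ |
| `gen_ultracorrelated_pair()` | sorted pairing | above $\mathrm{COOP}_c$ |

Choices where the framework left a gap:

* **Truncation interval.** Truncated Gaussians are truncated to
  mean ± π/2 by default — exactly one axial period, so any σ yields a
  proper axial density — and truncated *before* wrapping into $[0, \pi)$.
  With the default center π/2 no wrapping occurs at all, which is what
  lets the tests Kolmogorov–Smirnov-check the sample against the plain
  truncated-normal CDF. Sampling is inverse-CDF, so a draw of size n
  consumes exactly n uniforms and is reproducible across platforms with
  the same RNG.
* **Noise calibration.** For `gen_correlated_pair()` the target is an
  *empirical* OOP for Q. Because the order parameter of a sum of
  independent symmetric axial variables factorizes
  ($\mathrm{OOP}_{P+\eta} = \mathrm{OOP}_P \cdot \mathrm{OOP}_\eta$), the
  noise width is found by bisection on the empirical OOP of the noise
  alone against $\mathrm{OOP}_{target}/\mathrm{OOP}_P$ — 20 iterations on
  a fixed-seed calibration sample of 10⁵ draws. Closed-form deconvolution
  of truncated Gaussians is not available; the empirical route is, and the
  tests verify the achieved OOP lands within 0.01 of target. A target
  above P's own order is infeasible and errors.
* **Determinism.** Every generator takes a seed and restores the caller's
  RNG state, so identical spec + seed is bit-identical and surrounding
  code is unaffected.

What passing these tests does *not* show: real micrographs have spatially
correlated noise, out-of-focus offsets between channels, segmentation
artifacts and uneven construct density. The generators draw i.i.d. angles
(optionally with coordinates) and so validate the estimator's mathematics,
not the upstream imaging chain. Per-pixel angle extraction is consumed,
never performed, here.

## The grid pipeline

Image-scale comparisons average per-pixel directions within grid squares
before comparing constructs, which suppresses small channel offsets and
pixel-level detection error. Defaults and conventions:

* **Square size 30 px** (≈ 4.2 µm at the design imaging scale — about two
  sarcomere complexes, so each square contains at least one natural
  biological unit). Squares are half-open $[ks, (k+1)s)$ in both axes,
  indexed over the full image extent, origin configurable but never
  searched: grid-to-structure alignment cannot be controlled in practice,
  so no alignment optimization is attempted.
* **Partial edge squares are retained** with density computed against the
  clipped area, so they are down-weighted smoothly rather than dropped.
* **Per-square representative** is the tensor director (not a circular
  mean), keeping the pseudo-vector symmetry of the framework at every
  level; empty squares carry an `NA` director and zero density — never a
  silent 0 angle.
* **Weights** $W_i = \mathrm{OOP}_{P,i}\,\mathrm{OOP}_{Q,i}\,
  \rho_{P,i}\,\rho_{Q,i}$ with $\rho$ the per-square angle count divided
  by the (clipped) square area. A square missing either construct gets
  $W_i = 0$ and is provably inert: removing it changes no output.
* **How weights enter the COOP**: the framework defines the weights but
  not the weighted estimator. We form the relative-angle mean tensor as
  the $W$-normalized weighted average over squares — the only averaging
  step available — which reduces to the unweighted estimator for equal
  weights and reproduces the pixel-level COOP exactly in the
  one-pixel-per-square limit (both are asserted in tests). Published
  grid-level values could conceivably have used a weight *threshold*
  instead; with our reading, thresholding is the special case of setting
  small weights to zero, and a sensitivity check is a one-liner on the
  `weight` column.
* **Coordinates** are 0-based with raster orientation (x right, y down);
  the θ₀ sign convention above makes "clockwise from P to Q" unambiguous
  under that choice.

`consistency_matrix()` applies the weighted COOP pairwise across
co-registered samples of one construct; the diagonal is 1 by the
self-comparison theorem and the matrix symmetric by the P/Q swap symmetry
— both are structural test assertions, as the published per-cell values
require the original micrographs.

## Validation scales and numerical tolerances

The test suite asserts analytic identities at 1e-10 to 1e-12 and
sampling-based convergence at $3/\sqrt{n}$, reflecting the
$O(n^{-1/2})$ error of tensor-moment estimators. Problem sizes were
chosen so the full suite runs in about a minute on one core: limiting
cases at n = 10⁶, bound-tracking across 50 random truncated-Gaussian
pairs at n = 10⁵, 1000-case randomized symmetry suites, the full
0.01-spaced power surface, and a 60 000-pixel grid-level recovery of the
correlated bound on a 20 × 20-square grid. Larger n only tightens the
stochastic tolerances.

## Known limitations

* The COOP is a first-order parameter: it cannot capture second-order or
  spatially resolved correlation structure (the anti-correlated
  construction is precisely a case it summarizes as 0).
* θ₀ is meaningless as the COOP approaches 0, and multi-sample angle
  averaging degrades with it (hence the instability warning).
* Bounds involving $\min/\max$ of OOPs are noisy when both OOPs are
  small; the power analysis quantifies exactly when that matters.
* The pipeline trusts its input angles; no masking, registration or
  detection quality control is performed downstream of the files it
  reads (masked pixels are represented by omission).
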