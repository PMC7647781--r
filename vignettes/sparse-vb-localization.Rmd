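---
title: "Sparse variational-Bayes source localization: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse variational-Bayes source localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbsource)
```

## The inverse problem

EEG source localization estimates the amplitudes of a grid of current
dipoles from scalp potentials. With a lead field matrix
$H \in \mathbb{R}^{N \times K}$ (one column per dipole in fixed-orientation
mode, three Cartesian columns per dipole in free mode, so $K = M$ or $3M$),
the instantaneous observation model is

$$ y = Hx + e, \qquad e \sim \mathcal{N}(0, \beta^{-1} I). $$

Sensors number in the tens to hundreds while sources number in the
thousands, so the problem is severely under-determined and the prior on $x$
does all the work. This package implements a family of hierarchical sparse
priors estimated by variational Bayes (VB), plus classical baselines, a
synthetic benchmark generator and the standard evaluation metrics.

## The rescaled sparse prior and its VB updates

Each coefficient gets a zero-mean Gaussian prior whose precision is the
product of a Gamma-distributed variable $a_i$ and a known, deterministic
scale $\lambda_i$:

$$ p(x \mid a; \lambda) = \prod_{i=1}^{K} \mathcal{N}(x_i \mid 0,
   a_i^{-1}\lambda_i^{-1}), \qquad
   p(a_i) = \text{Gamma}(a_i; b_a, c_a), \qquad
   p(\beta) = \text{Gamma}(\beta; b, c). $$

Integrating $a_i$ out gives a Student-t marginal with shape $c_a$ and scale
$b_a / \lambda_i$, and in the improper limit the marginal behaves like
$1/(\lambda_i^{1/2}\,|x_i|)$. Setting $\lambda_i$ to $1/|\hat{x}_i|$ and
re-estimating it at every cycle sharpens this into a prior close to
$|x_i|^{-1/2}$ — substantially more sparsity-inducing than the plain
Gaussian–Gamma (RVM) hierarchy, which is the special case $\lambda \equiv 1$.

With the mean-field factorization $q(x)\,\prod_i q(a_i)\,q(\beta)$ all
updates are closed-form:

$$ C_x = (\hat\beta H^\top H + \hat\Lambda)^{-1}, \qquad
   \hat{x} = \hat\beta\, C_x H^\top y, $$

$$ \frac{1}{b'_{a_i}} = \frac{\lambda_i}{2}\left(\hat{x}_i^2 +
   C_{x,ii}\right) + \frac{1}{b_a}, \qquad
   c'_{a_i} = c_a + \tfrac12, \qquad \hat{a}_i = b'_{a_i} c'_{a_i}, $$

with $\hat\Lambda = \mathrm{diag}(\hat{a}_i \lambda_i)$. The noise-precision
update is the standard conjugate one for the Gaussian likelihood,

$$ c' = c + \tfrac{N}{2}, \qquad
   \frac{1}{b'} = \frac{1}{b} + \frac12\left(\lVert y - H\hat{x}\rVert^2 +
   \mathrm{tr}(H C_x H^\top)\right), \qquad \hat\beta = b'c'; $$

the trace term is the posterior-uncertainty part of
$\mathbb{E}_q\lVert y - Hx\rVert^2$, and the test suite verifies this
identity against a Monte-Carlo estimate on a small instance.

### Update order and initialization

Within a cycle the order is: $\lambda$ (from the previous mean), then
$C_x$ and $\hat{x}$, then $q(a)$, then $q(\beta)$ — the scale entering the
covariance is the freshly reweighted one. The state is initialized at
$\hat{x} = 0$, $\lambda = 1$, $\hat{a} = 1$,
$\hat\beta = N/\lVert y\rVert^2$ (a unit-SNR heuristic). Because the
reweighting rule $1/|\hat{x}_i|$ is undefined at the all-zero
initialization, the first cycle runs with the initial $\lambda = 1$ and
reweighting starts from the second cycle; this also makes the first cycle
identical to a classical RVM-VB step, which the tests exploit.

The magnitude in $\lambda_i = 1/\max(|\hat{x}_i|, \varepsilon)$ is
deliberate: a signed $\hat{x}_i$ would produce a negative prior variance,
and the marginal-prior analysis is phrased in $|x_i|$ throughout. The floor
$\varepsilon = 10^{-8}$ caps the precision of fully pruned sources at
$10^8 \cdot \hat a_i$, avoiding division by zero while leaving pruning
self-reinforcing: as $\hat{x}_i \to 0$, $\lambda_i$ grows, the prior
precision $\hat{a}_i\lambda_i$ grows, and the coefficient is driven further
to zero. The suite asserts this monotone growth on a known inactive source.

### Numerics

The covariance update inverts a $K \times K$ matrix; for $K > N$ (the only
regime that matters here) it is computed through the Woodbury identity

$$ C_x = \Lambda^{-1} - \Lambda^{-1}H^\top(\beta^{-1}I +
   H\Lambda^{-1}H^\top)^{-1}H\Lambda^{-1}, $$

inverting $N \times N$ only, and only the diagonal of $C_x$, the mean, and
$\mathrm{tr}(HC_xH^\top)$ are materialized inside the loop. The dense and
Woodbury routes agree to $10^{-8}$ relative error on random instances
(tested over 50 draws with $N \le 40$, $K \le 200$; observed agreement is
$\sim 10^{-12}$). Convergence is declared when the relative change of
$\hat{x}$ falls below `tol` ($10^{-6}$ by default, at most 500 cycles);
typical noise-free single-dipole runs converge in 10–40 cycles. Both
routes guard against non-finite states and report the iteration index on
failure.

Hyperparameter defaults $b_a = b = 10^6$, $c_a = c = 10^{-6}$ are the
customary vague choice (prior mean $b\,c = 1$, variance $10^6$); the method
is insensitive to them in the tested regimes.

## Group sparsity

The grouped solver shares one $(a_g, \lambda_g)$ pair across each group of
coefficients, so whole groups survive or die together:

$$ p(x \mid a; \lambda) = \prod_{g=1}^{G}
   \mathcal{N}(x_g \mid 0, a_g^{-1}\lambda_g^{-1} I_{d_g}). $$

The conjugate updates follow the same algebra with the quadratic statistic
summed within the group and the shape incremented by half the group size:

$$ \frac{1}{b'_{a_g}} = \frac{\lambda_g}{2}\left(\lVert\hat{x}_g\rVert^2 +
   \sum_{i \in g} C_{x,ii}\right) + \frac{1}{b_a}, \qquad
   c'_{a_g} = c_a + \frac{d_g}{2}, \qquad
   \lambda_g = \frac{1}{\max(\lVert\hat{x}_g\rVert, \varepsilon)}. $$

Singleton groups reduce these expressions exactly to the ungrouped solver —
in this implementation bit-exactly, since both run the same engine.

Three grouping strategies are provided: one group per dipole's three
Cartesian components (free orientation; `groups_per_dipole()`), groups from
caller-supplied anatomical/functional labels (`groups_from_labels()`), and
overlapping distance-based neighbourhoods (`groups_by_distance()`). For
overlapping covers the effective prior precision at a coefficient is the
*sum* of $\hat{a}_g\lambda_g$ over all containing groups. This
product-of-Gaussians composition is this package's design choice — it is
the unique composition that keeps $q(x)$ Gaussian with a diagonal prior
precision — and is not the only conceivable treatment of overlap.

## Spatially extended sources

Extended activations are not sparse in source space, but they are sparse in
a smoothed domain. With the Gaussian kernel

$$ \Psi_{ij} = \begin{cases} 1 & i = j \\ \exp(-r\, d_{ij}^2) & i \ne j
   \end{cases} $$

($d_{ij}$ the inter-source distance in mm, $r$ in mm$^{-2}$), sources are
modelled as $x = \Psi z$ with sparse $z$, the lead field becomes
$H_\psi = H\Psi$, any of the sparse solvers runs on $H_\psi$, and the
estimate is back-projected through $\Psi$. In free-orientation mode each
Cartesian component is smoothed independently (block structure by
component), preserving dipole direction fields; smoothing across components
would mix orientations with no physical justification.

Decisions worth noting:

* $r$ is treated as known. The default preset $r = 0.05$ mm$^{-2}$ gives
  $\psi = e^{-5} \approx 6.7\times10^{-3}$ at 10 mm. Because the right $r$
  depends on grid geometry, it should be chosen per source space;
  cross-validating it is out of scope here.
* As $r \to 0$, $\Psi$ tends to the singular all-ones matrix.
  `build_kernel()` refuses kernels whose reciprocal condition number falls
  below $10^{-12}$ rather than silently producing garbage.
* Entries below $10^{-6}$ are truncated to exact zero by default (an
  approximation switchable off with `truncate = 0`), making $\Psi$ sparse
  for large grids.
* A very large $r$ gives $\Psi = I$ exactly, and `run_fansmooth()` then
  reproduces `run_fan()` bit-for-bit — a reduction the suite asserts.

## Baselines

The minimum-norm estimate is the Tikhonov solution
$\hat{x} = H^\top(HH^\top + \rho I)^{-1}y$. No selection rule for $\rho$ is
canonical; the default ties it to an assumed sensor SNR,
$\rho = \mathrm{tr}(HH^\top)/(N \cdot \text{snr}_\text{power})$ with a
20 dB default, and $\rho$ is exposed both in R and on the command line.
RVM-VB is `run_fan()` with `lam_mode = "fixed_ones"` — deliberately the
same code path, so the comparison between the reweighted and plain priors
isolates exactly the reweighting.

## The synthetic generator

`simulate_problem()` emulates a pointwise-activation study: unit-variance
Gaussian amplitudes at 1–few active dipoles (three component draws per
dipole in free mode), white Gaussian sensor noise, and repeated seeded
configurations in which locations, amplitudes and noise are all resampled
per repetition with every seed recorded.

* **SNR calibration.** The noise is drawn white Gaussian and the realized
  vector is rescaled so that $10\log_{10}(\lVert Hx\rVert^2 /
  \lVert e\rVert^2)$ equals the configured value *exactly* (the package's
  exact-realization convention, chosen over expectation calibration so a
  seeded noisy instance is fully deterministic). The 60 dB preset therefore
  realizes 60.000 dB to machine precision.
* **Lead fields.** `random_gaussian` (i.i.d. normal entries, unit-norm
  columns) makes solver comparisons geometry-agnostic;
  `single_shell_sphere` evaluates the analytic current-dipole potential in
  a homogeneous conductor at electrodes on an enclosing sphere and leaves
  columns unnormalized, so deep sources are genuinely harder — the depth
  bias that penalises minimum-norm solutions. It does not include the
  boundary correction of a bounded head model, nor tissue layers.
* **Problem sizes.** Default test presets are $N = 32$, $M = 300$ (fixed
  orientation) and $N = 64$, $M = 200$ (free orientation, $K = 600$), with
  20 repetitions — deliberately smaller than realistic montages
  ($N \in \{128, 256\}$, $M$ in the thousands) but in the same
  under-determined regime ($K/N \approx 10$). Presets scale up by argument.
* **Separation.** Multi-dipole scenes accept a `min_separation` constraint
  (default 0, i.e. none) enforced by bounded rejection sampling.

What the generator does *not* emulate: correlated (non-white) sensor noise,
temporally extended sources, realistic conductor geometry, and electrode
co-registration error. Passing benchmarks here shows the solvers do what
their theory promises under the model's own assumptions; it does not certify
performance on real recordings.

## Evaluation metrics

* **Reconstruction error** $\lVert x_{est} - x_{true}\rVert^2 /
  \lVert x_{true}\rVert^2$, computed on the full coefficient vectors (3M
  components in free mode) — it is scale-sensitive by design.
* **Localization error**: distance from each true source to the amplitude
  peak among candidates within 25 mm (inclusive). Ties break towards the
  candidate nearest the truth; an all-zero neighbourhood scores the radius
  (25 mm) as a penalty. Neither degenerate case has a canonical treatment;
  both choices are conservative.
* **A′ detection index** $(H_R - F_R)/2 + 1/2$ with detection at 0.1% of
  the map maximum. A true source counts as a hit when its own grid point is
  supra-threshold *or* a supra-threshold source lies within one grid
  spacing (the strict own-point rule is available via `hit_rule`). The
  false-positive rate divides detected non-true sources by the number of
  non-true sources. An all-zero map is defined as chance, A′ = 0.5.
* **Gini coefficient** of the amplitude map summarizes compactness and is
  used to compare solver sparsity.

The benchmark runner emits one row per configuration × repetition × method
with the per-run seed, so means or medians can both be computed downstream,
and records solver failures as flagged rows rather than aborting a sweep.

## Containers and interchange

Lead fields, scenes, measurements, results and group structures serialize
to plain-text JSON containers (17 significant digits, hence exact round
trips) with the documented variable names `H`, `pos`, `ori`, `mode` and the
`[x, y, z]` per-dipole column convention in free mode. Arrays exported from
other toolchains under different names can be ingested via a name-remapping
table (`read_leadfield(..., var_map = )`). Coordinates are always mm; no
coordinate-frame transforms are applied — aligning frames is the caller's
responsibility.

## Known limitations

* Instantaneous model only: each time point is solved independently; no
  spatiotemporal coupling.
* No model-evidence (free energy) tracking; convergence is assessed on the
  posterior mean.
* The homogeneous-conductor lead-field model is a deliberately simple
  physical stand-in; results on it do not quantify realistic-head-model
  accuracy.
* The overlap composition for distance-based groups is an interpretation
  (sum of precisions), documented as such above.
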