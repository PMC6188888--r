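---
title: "Coarse-grained inference of multi-area decoding weights"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained inference of multi-area decoding weights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popdecode)
```

## The problem

Two classic experimental programmes ask how sensory cortex drives
perceptual decisions. *Correlational* studies measure, neuron by neuron,
how trial-to-trial response fluctuations co-vary with the animal's choice
(choice probability, or the closely related choice correlation).
*Causal* studies silence a candidate area and measure the change in the
behavioural discrimination threshold. In several systems the two
disagree sharply: an area whose neurons predict choice strongly can be
silenced with no behavioural cost. `popdecode` implements a
coarse-grained framework that reconciles the two kinds of measurement
and, by combining them, infers how much weight a linear decoder gives
each area — without requiring the full noise-correlation structure,
which is practically unmeasurable.

## Model

Responses $r \in \mathbb{R}^N$ of $N$ neurons, partitioned into $Z$
areas, are tuned to a scalar stimulus $s$ with means $f(s)$, a
stimulus-independent noise covariance $\Sigma$, and per-neuron variances
$\sigma_k^2 = \Sigma_{kk}$. A linear readout forms the locally unbiased
estimate $\hat s = w^T (r - f(s_0)) + s_0$ with $w^T f'(s_0) = 1$. Its
variance $\varepsilon = w^T \Sigma w$ sets the 68%-correct
discrimination threshold $\vartheta = \sqrt{\varepsilon}$; the locally
optimal readout is $w \propto \Sigma^{-1} f'$, whose threshold is the
inverse square root of the linear Fisher information $J = f'^T
\Sigma^{-1} f'$.

For multiple areas the global weights factor as $w = [a_1 w_1, \dots,
a_Z w_Z]$: per-area unbiased patterns $w_x$ ($w_x^T f'_x = 1$) and
scalar *scaling factors* $a$ with $a^T 1 = 1$. The scaling factors are
the quantity of interest: the coarse weight of each brain area.

### Choice correlations

The choice correlation of neuron $k$ is $C_k =
\mathrm{Corr}(r_k, \hat s \mid s) = (\Sigma w)_k / (\sigma_k
\sqrt{w^T \Sigma w})$. Under optimal decoding this collapses to
$C_{k,\mathrm{opt}} = \mathrm{sgn}(f_k')\, \vartheta / \vartheta_k$,
with $\vartheta_k = \sigma_k/|f_k'|$ the single-neuron threshold — a
practical test for optimality that needs no covariance measurement.
For suboptimal readouts, writing $w = \Sigma^{-1} g / (f'^T \Sigma^{-1}
g)$ and expanding over the covariance eigenmodes $u^i$ gives
$C = \sum_i \beta_i\, C^i_{\mathrm{opt}}$ with per-mode patterns
$C^i_{\mathrm{opt}} = \vartheta\, S^{-1} u^i (u^{iT} f')$ and
multipliers $\beta_i = (g^T u^i) / ((f'^T u^i)(f'^T \Sigma^{-1} g)
\vartheta^2)$; all $\beta_i = 1$ exactly when $g = f'$. (Several
published renderings of this decomposition garble the fractions; the
forms above are the unique ones that reconstruct $C$ exactly and give
unit multipliers at the optimum, and the package's tests verify both
properties on random instances.)

### Two models of correlated variability

*Extensive information.* Noise correlations proportional to signal
correlations ("limited-range"): $\bar R_{ij} = (1 - m)\delta_{ij} + m
R^{sig}_{ij}$ within an area, with per-area slopes $m_x$ and a cross-area
slope $k\sqrt{m_x m_y}$, $k \in [0,1)$; variances are Poisson-like, so
$\Sigma_{ij} = R_{ij}\sqrt{f_i f_j}$ at the reference stimulus.
Diversity around the mean trend is emulated by sampling one correlation
matrix from a Wishart distribution centred on $\bar R$, rescaling to
unit diagonal, and projecting to the positive semi-definite cone.
Information grows linearly with $N$ under this model.

*Limited information.* Adding differential correlations $F E F^T$ —
where $F$ is the block matrix of per-area tuning-derivative vectors and
$E$ a $Z \times Z$ covariance in squared stimulus units — caps the
information of area $x$ at $1/\epsilon_{xx}$ no matter how many neurons
it contains (the estimator-variance identity $(f'^T \Sigma_{IL}^{-1}
f')^{-1} = (f'^T \Sigma^{-1} f')^{-1} + \epsilon$ holds exactly and is
tested via direct inversion).

### Coarse graining

Either model reduces to a $Z \times Z$ description. For the extensive
model, each area's leading *own-block* eigenvector $u_x$ (sign-fixed so
$u_x^T f'_x \ge 0$) with eigenvalue $\lambda_x$ and cross-mode noise
$\lambda_{xy} = u_x^T \Sigma_{xy} u_y$ map into stimulus units as
$\epsilon_{xx} = \lambda_x/(u_x^T f'_x)^2$ and $\epsilon_{xy} =
\lambda_{xy} / ((u_x^T f'_x)(u_y^T f'_y))$. Pure differential noise is
the special case $u_x \propto f'_x$. At this level the behavioural
threshold is $\vartheta^2 = \tilde a^T E \tilde a$ and the per-area CC
slopes are $\beta_x = (E\tilde a)_x / (\tilde a^T E \tilde a)$, where
$\tilde a = (a \odot \rho)/\sum_x a_x \rho_x$ applies the retention
factors $\rho_x \in [0,1]$ of an inactivation experiment with l1
renormalisation (the readout stays unbiased after inactivation, as
observed experimentally). We use the normalised slope throughout because
it is the only form that gives $\beta_x = 1$ for every area at the
optimal scaling $a \propto E^{-1}1$; an unnormalised variant
(`beta_mode = "eq19"`) is provided for comparison.

### Inference

Each inactivation experiment $\phi$ contributes the polynomial
constraints $\theta_\phi^2 = \tilde a_\phi^T E \tilde a_\phi$ and, where
CC slopes were measured, $\beta_{x\phi} = (E \tilde a_\phi)_x / (\tilde
a_\phi^T E \tilde a_\phi)$. With $Z(Z+1)/2 + Z - 1$ unknowns,
`fit_decoder_scaling()` solves the system by Levenberg–Marquardt
nonlinear least squares on the squared-threshold and slope residuals. $E$
is parameterised through a Cholesky-like factor, which enforces positive
semi-definiteness (and with it the bound $|\epsilon_{xy}| \le
\sqrt{\epsilon_{xx}\epsilon_{yy}}$) by construction; $a$ is free apart
from the sum constraint, so negative scalings are representable and
reported. Because two different scalings can produce identical
behaviour (the U-shaped threshold curve admits solutions on both sides
of its minimum), the solver multi-starts from 32 random seeds by default
and retains all distinct local optima in the returned object rather
than silently picking one. For two populations the closed forms are
available directly: `two_population_ratio()` implements
$a_x/a_y = (\beta_x/\beta_y)(\vartheta_{-x}^2/\vartheta_{-y}^2)$ for
uncorrelated areas and its correlated-area generalisation with $\gamma =
\epsilon_{xy}/\epsilon_{xx}$, plus an exact variant that uses the noise
magnitudes themselves when they are known; when both are supplied the
exact form takes precedence.

Predictions close the loop: post-inactivation thresholds from the same
quadratic form, and the multiplicative CC change $\zeta_x =
(1/\beta_x)(\vartheta_{-y}/\vartheta)$ in the remaining area, which the
tests verify against directly recomputed post-inactivation correlations
(an exact identity at the coarse level, and exact for block-correlated
fine-grained populations).

## The synthetic generator

`build_population()` draws von Mises tuning $f_i(s) = b_i + h_i
e^{\kappa_i \cos(s - s_i)}$ with $b_i \sim \mathrm{Poisson}(\bar b)$,
$h_i \sim \mathrm{Poisson}(\bar h)$, $\kappa_i \sim |N(\mu_\kappa,
\sigma_\kappa^2)|$ and uniform preferred stimuli. Defaults: $\bar b = 5$
and $\bar h = 15$ spikes/s, $\mu_\kappa = 1$, $\sigma_\kappa = 0.5$
(reading the conventional $N(1, 0.25)$ notation as mean and variance),
circular domain $(-\pi, \pi]$, reference $s_0 = 0$. Heading-style tasks
on a linear domain in degrees are configured through
`tuning_params()`; the two domains are never mixed. Signal correlations
are evaluated on a uniform grid of 360 points by default — a config
parameter, since the appropriate resolution depends on tuning width.
Variances equal mean rates at $s_0$ (Poisson-like scaling), and trials
are multivariate *Gaussian*: the analysis is entirely
covariance-level, so only the first two moments matter; spiking
discreteness, temporal dynamics, serial dependence and adaptation are
deliberately out of scope. Passing tests on this generator therefore
validates the estimators and the inference algebra, not the realism of
cortical spike trains. A choice tied exactly at $s_0$ (measure zero) is
assigned $+1$ deterministically.

## Estimating choice statistics from trials

`choice_probability()` follows the grand-CP procedure: within each
stimulus level having at least 3 choices per side, responses are split
by the *direction of the choice* (not by each neuron's preference, so
CPs can fall on either side of 1/2), balanced z-scored — centred on the
unweighted mean of the two choice-group means and scaled by the
unweighted mean of the two choice-group SDs, so an imbalanced choice
split cannot bias the pooled distributions — pooled, and summarised by
the rank AUC with ties counted half. The CP–CC conversion uses the
small-correlation linearisation $C = (\pi/\sqrt 2)(CP - 1/2)$; its
companion identity $\mathrm{Corr}(r, \mathrm{sgn}(\hat s)) =
\sqrt{2/\pi}\, C \approx 0.8\,C$ under joint Gaussianity pins down the
constant, and the Monte-Carlo tests confirm the 0.8 attenuation
directly. The linearisation degrades above $|C| \approx 0.7$
(conversions are clipped to $[-1, 1]$). Per-area slopes
$\beta_x$ are fitted by least squares *through the origin* — the theory
predicts pure proportionality between observed and optimal CCs, and the
slope is the quantity consumed downstream — with a free-intercept option,
and a 95% percentile bootstrap over neurons (1000 resamples by default)
for the interval, matching the level at which such slopes are usually
reported.

## Numerical choices

- Eigenvector signs are fixed by $u^T f' \ge 0$ everywhere; coarse
  quantities are invariant to the convention (tested by flipping).
- Near-degenerate leading eigenvalues (relative gap below $10^{-6}$)
  trigger a warning; the first by index order is used, keeping runs
  deterministic.
- Singular covariances fall back to the Moore–Penrose pseudo-inverse
  with a warning; rank-deficient coarse models are legitimate inputs.
- Sampled-then-rescaled correlation matrices are PSD-projected by
  eigenvalue clipping; rescaling the diagonal can break PSD marginally.
- The Wishart degrees of freedom are exposed directly, with
  `calibrate_wishart_dof()` bisecting on the Monte-Carlo standard
  deviation of the refitted slope when a target uncertainty is wanted.
  Sampling is done once per seed; bootstrap-style resampling is the
  caller's choice.
- Decoders orthogonal to the signal in the $\Sigma^{-1}$ metric make the
  unbiased normalisation undefined and raise an error rather than being
  regularised silently.
- The solver treats non-finite residuals (fully inactivated
  renormalisations) as large penalties, keeping Levenberg–Marquardt
  inside the feasible region.

## A property worth knowing

On the circular generator the two leading noise modes form a
near-degenerate cos/sin harmonic pair (a consequence of the ring
symmetry), so the RMS choice correlation of a subspace decoder barely
changes between $p = 1$ and $p = 2$ decoded modes and declines only
gradually towards the full-optimal value (roughly 3–4 times lower at
$N = 512$). Claims that confining the readout to a couple of leading
modes collapses choice correlations by an order of magnitude do not hold
on this generator; what does hold, and is tested, is that RMS CC
decreases from $p = 1$ to $p = N$, that the single-mode readout's CCs
are insensitive to population size while the optimal readout's shrink,
and that the subspace decoder's efficiency falls off approximately as
$1/N$.

## Problem sizes

The test suite exercises populations of 512 neurons for the
subspace-decoding properties, 1024 for the efficiency scaling law,
6-population recovery with 14 inactivation experiments, and Monte-Carlo
checks with $2\times 10^4$–$10^6$ draws; recovery-robustness uses 50
repeats of a two-area fit under 5% observation noise. These sizes were
chosen to make sampling error comfortably smaller than the tested
effects while keeping the default suite fast.

## Known limitations

Feedforward, static, Gaussian; no recurrence or decision feedback, no
temporal integration or sliding-window analysis (repeated invocation on
windowed tables achieves the latter); stimulus-independent covariance;
no propagation of measurement uncertainty beyond the bootstrap and the
multi-start spread. Counting of independent constraints when some
slopes are unmeasured is left to the user: the solver requires at least
as many residuals as unknowns and reports conditioning through its
residual diagnostics.
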