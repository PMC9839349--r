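---
title: "Kernel methods for the inductive bias of population codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel methods for the inductive bias of population codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popkernel)
```

# The model

`popkernel` works with deterministic population codes: a map from a
discrete stimulus set $\{\theta_m\}_{m=1}^M$ with probabilities $p_m$ to
response vectors $r(\theta_m) \in \mathbb{R}^N$. A readout neuron learns
weights $w$ from $P$ stimulus-response examples drawn i.i.d. from $p$,
using the batch delta rule with optional weight decay. Its fixed point is
kernel ridge regression with the code's inner-product kernel
$K(\theta,\theta') = \tfrac1N r(\theta)\cdot r(\theta')$, so the learned
function — and therefore the code's inductive bias — depends on the code
only through $K$. Two consequences organize the whole package:

* **Rotation degeneracy.** Any orthogonal $Q$ gives a code $Qr(\theta)$
  with the same kernel and identical learning behavior on every task.
* **Spectral bias.** With the measure-weighted eigendecomposition
  $\sum_{m'} p_{m'} K(\theta_m,\theta_{m'})\psi_k(\theta_{m'}) =
  \lambda_k \psi_k(\theta_m)$ and target coefficients
  $v_k = \sum_m p_m y(\theta_m)\psi_k(\theta_m)$, the expected
  generalization error after $P$ samples is
  $E_g = \frac{\kappa^2}{1-\gamma}\sum_k \frac{v_k^2}{(\lambda_k P +
  \kappa)^2}$, where $\kappa \ge 0$ solves
  $\kappa = \lambda + \kappa\sum_k \lambda_k/(\lambda_k P + \kappa)$ and
  $\gamma = P\sum_k \lambda_k^2/(\lambda_k P+\kappa)^2$. Modes with
  larger eigenvalues are learned from fewer samples.

Assumptions worth keeping in mind: responses are noise-free and static
through learning; the readout is linear; the dataset average behind
$E_g$ treats $P$ as continuous and is an asymptotic approximation (see
*Limitations*).

## Measure convention

Eigenfunctions are orthonormal under the empirical measure,
$\sum_m p_m \psi_k \psi_l = \delta_{kl}$, so on a uniform $M$-point grid
eigenvalues carry a factor $1/M$ relative to a plain matrix
eigendecomposition. The kernel-matched generator `code_from_kernel()`
compensates internally: it returns
$R = \sqrt{N}\, Q_{[,1:K]} \Lambda^{1/2}\Psi^\top$, so
`compute_kernel(code)` (which includes the $1/N$) reproduces the input
kernel to machine precision. Both kernel normalizations are exposed
(`normalize = TRUE` divides by $N$; `FALSE` gives the raw Gram matrix);
all spectral machinery uses the normalized convention so that theory and
simulation share one ridge parameter.

# Numerical choices

* **$\kappa$ solver.** Bracketed root finding (`uniroot`) on
  $g(\kappa)=\kappa-\lambda-\kappa\sum_k\lambda_k/(\lambda_k P+\kappa)$
  over $[\lambda+\varepsilon, \lambda+\sum_k\lambda_k]$, followed by
  Newton polishing using $g'(\kappa)=1-\gamma(\kappa)$, to $10^{-12}$
  relative. $P=0$ returns $\lambda+\sum_k\lambda_k$ exactly; the
  ridgeless case with $P \ge$ the number of nonzero modes returns
  $\kappa = 0$ exactly (interpolation regime, all mode errors zero).
* **Rank floor.** Eigenvalues below $10^{-12}\lambda_1$ are treated as
  exact zeros everywhere: rank determination, pseudo-inverses in
  ridgeless regression, and the generator's factorization.
* **Degenerate eigenvalues.** Ties are broken by the deterministic
  ordering of the symmetric eigensolver; the basis inside an eigenspace
  is arbitrary, so only invariant quantities ($E_g$, $C(k)$ sums,
  eigenvalue sets) should be compared across runs. When a specific basis
  matters (per-frequency coefficients of a fully degenerate
  bounded-frequency kernel), construct the spectrum explicitly in the
  Fourier basis rather than relying on the eigensolver's choice.
* **Spectral-bias checking.** `spectral_bias_check()` enforces
  $\lambda_k > \lambda_l \Rightarrow E_k < E_l$ up to a $10^{-10}$
  tolerance relative to the mode-error scale: for eigenvalues orders of
  magnitude below $\kappa/P$ the errors approach the common limit
  $1/(1-\gamma)$ and tie in double precision, and near-degenerate pairs
  are allowed exactly the spread the error formula assigns to their
  eigenvalue split.
* **Delta rule.** Implemented on $N$-normalized features $r/\sqrt N$ so
  that its weight-decay constant equals the Gram-matrix ridge. Default
  learning rate $1/(2\lambda_{\max})$ of the empirical feature
  covariance (half the stability bound), convergence at
  $\max|\Delta w| < 10^{-10}$ (tests use $10^{-12}$), divergence
  detection on the weight norm. `empirical_learning_curve()` uses the
  closed-form fixed point by default — the rule's convergence to it is
  itself verified — with `method = "delta"` available.
* **Out-of-span targets.** Residual target power outside the
  nonzero-eigenvalue span is carried through the theory as an
  irreducible error floor, and `decompose_target()` reports it.

# Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `ridge` / `weight_decay` | theory, readout | 0 | explicit regularization $\lambda$ (Gram convention) |
| `sigma` | von Mises codes | — | tuning bandwidth; kernel $e^{\cos\Delta/\sigma^2}$ |
| `sigma_sq`, `q`, `a` | Gabor model | 0.2, 1.7, 0.2 | drive width, power-law exponent, threshold |
| `s` | Gabor mixture | — | simple-cell fraction; kernel $sK_s+(1-s)K_c$ |
| `gain`, `tau`, `dt` | reservoir | 1.5, 0.05, `tau/10` | recurrent gain (chaos onset near 1), time constant, Euler step |
| `beta`, `eta`, `iters` | rotation optimizer | `10/median|r|`, $10^{-3}$, 2000 | soft-min sharpness, manifold step, steps |

The default Gabor nonlinearity `(q, 1/sigma_sq, a) = (1.7, 5.0, 0.2)` is
the parameterization recovered by `fit_gabor_kernel()` in its
self-consistency test and is a realistic mouse-V1-like operating point;
the threshold can be tied to a coding level $f$ (firing fraction) via
$a = \cosh(\sigma^{-2}\cos(\pi f/2))/\cosh(\sigma^{-2})$, read so that
$f = 1$ places the threshold exactly at the tuning minimum.

# What the generators emulate — and what they do not

**Von Mises populations** model smooth orientation/direction tuning with
a controllable bandwidth; narrower tuning keeps more high-frequency
spectral power. **Kernel-matched codes** realize any PSD kernel exactly
and are the canonical demonstration that one inductive bias is shared by
infinitely many codes. **The Gabor mixture** models simple cells as a
phase-modulated drive through a threshold-power nonlinearity and complex
cells by the energy model (sum of squares of quadrature drives), giving
exact phase invariance; the complex-cell peak is normalized to the
simple-cell peak — a modeling choice, as is the $\cos(\phi-\phi_i)$
phase modulation of the simple-cell drive. Preferred parameters tile
deterministically (orientations uniformly; simple-cell phases on a
golden-ratio progression so any cell count covers phase quasi-uniformly).
**The reservoir** is the standard rate network
$\tau\dot u = -u + gJ\tanh(u) + W_{in}\theta(t)$ with $J_{ij}\sim
\mathcal N(0, 1/N)$, Euler-integrated from $u(0)=0$; responses are
$\tanh(u)$ (raw $u$ optional), with input scale and step exposed.

None of these emulate trial-to-trial noise, adaptation, or calcium-
imaging preprocessing of real recordings. Passing tests therefore show
the machinery is correct on deterministic codes; applying it to real
data requires denoised (e.g. trial-averaged) response matrices, which the
I/O layer accepts but the package does not produce.

# Design decisions that were genuinely open

* **Energy-model normalization** (peak-matched to simple cells) and the
  simple-cell phase modulation: minimal choices satisfying exact phase
  invariance and phase-dependent simple-cell kernels.
* **Sampling with replacement** in `empirical_learning_curve()`: matches
  the i.i.d. dataset average the theory computes.
* **Soft minimum** in the rotation optimizer:
  $\mathrm{softmin}(a;\beta)=\sum_\mu a_\mu e^{-\beta a_\mu}/\sum_\nu
  e^{-\beta a_\nu}$, a weighted average converging monotonically to the
  minimum; gradients are closed-form, and the manifold update
  $Q \leftarrow e^{-\eta G}Q$ with skew-symmetric $G$ keeps
  $\|Q^\top Q - I\|_{\max}$ at floating-point level. The optimizer
  returns the lowest exact-cost iterate of its trace, so the reported
  optimized cost never exceeds the initial cost.
* **Sparseness form.** Lifetime sparseness is
  $(\mathrm{Var}_\theta s / \langle s^2\rangle_\theta)/(1-1/M)$ — the
  Treves–Rolls/Vinje–Gallant selectivity — which is bounded in $[0,1]$;
  all-zero rows are reported as undefined (`NA`), not 0.
* **Heaviside windows** in the delayed-response task are closed at both
  ends ($H(0)=1$), making window membership deterministic on grid points.

# Known limitations

* The learning-curve theory is an asymptotic, self-consistent
  approximation. Near the ridgeless interpolation threshold
  ($P$ comparable to the kernel's numerical rank) it systematically
  underestimates the dataset-averaged error for steeply decaying
  spectra: for the von Mises code with $\sigma^{-2}=4$ on the 120-point
  grid, high-repeat empirical means are $\approx 0.21$ vs theory 0.15 at
  $P=8$ and $\approx 0.02$ vs $9\times10^{-5}$ at $P=16$ (total target
  power 0.68), converging again for larger $P$. The discrepancy
  persists on a 720-point grid and is insensitive to the pseudo-inverse
  rank floor, so it is a property of the approximation, not of the
  solver. Agreement is excellent away from the threshold and exact in
  the closed-form regimes.
* Theoretical $E_g(P)$ need not be monotone: when target power sits on
  eigenvalues far below the top of the spectrum the $1/(1-\gamma)$
  factor produces a genuine peak before the threshold (the same
  mechanism as overfitting peaks for noisy or out-of-span targets).
* Ridgeless empirical curves on targets with substantial out-of-span
  power can spike near the threshold; use a ridge there.
* The RROS cost distribution is sampled, not characterized analytically;
  z-distances inherit Monte-Carlo error of order $1/\sqrt{n_{\rm samples}}$.

# Problem sizes used by the tests

The suite exercises the full pipeline at desk scale: 120-point circular
grids with $N \le 200$ neurons for the static analyses, a
500-neuron/20-sequence/50-time-point reservoir (integration step
$\tau/10$) for the temporal analyses, 20-seed batches for the
participation-ratio and manifold-optimization experiments, and
1000-case fuzzing for the sparseness bounds. Larger,
publication-scale configurations (e.g. $N = 6000$, 80 sequences, 100
stored times) are reachable through the same function arguments.
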