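---
title: "Discrete dynamic neural fields: model, stability theory, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete dynamic neural fields: model, stability theory, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddnf)
```

## The model and its assumptions

A dynamic neural field describes the average membrane potential $V_k(x, t)$
of a continuum of neurons at positions $x$ on layer $k$: the potential decays
toward rest while lateral connectivity $W_{k\ell}(x, y)$, filtered through a
monotone pulse-emission gain $G$, and an external stimulus $S_k(x, t)$ drive
it. `ddnf` works with the discrete-time, discrete-space counterpart

$$
V^{(k)}_{i,n+1} \;=\; \alpha\, V^{(k)}_{i,n}
 + (1-\alpha) \sum_{\ell \in L_k} \sum_{j=1}^{M_\ell}
   \beta_\ell\, W^{(k,\ell)}_{ij}\, G\!\big(V^{(\ell)}_{j,n}\big)
 + (1-\alpha)\, S^{(k)}_i ,
$$

obtained by a *nearly exact* discretization: the time derivative is divided
by the time scale $\phi(h) = 1 - e^{-h}$ rather than by $h$, which makes the
per-step memory factor $\alpha = e^{-h}$ exact for the linear decay part —
with no coupling the iteration relaxes to the stimulus *exactly* at rate
$e^{-h}$ per step, for any $h$. This is the property an Euler scheme loses
for large steps, and it is why the package treats $h = 0.8$ as a perfectly
usable default rather than a coarse approximation. The spatial integral
becomes a midpoint Riemann sum with weights $\beta_\ell = |\Omega|/M_\ell$ on
the grid $x_i = a + (i - \tfrac12)|\Omega|/M$.

Assumptions baked into the implementation:

* **Chain topology.** Layer $k$ talks to itself and its immediate neighbors
  ($L_k = \{k-1, k, k+1\}$, clipped at the ends). Blocks for non-adjacent
  layers are structural zeros and are never stored.
* **Constant time step.** $h_n = h$; $\alpha$ may be overridden directly
  (the sweep scenario uses $\alpha = 1$, which freezes the field, because
  $(1-\alpha)$ multiplies every driving term).
* **Time-constant stimulus.** $S = \nu + U$ with resting level $\nu < 0$ and
  a time-constant $U$ (zero, a standard-normal density bump, or an explicit
  matrix). Time-varying inputs are out of scope.
* **Ragged layers.** With unequal $M_k$ the state matrix is zero-padded;
  padded entries are masked out of the update and remain exactly zero.

## Kernels and activations

Connectivity kernels: normalized Gaussian
$\mathrm{Gau}(x,y,\sigma) = (\sigma\sqrt{2\pi})^{-1} e^{-\|x-y\|^2/2\sigma^2}$,
Laplacian $(2\sigma)^{-1} e^{-\|x-y\|/\sigma}$, the inner-product kernel
$1 + \tanh(\beta x y + r)$ (asymmetric by construction; deliberately not
symmetrized), and "Mexican hat" differences
$\sigma^+ \mathrm{base}(\cdot,\sigma_1) - \sigma^- \mathrm{base}(\cdot,\sigma_2)$.
The scenario default is the normalized difference of Gaussians with
$\sigma^+ = 4$, $\sigma^- = 1.5$, $\sigma_1 = 1$, $\sigma_2 = 4.5$; its peak
value $(4 - 1.5/4.5)/\sqrt{2\pi} \approx 1.4628$ at $x = y$ is also the
uniform weight bound $W_0$ on the reference grid. The coordinate norm is the
Euclidean norm on the 1-D domain; the interface leaves coordinates extensible
but higher-dimensional domains are not implemented.

Activations: the sigmoid $G(v) = (1 + e^{-\theta(v - v_0)})^{-1}$ with
derivative $\theta G(1-G)$ and Lipschitz constant $\theta/4$ (the derivative
maximum, at $G = \tfrac12$); and the Heaviside indicator of the *open*
interval $(v_0, \infty)$ — the threshold itself maps to 0, which is the
convention that makes the below-threshold closed form exact. The Heaviside
derivative exists only distributionally: it is zero away from $v_0$ and a
Dirac mass at $v_0$. `activation_derivative()` therefore refuses to evaluate
within $10^{-9}$ of the threshold rather than silently returning 0, and
`build_jacobian()` inherits that refusal: a fixed point sitting on the
threshold has no meaningful linearization.

The reference simulations never state $\theta$ or $v_0$; the package fixes
$\theta = 1$, $v_0 = 0$ as documented defaults, so sigmoid-scenario
reproduction is qualitative (regime shape, convergence), not bit-wise.

## Fixed points and the Mann iteration

A time-constant field is a fixed point when $V = \Gamma G(V) + S$, where
$\Gamma$ collects $\beta_\ell W^{(k,\ell)}$. The update is exactly the
averaged (Mann-type) iteration $V_{n+1} = \alpha V_n + (1-\alpha) T(V_n)$
for $T(V) = \Gamma G(V) + S$. When $G$ is Lipschitz with constant $C$ and the
weights are bounded by $W_0$, the Lipschitz constant of $T$ is at most
$C\, W_0 |\Omega|$ (per layer the Riemann weights sum to $|\Omega|$);
`mann_iterate()` reports this *contraction product* and flags guaranteed
convergence when it is at most 1. For the Heaviside gain no Lipschitz
constant exists and the diagnostic is `NA` — the iteration may still
converge, it just carries no certificate. Non-convergence within the
iteration cap is a reported outcome, not an exception, so callers can
inspect the residual history. `fixed_point_residual()` measures
$\|V - (\Gamma G(V) + S)\|_\infty$ independently of how $V$ was produced.

One notational subtlety: some displays of the single-layer update drop the
$(1-\alpha)$ factor on $S$. The package keeps it, because only that form is
consistent with the fixed-point condition above and with the matrix form of
the update; the alternative would shift every fixed point by a factor
$(1-\alpha)^{-1}$ on the stimulus.

## Stability analysis

`build_jacobian()` assembles the derivative of the update map at a reference
field, blocked by layer:

$$
A^{(k,m)}_{ij} \;=\; \alpha\,\delta_{ij}\,\mathbf{1}\{m = k\}
 + (1-\alpha)\,\beta_m\, W^{(k,m)}_{ij}\, G'\!\big(V^{(m)}_{j,*}\big),
 \qquad m \in L_k,
$$

zero otherwise. This *is* the calculus Jacobian — the suite verifies it
against central finite differences of `ddnf_step()` on dozens of seeded
random multilayer models — and it is block tridiagonal because of the chain
topology. Classification follows the spectral radius computed by the dense
general eigensolver: stable below $1 - 10^{-9}$, unstable above
$1 + 10^{-9}$, otherwise *inconclusive* (the linearization is silent at
$\rho = 1$, and no marginal analysis is attempted). The tolerance exists
because an eigenvalue computed at $1 \pm 10^{-12}$ carries no sign
information worth acting on. A related design choice: closed-form
coefficient formulas for special architectures (below) are exposed as
*separate* operations taking the $K$ values directly, rather than
auto-detected from a general model — detecting exact coefficient constancy
in floating point is fragile, and the caller knows whether the reduction
applies.

Writing $K^{(k,\ell)}_{ij} = W^{(k,\ell)}_{ij} G'(V^{(\ell)}_{j,*})$ for the
weighted emission rates:

* **Single layer.** $\mu_i = (|\Omega|/M) \sum_j K_{ij}$; if
  $\max_i |\mu_i| < 1$ the row-sum norm of $A$ is at most
  $\alpha + (1-\alpha)\max_i|\mu_i| < 1$ and the fixed point is
  asymptotically stable. The norm-bound step moves an absolute value inside
  the row sum, so the certificate is honest only when the products
  $W_{ij}G'$ in a row do not change sign — the positive-connectivity setting
  the theory assumes. The package computes $\mu_i$ for arbitrary weights but
  the test suite exercises the bound under that hypothesis, and the
  *stable* fixture regime (below) rescales on absolute row sums so its
  certificate covers mixed-sign draws.
* **Heaviside fixed points.** Off threshold every $G'$ vanishes, $A =
  \mathrm{diag}(\alpha)$, $\rho = \alpha < 1$: any off-threshold fixed point
  of a Heaviside field is asymptotically stable, with the closed-form
  below-threshold trajectory $V_n = \alpha^n V_0 + \nu(1 - \alpha^n)$ (the
  geometric partial sum of the per-step drive, converging to $\nu$) and the
  a-priori bound
  $|V_{i,n}| \le \alpha^n \max_i |V_{i,0}| + Y_m (1-\alpha^{n+1})/(1-\alpha)$,
  $Y_m = (1-\alpha)(\bar S + |\Omega| \bar W)$.
* **One-neuron-per-layer chains.** With constant intra-layer rate $K_0$ and
  transitional rates $K_1, K_2$, the super-adjacency matrix is the constant
  tridiagonal matrix with $a = \alpha + (1-\alpha)|\Omega| K_0$,
  $b = a |\Omega| K_2$, $c = a |\Omega| K_1$, and eigenvalues
  $\mu_k = a\,[1 - 2|\Omega|\sqrt{K_1 K_2} \cos(\pi k/(L+1))]$. Note the
  off-diagonal coefficients both carry the factor $a$ — that is the printed
  convention for this reduction, kept exactly as stated and cross-checked
  against the dense spectrum. The compact bound
  $a\,[1 + 2|\Omega|\sqrt{K_1 K_2}]$ dominates $\max_k|\mu_k|$ for every $L$
  and is approached as $L \to \infty$; the package documents it as a
  length-independent upper bound rather than an equality, which is what it
  is for finite chains.
* **Transfer-matrix determinants.** `transfer_matrix_det()` evaluates
  $\det(A - \lambda I)$ of a tridiagonal chain as the trace of a product of
  $2\times 2$ transfer matrices, and of the *closed* chain (corner entries
  joining layer $L$ back to layer 1) with a modified corner matrix plus the
  boundary term $(-1)^{L+1}(\prod_i b_i + \prod_i c_i)$. The typeset corner
  matrix in the source material is ambiguous, so the implemented reading —
  corner matrix $[[a_1-\lambda, -b_L c_0], [1, 0]]$ — was frozen only after
  validating against dense determinants (relative error below $10^{-14}$
  over hundreds of random open and closed chains). Closed chains require
  $L \ge 3$; for $L = 2$ the corner entries would collide with the band.
* **Two layers, one neuron each.** The $2 \times 2$ matrix
  $A = [[a_1, b_1], [c_1, a_2]]$ is classified by the determinant–trace
  criterion $|\mathrm{tr}A| - 1 < \det A < 1$, which for a $2\times2$ matrix
  is *exactly* equivalent to both eigenvalues lying inside the unit circle.
  The report also evaluates the composite quantities
  $\theta = 1 - |\Omega|^2 K^{(1,2)} K^{(2,1)}$,
  $\mu_0 = |\Omega|(K^{(1,1)} + K^{(2,2)})$,
  $\mu = \alpha(K^{(1,1)}+K^{(2,2)}) + (1-\alpha)|\Omega| K^{(1,1)}K^{(2,2)}$
  and the three closed-form conditions $0 < \theta < 1$, $\mu < 1$,
  $(\mu\theta + 2 - \mu_0)^2 < 4\theta(\mu\theta + 1 - \mu_0)$, exactly as
  printed in the source formulation. Two caveats the package documents
  rather than hides. First, expanding $\det A$ in these variables gives
  $[\alpha^2 + (1-\alpha)|\Omega|\mu]\,\theta$ — an $|\Omega|$ factor
  appears that the compact form omits. Second, the discriminant condition is
  *unattainably strict*: the polynomial
  $P(\alpha) = \det A - \mathrm{tr}A + 1
  = \theta\alpha^2 - (\mu\theta + 2 - \mu_0)\alpha + (\mu\theta + 1 - \mu_0)$
  satisfies $P(1) = \theta - 1 < 0$ whenever $\theta < 1$, so $P$ always has
  real roots and its discriminant can never be negative on the condition
  set's own domain — numerically, zero satisfying draws in $2\times10^4$
  random positive-connectivity instances. The three-condition flag is
  therefore a (vacuously) sufficient certificate, and the determinant–trace
  flag is the one to use; the acceptance suite records this discrepancy as a
  deliberately failing equivalence check rather than papering over it.

Negative connectivity values flow through every numeric path (dense
eigensolver, determinants) — with a warning where a closed form assumes
positivity, since those reductions are only proven for positive weights.

## Reference scenarios and the fixture generator

Seven scenarios share the configuration $\Omega = [-20, 20]$, $h = 0.8$,
$M = 200$, $N = 100$, the difference-of-Gaussians kernel above, $\nu = -0.5$,
$V_0 = -1.5$: single-layer Heaviside/sigmoid with and without the Gaussian
input bump $U(x) = (2\pi)^{-1/2}e^{-x^2/2}$ (the negative exponent — the
positive-exponent variant that appears once in the source text would blow up
off-center and is treated as a typo), two multilayer chains of one-neuron
layers, and an $\alpha$ sweep. Two documented inconsistencies in the source
configuration: the multilayer layer count is stated both as 250 and as 200
(the package defaults to $L = 200$, configurable), and some quoted probe
coordinates (e.g. a layer index of 293) exceed the stated grids — probes are
therefore configurable and snap to the nearest grid point. The $\alpha$
sweep uses 50 evenly spaced values in $(0, 1]$ including $\alpha = 1$
exactly, where the field provably never moves. The scenario runs are fully
deterministic; "simulation" here means trajectory integration, not sampling.

The fixture generator draws random models for property tests: random
Gaussian-kernel connectivity with uniform sign/magnitude jitter, random
sigmoid steepness, on a unit domain. Its key design point is that the
reference field is *the zero field made an exact fixed point* by setting
$S = -\Gamma G(0)$ — no root-finding, no approximation error in the fixed
point itself. The `stable` regime rescales weights so the absolute-row-sum
version of $\max_i|\mu_i|$ equals 0.85 (certifying $\rho \le \|A\|_\infty
\le \alpha + 0.85(1-\alpha) < 1$); the `unstable` regime exploits the fact
that the Jacobian eigenvalues are affine in a global weight scale to place
$\rho$ at 1.2 by a bracketed root search. Draws are deterministic in the
seed and leave the session RNG untouched.

What the generator does *not* emulate: spatially structured (Mexican-hat)
sign patterns, heterogeneous per-neuron gains, ragged multilayer geometries
beyond small sizes, or measured biological connectivity. Passing the
property suite on these fixtures demonstrates correctness of the formulas
and certificates on generic small systems, not fidelity to any particular
cortical tissue.

## Numerical choices, sizes, and limitations

* Dense `eigen()` / `det()` (LAPACK) everywhere a spectrum or determinant is
  needed; closed forms are used only where derived, and always cross-checked
  against the dense route in the suite. The closed-form eigenvalue tests use
  the symmetrized tridiagonal ($\sqrt{bc}$ off-diagonals, symmetric solver)
  as the oracle, which is accurate to machine precision where the general
  nonsymmetric solver drifts near $10^{-10}$.
* `cospi()` rather than `cos(pi*...)` in the closed forms, so boundary cases
  (e.g. $L = 1$, where $\cos(\pi/2)$ must vanish) are exact.
* Trajectory CSVs are written at 17 significant digits with fixed line
  endings: round trips are bit-exact and repeated runs byte-identical
  (checksummed in the manifest).
* Tolerances: $10^{-9}$ for spectral classification and the Heaviside
  threshold band; $10^{-6}$ sup-norm for "converged" summaries; Mann
  iteration default $10^{-10}$.
* Test problem sizes: property tests run models with $L \le 3$,
  $M_k \le 5$ (50 seeded draws for the Jacobian oracle), chains up to
  $L = 50$ for spectra and $L = 12$ for determinants, 1000 draws for the
  two-layer criteria, and the full $M = 200$, $N \in \{100, 200\}$ reference
  runs — the whole suite completes in seconds.
* Known limitations: 1-D domains only; time-constant stimuli; no
  continuous-time integration; no bifurcation analysis (the memory factor is
  not a bifurcation parameter here — at $\alpha = 1$ the map degenerates to
  the identity rather than crossing a bifurcation); the closed-form
  multilayer results assume positive connectivity; sigmoid scenario
  reproduction is qualitative because the gain parameters are conventions,
  not published values.
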