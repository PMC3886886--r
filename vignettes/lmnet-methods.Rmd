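---
title: "Leaky Markovian networks: models, landscape thermodynamics, and avalanches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leaky Markovian networks: models, landscape thermodynamics, and avalanches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmnet)
```

## The model

A leaky Markovian network (LMN) is a continuous-time Markov model of $N$
binary nodes. Node $i$ turns on at rate $(1-x_i)\,[a_i + \varphi(u_i)]$ and
off at rate $x_i\,[b_i + \psi(u_i)]$, where $u_i = h_i + \sum_j w_{ij} x_j$
is the net input ($w_{ii} = 0$: no self-regulation). The constant leaks
$a_i, b_i > 0$ keep every transition available regardless of input; this
*leakiness* makes the chain irreducible, so it has a unique stationary law.
Epidemic processes with spontaneous infection and stochastic spiking
populations are both of this form.

The node-level chain lives on $2^N$ states, so `lmnet` works with the
**coarse-grained** model: nodes are partitioned into homogeneous blocks and
only the vector of active counts $n = (n_1,\dots,n_M)$, $0 \le n_k \le N_k$,
is tracked. When leaks, gains, inputs, and (block-pairwise) weights are
constant within blocks, the count process is exactly Markov on the lattice
$\prod_k \{0,\dots,N_k\}$, with birth/death propensities

$$\beta_k(n) = (N_k - n_k)\,[a_k + \varphi_k(\bar u_k(z))], \qquad
  \delta_k(n) = n_k\,[b_k + \psi_k(\bar u_k(z))],$$

where $z_k = n_k/N_k$ and $\bar u_k(z) = h_k + \sum_l \bar W_{kl} z_l$ with
$\bar W_{kl} = N_l\, w(k,l)$. One approximation is involved: a node's own
state is excluded from its input, which shifts the input of *active* nodes
by $-w(k,k)$, an $O(1/N_k)$ correction bounded by $|\bar W_{kk}|/N_k$. In
both worked models the deactivation gain is zero, so the coarse chain is
exactly lumpable from the node level; the test suite verifies this against
a brute-force $2^N$-state solve on random small fixtures.

The **network size** $\Omega = \sum_k N_k / N_0$ (with a fixed normalizer
$N_0$) is the structural parameter of interest: coupling acts through
fractions, so `resize()` changes all block sizes (round-half-even, at least
one node per block) while leaving rates and weights untouched. Intrinsic
noise scales like $1/\sqrt{\Omega}$.

## Exact master-equation machinery

`build_generator()` assembles the sparse rate matrix of single-step moves
$n \to n \pm e_k$. Stationary laws are computed by **GTH state reduction**
(compiled) for lattices up to 4096 states: the algorithm uses no
subtractions, so every component of $\pi$ carries full *relative* accuracy.
This matters: at supercritical sizes the inactive origin can carry
probability $e^{-80}$ relative to the mode, far below the absolute noise
floor ($\sim 10^{-16}\,\pi_{\max}$) of an LU solve, yet its logarithm is
exactly the quantity the landscape analysis needs. Larger lattices fall
back to the sparse LU solve with one balance row replaced by the
normalization (with power iteration as a last resort); in that regime
deep-tail values are at the solver's floor, and sweeps mark them with
$V = \infty$ rather than failing.

Transient solves use **uniformization** rather than a stiff ODE
integrator: $p(t) = \sum_k \mathrm{Pois}(k;\Lambda t)\, p_0 P^k$ with
$P = I + Q/\Lambda$ conserves probability mass by construction; very stiff
steps are split so each segment's Poisson series stays short. Mean
first-passage times come from the exact sparse linear system ($\tau = 0$ on
the target, $Q\tau = -1$ elsewhere), and the single-state exit time is the
exponential holding time $1/\sum_k(\beta_k + \delta_k)$ — for the SISa model
at the origin this is exactly $1/(Na)$.

A one-dimensional **birth–death closed form** ($\pi_n \propto \prod
\lambda_{m-1}/\mu_m$) is kept as an independent oracle; every single-block
stationary solve in the test suite is checked against it.

The **affinity** of a transition pair is $\ln[p(n)q(n,n')] -
\ln[p(n')q(n',n)]$; its maximum absolute value is zero exactly at detailed
balance. It is computed for a *supplied* distribution because a
one-dimensional birth–death chain is always in detailed balance at
stationarity — so any nonzero "stationary affinity" reported for a
one-dimensional model must refer to a different construction (transient
law, or the node-level chain). The operation therefore supports transient
distributions directly; the package records this ambiguity rather than
resolving it.

## Landscape and thermodynamics

Given a strictly positive law $p$, the potential is $V(n) =
\ln[p(n^*)/p(n)] \ge 0$ with $n^*$ the most probable state (ties within
$10^{-9}$ relative all count as ground states; the lowest lattice index is
the representative). $e^{-V}/Z$ reconstructs $p$ — a Boltzmann–Gibbs form
with the temperature absorbed (all quantities in nats). Per size:

* entropy $S = -\sum p \ln p$,
* self-information of the ground state $I^* = -\ln p(n^*)$,
* internal potential energy $U = E[V] = S - I^*$,
* free potential energy $F = U - S = -I^*$,

and across a size grid, by central finite differences (one-sided at the
ends): internal pressure $\Pi = -dU/d\Omega$, pressure $P = dI^*/d\Omega =
-dF/d\Omega$, and bulk modulus $B = \Omega\,|dP/d\Omega|$. The absolute
value in $B$ is a convention: the quantity is used as a *pulse detector*
for the pressure discontinuity, and the absolute value makes the spike
positive regardless of sign convention. Since block sizes are integers,
$\Omega$ is only quasi-continuous; the default grids are dense enough
(60 points) that the discretization is below the features of interest.

The **critical network size** $\Omega_c$ is where the stationary ground
state reallocates between the macroscopic well (the lattice state nearest
the deterministic fixed point $x^*$) and the inactive origin.
`detect_critical_size()` interpolates the sign change of
$V(\text{origin}) - V(\text{macro})$ linearly between grid points
(primary), and reports the interior argmax of $B$ (secondary) with an
agreement flag. For the shipped SISa model the two detectors land at
0.1727 and 0.179 on a 60-point grid over $(0.05, 1)$ — both within one
grid step of the calibrated 0.175.

## Macroscopic limit and its failure

The deterministic limit $\dot x_k = (1-x_k)[a_k + \varphi_k(\bar u_k(x))] -
x_k[b_k + \psi_k(\bar u_k(x))]$ is integrated with an adaptive Cash–Karp
RK45 (the unit hypercube is forward-invariant). `find_fixed_point()`
integrates from the center and polishes with damped Newton to
$\|g\| \le 10^{-12}$, warning on boundary-adjacent or multiple roots.

The **linear noise approximation** (LNA) places a Gaussian at $x^*$ with
covariance $C$ from $AC + CA^{\mathsf T} + D = 0$, where $A$ is the drift
Jacobian (analytic when gain derivatives are registered, central
differences otherwise) and $D = \mathrm{diag}\{r_k/N_k\}$,
$r_k = (1-x^*_k)(a_k+\varphi_k) + x^*_k(b_k+\psi_k)$ — the standard
system-size expansion for jumps of size $1/N_k$. The convention is pinned
by the zero-coupling closed form $C = x^*(1-x^*)/N$, the exact binomial
variance. Discretized onto the lattice, the LNA law matches the exact one
to sup-norm $< 0.01$ at $N = 50$ per block and improves with $N$ — but it
is *parabolic by construction*: the exact landscape near criticality is
lower and flatter left of $x^*$ and higher and steeper to the right, and
the exact origin mass exceeds the LNA prediction by orders of magnitude.
That failure — the invisibility of the noise-induced mode at the origin —
is asserted by the test suite, not just narrated.

## Simulation and avalanche statistics

`simulate_lmn()` is a direct-method Gillespie sampler (compiled kernel for
built-in gain functions; an interpreted fallback for user-registered gains
draws from the RNG identically, so the two paths produce byte-identical
logs). Runs are reproducible from `(model, seed, t_end)` via R's Mersenne
Twister; the seed travels with every output.

Two avalanche definitions are provided:

* **Threshold-based** (`detect_threshold_avalanches()`): maximal half-open
  intervals on which the total active fraction is $\ge \theta$ (ties belong
  to the avalanche; the series is right-continuous, matching "at least 1
  out of 100 individuals"). Size = activation events inside the interval;
  fractional size divides by the current total $N$.
* **Bin-based** (`bin_avalanches()`): maximal runs of nonempty bins of
  width $\Delta$, the definition used for neural shape analysis. The NN
  analysis uses $\Delta = 4$ ms, derived from the printed 80,000,000 ms /
  20,000,000 bins. Runs touching the record boundaries are flagged
  truncated and excluded from statistics by default.

Size distributions are log-binned (50 bins/decade, empty bins dropped, not
zero-filled) and fit by OLS in log–log space over a stated range (default
$[\theta, 1)$: at most $N$ activations in a scale-free avalanche); the
adjusted $R^2$ of that line is the scale-freeness diagnostic, scanned
across sizes by `rsq_vs_omega()` with an optional degree-4 polynomial
smoother. Maximum-likelihood (Clauset-style) estimation is deliberately out
of scope: the replicated analysis is the regression one.

`size_duration_scaling()` regresses $\ln\langle S\rangle(T)$ on $\ln T$
over duration groups with at least 10 members. On long records of
near-critical models the scale-free cascade regime crosses over, at large
$T$, to rare up-state excursions whose mean size is *linear* in duration;
a fit across all durations then blends two regimes and drifts with the
record length. The optional `t_range` argument restricts the fit to the
scaling window; the shipped NN experiment uses 4–200 ms, the observed
crossover scale, which brackets the 60–76 ms durations used for shape
collapse. `shape_collapse()` multiplies each mean shape by $T^{1-\gamma}$,
rescales time to $[0,1]$ (shapes pinned to zero at both ends: no events
fire right before or after an avalanche), interpolates onto a common grid,
and scores the mean across-duration variance *normalized by the squared
span of the mean profile* — without that normalization a too-large
exponent would shrink all curves and spuriously lower the error. On exact
self-similar input the error is zero and any wrong exponent strictly
increases it; `synth_selfsimilar_avalanches()` generates such inputs
(optionally with Poisson noise) for the recovery tests.

## The two shipped models and their calibration

**SISa** (susceptible–infected–susceptible with spontaneous infection;
MRSA-style colonization, time unit days): $M = 1$, $\varphi(u) = u$,
$\psi = 0$, per-susceptible infection rate $a + \beta z$, recovery $g$.
The shipped numbers are *derived from printed constraints* rather than
transcribed (the source supplement was unavailable): $a = 10^{-4}$/day and
$N_0 = 200$ from the escape-time law $\tau(0) = 1/(Na)$ with the printed
200/286/500 days at $\Omega = 0.25/0.175/0.1$; $g = 0.055$/day placing the
ground-state crossing at the printed $\Omega_c = 0.175$; and $\beta$
calibrated so the macroscopic fixed point is exactly the printed 0.4719.
With mean colonization duration $1/g \approx 18$ days and transmission
$\beta \approx 0.104$/day these are epidemiologically plausible
magnitudes. Given the first two constraints, the sweep's recovery of
$\Omega_c$ and the bulk-modulus spike at the same location are genuine
outputs of the machinery, not inputs.

**NN** (two homogeneous populations of excitatory and inhibitory neurons,
1:1 by default, time unit ms): both populations see $u = h + w_E z_E -
w_I z_I$; activation rate $\text{leak} + \tanh^+(u)$, deactivation constant
$\alpha$. $\alpha = 0.1$/ms and the clipped-tanh response follow the cited
stochastic E/I modeling convention; $h = \text{leak} = 10^{-4}$/ms keep
quiescent firing sparse on the 4-ms bin scale; $(w_E, w_I) = (0.5, 0.2)$ is
balanced (the drive scale $w_E + w_I$ dominates the net gain $w_E - w_I$)
and places the critical size at $\Omega_c \approx 0.59$, inside the unit
sweep range. Note the E/I sign structure admits only the diagonal symmetry
$x^*_E = x^*_I$; full exchange symmetry of the law requires exchangeable
couplings (it holds exactly at zero coupling, where the stationary law is
the product binomial).

The scaled-down shape-collapse experiment runs the NN at $\Omega = 0.25$
(subcritical, near-critical — also the size used for the epidemic bursting
illustration) for $3\times 10^6$ ms instead of the full $8\times 10^7$ ms.
That yields $\ge 10^4$ avalanches and a size–duration exponent stable at
$1.450$–$1.456$ across seeds and horizons (adjusted $R^2 \approx 0.98$
over 50 duration groups), against the printed $1.4292$.

## What the synthetic data does and does not establish

All test inputs are generated: random small node-level networks with
block-constant parameters (for lumpability and oracle checks), random
positive distributions (for the thermodynamic identities), self-similar
avalanche sets with known exponent (for the recovery pipeline), and seeded
Gillespie runs of the two shipped models. A green suite therefore
establishes internal mathematical consistency — solver against closed
forms, identities to $10^{-9}$, generator-known truth recovered — and
reproduction of the printed constants under the calibrations stated above.
It does not establish that the shipped parameter values equal the original
study's unpublished ones, nor anything about real MRSA or cortical
recordings; fitting to data of that kind is out of scope.

## Numerical choices and limitations

* Probabilities below the LU noise floor are exact only on the GTH path
  (lattices $\le 4096$ states by default; raise `gth_cap` at cubic cost).
* Transient uniformization is accurate but not fast for very stiff, very
  long horizons; Krylov/uniformization hybrids are out of scope.
* Finite-difference pressures inherit grid noise where $I^*(\Omega)$ has
  integer-rounding steps; the bulk-modulus argmax is therefore the
  *secondary* critical-size detector.
* The node-level model is a validation oracle only ($N \le 12$).
* Event logs are kept in memory (a guard cap of $5\times 10^7$ events,
  overridable); truly unbounded streaming runs are not implemented.
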