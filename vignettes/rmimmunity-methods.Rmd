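---
title: "Modeling restriction-modification immunity across scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling restriction-modification immunity across scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmimmunity)
```

This vignette is the package's own account of the models it implements,
the assumptions behind them, the numerical choices made where the design
was genuinely open, and what the test suite does and does not establish
about real biological systems.

## The single-site methylation chain

A restriction site on the host genome is modeled as a continuous-time
Markov chain over three transient states — unmethylated (U),
hemi-methylated (H), doubly-methylated (D) — plus one absorbing state in
which the site has been cut and the cell is dead. Methylation adds methyl
groups at the total methyltransferase activity $m$ (U→H and H→D).
Replication at rate $\lambda$ removes them: a doubly-methylated site is
copied into two hemi-methylated sites (D→H at rate $\lambda$), and a
hemi-methylated site is copied into one hemi-methylated and one bare site,
so the tracked site turns unmethylated at rate $\lambda/2$. Cutting occurs
only from U, at the total endonuclease activity $r$, and is lethal (no
repair). The transient sub-generator and absorption vector are

$$
B = \begin{pmatrix} -(r+m) & m & 0 \\ \lambda/2 & -(m+\lambda/2) & m \\
0 & \lambda & -\lambda \end{pmatrix}, \qquad c_1 = (r, 0, 0)^\top ,
$$

with the state ordering (U, H, D) fixed everywhere in the package to match
the methylation-configuration vector $p_Q = (p_0, p_1, p_2)$. The waiting
time to a site's first cut is phase-type,
$f(\tau) = p_Q e^{B\tau} c_1$, with mean $-p_Q B^{-1}\mathbf{1}$.

Key modeling assumptions inherited from this construction: sites are
exchangeable and independent (no DNA-sequence context), enzyme activities
are constant totals (no expression noise within a cell), and restriction
is irreversibly lethal.

**Units.** All rates are min⁻¹ and all times minutes; there is no unit
conversion layer.

**Numerics.** The matrix exponential of the dense 3×3 generator is
computed with `Matrix::expm`; the quadrature oracles in the tests use
`stats::integrate`. Eigen-decompositions use base `eigen` on $B^\top$.
Tiny negative entries of the dominant left eigenvector (relative magnitude
below 1e-10) are clamped to zero and the vector renormalized; anything
worse is reported as a numerical failure rather than silently cleaned.

## Quasi-stationarity and population growth

In a growing population, replication constantly replenishes unmethylated
sites while self-restriction preferentially removes the cells that carry
them. The methylation state of a randomly chosen *surviving* cell
therefore relaxes to the quasi-stationary distribution (QSD) of the site
chain — the dominant left eigenvector of $B$, eigenvalue $\gamma_1 \le 0$.
Conditioned on survival the cut hazard is constant, so the per-site
waiting time is exactly exponential with rate $-\gamma_1$ and the per-cell
self-restriction rate is

$$\mu(r, m, \lambda) = -\gamma_1 N_S .$$

`self_restriction_rate()` computes $\mu$ from the eigenvalue and
cross-checks it against the inverse-mean form $N_S / E[\tau]$ evaluated at
the QSD. The cross-check tolerance is 1e-8 relative plus an absolute floor
of $32\,\varepsilon\,(r+m+\lambda)N_S$: dense eigensolvers deliver
eigenvalues to about machine epsilon times the matrix norm, so when
$\gamma_1$ sits ten or more orders below the largest rate (as it does
along the calibrated Pareto front, where $r \sim 10^3$ and
$\mu \sim 10^{-12}$–$10^{-3}$) a purely relative criterion is not
attainable and would abort legitimate sweeps.

The effective growth rate with $k$ equivalent, independent RM systems and
linear expression costs is
$\lambda_e = \lambda - k(\mu + c_r r + c_m m)$; negative values are legal
and describe shrinking populations. Degenerate inputs return well-defined
sentinels rather than raising: $r = 0$ gives $\mu = 0$, and $\lambda = 0$
gives $\mu = 0$ because a fully methylated genome never demethylates
without replication. This keeps boundary points of optimization sweeps
well-behaved.

A notable multi-scale effect, covered by the tests: because the QSD is
biased away from unmethylated configurations relative to the
absorption-free stationary law, the QSD-based $\mu$ is never larger than
the naive single-cell estimate, and $\mu$ grows faster than linearly with
$\lambda$ in the transition regime.

## The stochastic validation engine

`simulate_population()` is an exact Gillespie realization of the
agent-level process: every cell carries site counts $(n_U, n_H, n_D)$
summing to $N_S$, with per-cell channels U→H ($m\,n_U$), H→D ($m\,n_H$),
D→H ($\lambda\,n_D$), H→U ($\lambda n_H/2$), death ($r\,n_U$), and
division at $\lambda$ with the daughter copying the mother's
configuration. Cells with equal configurations are exchangeable, so the
C++ engine tracks counts per configuration — for $N_S = 5$ only 21 types —
which makes the exact simulation essentially free while remaining an exact
sample of the agent process.

Design choices that were open:

* **Demethylation as continuous channels** (the default,
  `"analytic-consistent"`) matches exactly the process the analytic
  generator describes, which is what a validation oracle must target. A
  `"mechanistic"` mode instead couples demethylation to division (each D
  site becomes H in both daughters; each H site is H in one daughter and U
  in the other, by a fair coin per site). It is provided for
  model-discrepancy exploration and carries no validation weight.
* **Population control** by uniform binomial subsampling to half the cap,
  with the log dilution factor accumulated so that the dilution-corrected
  log population remains an unbiased growth record.
* **Estimators**: $\hat\lambda_e$ is the least-squares slope of corrected
  log population versus time after a burn-in (default 20 % of the
  horizon, ample next to the site chain's ~30–100 min relaxation time);
  $\hat\mu$ is total deaths over total live-cell time; the QSD estimate is
  the time-averaged site-class occupancy. Standard errors come from a
  block bootstrap over 20 contiguous time blocks, which absorbs the
  autocorrelation of the event stream.
* **Initial state**: fully methylated cells, the natural state of an
  established genome; configurable.

Default problem sizes (`t_max` 20 000 min, `pop_cap` 2 000, 400 recording
intervals) give standard errors of a few times $10^{-5}$ min⁻¹ on both
rates at the reference regime — small enough that a 3-standard-error
comparison against the analytics is a meaningful test — and run in well
under a second.

## Phage escape and the first-escape law

Escape of a single infection is a race at each of the $N_V$ phage sites
between methylation and cutting, giving
$p_V = \left(m/(r+m)\right)^{kN_V}$, increasing in $m$, decreasing in $r$.
The boundary $r = m = 0$ is defined as $p_V = 1$ (no functioning system),
the continuity choice for sweeps that touch the origin.

With a constant phage population $v$, encounter rate $\rho$, and a host
population growing as $n(t) = n_0 e^{\lambda_e t}$, escape events form an
inhomogeneous Poisson process with rate $\rho v p_V n(t)$. The
first-escape time has the closed-form hazard integral
$\Lambda(\tau) = a(e^{\lambda_e \tau} - 1)/\lambda_e$ with
$a = \rho v n_0 p_V$, from which density, distribution function, quantile
(closed-form inverse) and inverse-transform sampler all follow. The
exponent is evaluated in log space (`expm1`/`log1p`) so that the
$\lambda_e \to 0$ limit is exact and extreme arguments underflow to zero
rather than overflowing. For $\lambda_e < 0$ the total mass is
$1 - e^{a/\lambda_e}$; quantile levels beyond it return `Inf`, meaning
escape never happens on that sample path.

The performance metrics use the time change $u = \int_0^t n(s)\,ds$, under
which escape and mutation both become homogeneous Poisson processes with
rates $\rho v p_V$ and $c_\text{mut}$. The closed forms
($n_s = \lambda_e/(\rho v p_V)$, mutation-first probability
$\tilde c/(\tilde c + p_V)$, expected mutation supply $\tilde c/p_V$ with
$\tilde c = c_\text{mut}/\rho v$) hold for $\lambda_e \ge 0$ — at
$\lambda_e = 0$ the time change is still a bijection onto $[0,\infty)$ —
so only shrinking populations ($\lambda_e < 0$) fall back to Monte Carlo,
flagged `regime = "non-growing"`; there, a path on which escape never
occurs contributes $n(\tau_p) = 0$ (the population has died out). All
three metrics are independent of $n_0$ by construction; the tests verify
this by Monte Carlo at $n_0 \in \{1, 10, 1000\}$.

Reporting convention: expected growth until escape is stated in units
fixing $1/(\rho v) = 1$ min, so `n_s` equals $\lambda_e/p_V$ numerically.

## The ecology reconstruction

The deterministic bacteria–phage module tracks RM-carrying bacteria $B$,
optional RM-free bacteria $B_0$, unmethylated phage $V_u$, and methylated
phage $V_m$, in a Levin–Stewart-style system with a logistic resource
surrogate (capacity $K$), mass-action adsorption $\delta$, instantaneous
burst $\beta$, and spontaneous inactivation $d_V$. This concrete system is
the package's own reconstruction: infection of an RM cell by unmethylated
phage is aborted (phage removed, host survives) except with probability
$p_V$, in which case the host lyses and releases a methylated burst; no
latent period is modeled. The qualitative conclusions drawn from the
module are robust to these details.

The solver is `deSolve::lsoda` with an absolute tolerance of 1e-30 so
that phage densities that are biologically extinct remain mathematically
positive — the point being that in an ODE description phage never reach
zero, and whenever $p_V > 0$ the methylated phage eventually outnumbers
the susceptible phage regardless of how efficient the RM system is. The
sweep helper records "takeover" as $V_m > V_u$ at the horizon. Two
consequences worth noting when designing sweeps:

* Grid cells with $\lambda_e \le 0$ collapse the host population, so no
  phage is produced at all and the takeover question is ecologically moot;
  the packaged sweeps therefore use activity grids on which
  $\lambda_e > 0$ throughout while $p_V$ still spans many decades.
* The takeover horizon at the packaged ecological parameters
  ($\delta = 10^{-9}$, $\beta = 50$, $d_V = 0.1$, $K = 10^9$) is about
  1 000 min; sweeps integrate to 1 500 min with a relaxed relative
  tolerance of 1e-6, which a direct comparison against a tight-tolerance
  integration shows is ample for the recorded outcomes. The packaged
  takeover-independence check uses a 50×50 activity grid — a desk-scale
  stand-in for a much denser exploration; because the takeover outcome is
  a monotone consequence of $p_V > 0$, grid density is not the limiting
  factor of that conclusion.

## Pareto optimality and the EcoRI calibration

`sweep_objectives()` evaluates $(\lambda_e, n_s)$ over log-spaced grids of
$(r, m)$ and a list of $k$; `pareto_front()` extracts the non-dominated
subset (maximize both) by a sort-and-sweep with a 1e-12 relative tie
tolerance, cross-checked in the tests against a brute-force $O(n^2)$
oracle. Points with $\lambda_e \le 0$ carry $n_s = 0$.

`optimal_activities()` solves the constrained problem: minimize $p_V$
subject to spending exactly the growth-reduction budget
$\lambda - \lambda_e^{\text{target}} = k(\mu + c_r r + c_m m)$. The search
is deterministic and nested — for each total activity $s = r + m$ the
budget equality pins the split by bisection ($\mu$ is monotone in the
split), and the outer problem over $\log s$ is solved by a coarse scan
plus golden-section refinement. No random initialization is used, so
results are bit-reproducible.

One genuine subtlety: the *continuous* problem has a degenerate boundary
optimum in which $m \to 0^+$ while $r \approx$ budget$/N_S$ (often
$\sim 10^{-6}$ min⁻¹), formally giving $p_V \to 0$ at almost no cost. It
is an artifact of the escape model being a pure rate race with no phage
replication timescale: a restriction activity of $10^{-6}$ min⁻¹ would
"cut" an infecting phage after roughly two years. Grid-based sweeps never
sample this corner because log grids have a positive floor on $m$; the
optimizer's default total-activity search range, $s \in [10^{-2}, 10^7]$
min⁻¹, plays the same role and confines the search to the biologically
meaningful branch. Users who widen `s_range` far below activities of
order $10^{-2}$ min⁻¹ should expect to find the artifact.

Two structural properties of the solutions, both covered by tests: along
the front interior the growth reduction splits equally between enzyme cost
and self-restriction (within 5 %), and the total cost falls linearly as
the target growth rate rises. Near the fast-growth end the optimizer
shuts the system down non-uniformly — the restriction activity collapses
first, since self-restriction must fall to half of a vanishing budget
while the methylation activity still carries the (equally vanishing) cost
share.

`calibrate_reference()` applies the optimizer at the EcoRI operating
point: $\lambda = 0.017$ min⁻¹, $N_S = 599$, $N_V = 5$, $k = 1$, equal
costs $c = 3.7\cdot 10^{-7}$, and a measured growth-rate reduction of
about $10^{-3}$ min⁻¹. The budget is interpreted as the *total* reduction
$\lambda - \lambda_e$ — the measured self-restriction dominated it and the
wild-type expression cost was below detection — and under this
interpretation the optimizer returns $r \approx 1.2\cdot 10^3$ min⁻¹ and
$m \approx 1.5\cdot 10^2$ min⁻¹, with the equal cost split emerging rather
than being imposed. The exact dominant eigenvalue is used for $\mu$
throughout; no approximation enters the calibration. How the cost value
$c \approx 3.7\cdot 10^{-7}$ itself would be pinned down is not modeled
here; it is an input.

## Named parameter regimes

`fixture_params()` provides the regimes used across examples and tests:

* `"reference"`: $r = 0.1$, $m = 0.05$, $\lambda = 0.017$ min⁻¹,
  $N_S = 5$ — inside the transition region where self-restriction
  materially slows growth ($\mu \approx 0.0067$ min⁻¹ of
  $\lambda = 0.017$). The small site count is an illustration-scale
  choice; real RM systems recognize hundreds of sites.
* `"small"` / `"large"`: the same with activities scaled $2e$-fold down
  and $e$-fold up — bracketing the transition region from the
  nearly-harmless and the well-protected sides.
* `"fig_sweep"`: $N_S = 599$, $N_V = 5$, cost $10^{-5}$ — the
  realistic-genome setting for front sweeps.
* `"ecoli"`: cost $3.7\cdot 10^{-7}$, budget $10^{-3}$ min⁻¹ — the
  calibration input.

## What the tests do and do not show

The synthetic data in this package are generated by its own stochastic
engines under the model's assumptions: exchangeable independent sites,
constant enzyme activities, constant phage pressure, well-mixed
populations without age structure or spatial structure. Passing tests
therefore establish internal correctness — the analytics, the samplers,
and the simulations agree with each other and with independent oracles at
stated tolerances — not that the model describes any particular organism.
Cell-to-cell variation in enzyme activities, restriction-site avoidance,
DNA repair, multi-species communities, and the evolution of site counts
are all outside scope. The ecology module in particular supports
qualitative conclusions (takeover, non-extinction) rather than
quantitative trajectories, since its concrete equations are a
reconstruction.
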