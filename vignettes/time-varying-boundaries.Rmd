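---
title: "Finding time-varying decision boundaries for diffusion models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding time-varying decision boundaries for diffusion models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvbounds)
```

## The model

Two-choice sequential-sampling models assume that evidence is sampled from a
stimulus, one piece every $\lambda$ seconds, until an accumulated tally
crosses a threshold and triggers the associated decision. `tvbounds` works
with the Wiener diffusion form of this idea: evidence samples are
$\mathcal N(\mu, \sigma^2)$, so in continuous time the tally $X(t)$ is a
Wiener process with drift $\xi = \mu / \lambda$ and infinitesimal variance
$s^2 = \sigma^2 / \lambda$. The decision boundaries $a_A(t) > 0 > a_B(t)$
may be arbitrary functions of time. The model maps
$(\mu, \sigma, a_A, a_B)$ to a decision probability and a pair of
*defective* response-time densities $g_A, g_B$ — each integrates to the
probability of its decision.

The free (no-boundary) transition density is Gaussian,
$$
f(x, t \mid y, \tau) = \frac{1}{\sqrt{2\pi s^2 (t-\tau)}}
  \exp\!\left(-\frac{(x - y - \xi(t-\tau))^2}{2 s^2 (t-\tau)}\right),
$$
and a renewal argument links it to the first-passage densities through a
pair of coupled first-kind Volterra integral equations: the density of
being at a boundary now is the density of having first hit either boundary
earlier and diffused back. Because $f$ is singular as $\tau \to t$, the
first-kind system is transformed into a second-kind system with the kernel
$$
\Psi(a(t), t \mid y, \tau) = \frac{f(a(t), t \mid y, \tau)}{2}
 \left(a'(t) - \frac{a(t) - y}{t - \tau}\right),
$$
which stays bounded along a smooth boundary: the bracket vanishes at the
same rate the density diverges. A point worth recording: for constant drift
the kernel carries *no* explicit drift term. The general kernel bracket is
$(a'(t) - \xi)/2 - (a(t) - y - \xi(t-\tau)) / 2(t-\tau)$, and the two
$\xi$ contributions cancel algebraically, leaving the expression above. We
verified this both symbolically and against the oracles below.

## The forward solver

`solve_fpt()` steps the second-kind system on the sampling grid
$t_n = n\lambda$ with the composite trapezoidal rule. Two properties make
the stepping explicit rather than implicit:

* the first-passage densities vanish at $t_0$, so the left quadrature
  endpoint contributes nothing;
* the diagonal kernel value $\Psi(a(t), t \mid a(t), t)$ is the analytic
  limit $0$ for boundaries of bounded curvature (the bracket is
  $O(t-\tau)$ while the density is $O((t-\tau)^{-1/2})$), and the
  cross-boundary diagonal term vanishes faster still (the density is
  Gaussian in $1/(t-\tau)$), so the right endpoint also contributes
  nothing.

Per-step decision masses follow the convention $P_{X,n} = g_X(n\lambda)\,
\lambda$. The raw quadrature masses are reported as computed; the
trapezoidal rule can overshoot a total mass of 1 by $O(\lambda^2)$, and we
deliberately do not rescale, because rescaling injects a small systematic
bias into every per-step mass that round-trip inversion is sensitive to.

Correctness is anchored to two independent oracles rather than to
transcription of any particular printed discretization:

* `analytic_fpt_constant()` — the classical infinite-series solution for
  constant boundaries $\pm a$ (truncated at term size $10^{-12}$), with the
  closed-form absorption probability as a second check. The solver matches
  the series to better than $10^{-3}$ in sup-norm on per-second densities
  across all exercised regimes ($\mu \in \{0, 0.01, 0.05\}$,
  $\sigma \in \{0.1, 0.12\}$, $\lambda = 0.01$), and to near machine
  precision for constant boundaries, where the self-interaction kernels
  vanish identically.
* `simulate_paths()` — Monte Carlo. The plain discrete random walk is *not*
  a faithful oracle for the continuous diffusion: it only checks the
  boundary at grid times and misses within-step crossings, a bias of order
  $\sigma\sqrt{\lambda}$ (about half a grid cell of evidence here). The
  simulator therefore applies the exact Brownian-bridge crossing
  probability $\exp(-2(a_0 - x_0)(a_1 - x_1)/\sigma^2)$ within each step
  by default (`bridge = FALSE` recovers the plain walk). With the
  correction, a $10^6$-trial simulation agrees with the solver to
  Kolmogorov–Smirnov distance well under $2/\sqrt{n}$.

When comparing the solver with binned Monte Carlo output, the solver's
cumulative curves are formed by trapezoidal integration of the densities:
the right-endpoint convention $g(n\lambda)\lambda$ differs from a true bin
integral by $\tfrac{\lambda}{2} g$, which is a convention mismatch, not an
error, and would otherwise dominate the comparison.

## The inverse problem

`invert_boundaries()` recovers the boundaries that generate a given
defective distribution, stepping through the grid and solving, at each
step, the equation $g_X(n)\lambda = P_{X,n}$ for the boundary level at that
step, given all previously fixed levels. The candidate levels span
$(0, \text{start}]$ in $I$ cells (default $I = 100$, increment
$l = 0.01$ for unit starts); because the boundaries scale with $\sigma$
without changing shape, an unbiased process can fix the starting values at
$\pm 1$ without loss of generality. Two implementation choices matter:

* **Sub-grid root polishing.** The grid search brackets the solution; where
  the bracketing cells show a sign change of $q(c)\lambda - P$, we solve
  the same equation to machine precision with a root finder and commit the
  polished level together with its own density. The grid is a search
  device; the equation is the method. Without polishing, the half-cell
  snapping errors feed back through the kernel history and compound
  geometrically, and the recovered boundary leaves the truth within a few
  tens of steps. With it, forward-then-invert round trips recover constant
  and exponentially collapsing boundaries to near machine precision across
  the entire region holding 95% of the decision mass.
* **Target renormalization.** Targets whose mass is clearly truncated
  (total below 0.999) are renormalized to 1, and the truncation recorded.
  Targets already within quadrature tolerance of 1 are left untouched, for
  the same reason the solver does not rescale.

The per-step recursion is nonetheless *exponentially unstable* at late
times: once the remaining decision mass is small, boundary perturbations
that leave every per-step probability essentially unchanged exist, and
rounding noise grows by a factor of roughly 2–4 per step along them. The
point-wise phase therefore has a finite horizon of validity, as the
corrective phase below anticipates. The critical step is detected as the
earliest of three observable signals: (i) the regenerated distribution
deviates from the target by more than 10% of the step's mass (floor
$10^{-5}$) on two consecutive steps, not counting steps whose level is
pegged at the candidate cap (an out-of-range target step has a constrained
optimum there, which is not a failure); (ii) the boundary jumps inward by
more than 10% of its starting level in one step while target mass remains
(the signature of collapse); (iii) the levels stop agreeing, within half a
grid cell, with a shadow run whose target is perturbed at relative
$10^{-12}$ — i.e. they are no longer numerically reproducible.

`piecewise_refine()` rebuilds everything beyond the critical step as a
connected piecewise-linear curve, each segment 2–3 steps long. Segment
endpoints are chosen by direct search over the candidate grid augmented
with the incumbent value (so a segment can never end worse than it
started), followed by a continuous polish within one grid cell; the
objective is the summed absolute deviation between regenerated and target
per-step masses over the segment plus a one-segment lookahead in which the
boundary continues at the segment's slope. The lookahead prevents a
segment from buying local fit by dumping mass that the following steps
will then miss. Segments are committed left to right, so the total
objective never increases across segments, and the refined tail is kept
only if it beats the unrefined one. Once the remaining target mass falls
below $10^{-4}$ the boundary is held flat: every remote level generates
the same negligible mass there, and free segments would only chase
quadrature noise.

`invert_symmetric()` constrains $a_A(n) = -a_B(n)$ and minimizes the
combined deviation $|q_A\lambda - P_{A,n}| + |q_B\lambda - P_{B,n}|$ with
a single level per step. Ties in all grid searches break toward the
smaller candidate index (the level closest to zero), making the whole
inversion deterministic. Boundary monotonicity is deliberately *not*
enforced; recovered boundaries may be locally non-monotone.

## Equating accumulator and diffusion models

The accumulator (race) model keeps two separate non-decreasing tallies fed
by the same Gaussian samples: a positive sample adds to tally A, a
negative one adds its magnitude to tally B, and the first tally to reach
the criterion $K$ wins. `accumulator_fpt()` computes its defective
distributions by propagating the joint sub-threshold mass on a 2-D grid,
with increments discretized by CDF differences (which conserves mass
exactly), anchored to a trial-level simulator (`accumulator_simulate()`).
The criterion is never stated numerically in the source analyses; only
$K/\sigma$ matters by the scaling property, and the default $K = 1$ pairs
naturally with diffusion starting boundaries $\pm 1$.

`equate_models()` composes the recursion with the inversion. Across the
four evidence distributions exercised in the tests
($\mu \in \{0.01, 0.05\} \times \sigma \in \{0.1, 0.12\}$), the diffusion
process with the inferred time-varying boundaries reproduces the race
model's choice probabilities and RT distributions with total-variation
distance 0.002–0.018, on decision probabilities ranging from near 50% down
to below 1%. The inferred boundaries collapse toward zero and are
asymmetric whenever $\mu > 0$; for $\mu = 0.05, \sigma = 0.1$ the lower
boundary reaches zero well before the upper one. One structural limit is
worth knowing: at the very first steps the diffusion with boundaries
capped at the starting values produces slightly *more* early decision mass
than the race (the equivalent boundary would need to start above the cap),
which contributes a small irreducible part of the total-variation
distance. Constraining the boundaries to be symmetric still mimics the
race closely at $\mu = 0.01$ (TV $\approx 0.02$–0.023) but measurably
worse than the unconstrained fit at $\mu = 0.05$, while preserving skew
direction and the ordering of the two alternatives' mean response times.

The discrete ancestor of this equivalence is exact and is verified
exhaustively: for $\pm 1$ evidence increments, a race to $K$ favorable
samples is path-for-path identical to a random walk absorbed at boundaries
that start at $\pm 2K$ and decrease by one unit per step
(`enumerate_race()` / `enumerate_walk_collapsing()`, all $2^{10}$ sign
sequences).

## The empirical pipeline

For stimuli that objectively favor neither alternative, the drift is fixed
at zero and `fit_boundaries_empirical()` runs the full chain: shift the
response times by the smallest observed value minus a 1 ms guard (a crude
but standard stand-in for non-decision time), fit a two-parameter Weibull
per alternative by maximum likelihood (via `fitdistrplus`), discretize the
fitted distributions into per-step targets
$P_{X,n} = p_X\,[F_X(n\lambda) - F_X((n-1)\lambda)]$ at
$\lambda = 0.01$ s, and invert. Raw binned data are never inverted
directly: the point-wise recursion amplifies the multi-modality of
histograms, and the Weibull smoothing step is what makes the inversion
stable. Fit quality is assessed by Pearson chi-square on the fitted
distribution's deciles with $10 - 1 - 2 = 7$ degrees of freedom.

The assumed per-sample evidence distribution is $\mathcal N(0, 0.01)$,
read as standard deviation $\sigma = 0.01$ (the reading is exposed as an
argument, since the variance reading is also defensible). With the
evidence scale assumed rather than known, the boundary starting values
become free parameters, searched on a geometric grid (20 values per side
by default) around the scale heuristic $s\sqrt{\bar T}$ — for a zero-drift
process absorbed at $\pm a$, $E[T] = a^2/s^2$. Candidates are ranked by
the achieved-vs-target distance of a fast unpolished inversion, and only
the winner is re-inverted with polishing and refined; refining every
candidate would not change the selected optimum.

Two honest limitations, both visible in the tests:

* **The start values are weakly identified.** With every later level free,
  the polished inversion reproduces the smoothed target almost exactly for
  a wide range of start values, so the distance criterion nearly ties and
  the selected start can sit tens of percent from the generating value.
  The boundary *shape* over the region carrying the decision mass is what
  the data determine: in end-to-end recovery from $10^4$ trials of a known
  zero-drift collapsing diffusion, the recovered and true boundaries
  correlate above 0.98 over the central 90% of mass.
* **The min-RT shift is biased.** The smallest observed response time
  exceeds the true non-decision time by the smallest first-passage time in
  the sample (~50 ms in the recovery setting), compressing the recovered
  time axis accordingly. This is a property of the procedure, acknowledged
  as an approximation in its source, not of the implementation.

On the decile chi-square: with shape and scale estimated by maximum
likelihood from the ungrouped data, the statistic's true null distribution
lies strictly between $\chi^2_7$ and $\chi^2_9$ (the classical
Chernoff–Lehmann bracket), so p-values computed at the conventional
$\mathrm{d.f.} = 7$ are not exactly uniform under the true model — across
1,000 replicates their empirical CDF sits 0.07–0.09 from uniform at its
farthest point, enough for a Kolmogorov–Smirnov test at $n = 1000$ to
notice, while the test's size at conventional $\alpha$ levels stays near
nominal. We keep $\mathrm{d.f.} = 7$ because it is the field's convention
and what published worked examples use; the calibration caveat is the
price of that convention.

## What the synthetic generators do and do not emulate

`simulate_weibull_rts()` draws shifted-Weibull response times with a
choice probability — the shape assumed by the empirical pipeline itself —
with defaults (2,000 trials, shape 1.8, scale 0.35 s, shift 0.3 s)
matching an individual subject's accuracy-condition data: unimodal,
right-skewed, decisions within roughly 0.3–1.5 s.
`simulate_diffusion_rts()` draws from a known boundary-diffusion ground
truth for recovery checks. Neither emulates trial-to-trial parameter
variability, contaminant responses, lapses, or condition mixtures; passing
recovery tests therefore show that the chain of estimators inverts its own
assumptions faithfully, not that those assumptions hold for any particular
real dataset.

## Numerical choices at a glance

* Sampling step $\lambda = 0.01$ s throughout the worked analyses; horizons
  chosen so the undecided mass is below $10^{-3}$.
* Candidate grid $I = 100$ cells per side; sub-grid polishing to machine
  tolerance; ties to the smaller index.
* Critical-step tolerance: 10% of the step's target mass, floored at
  $10^{-5}$, two consecutive steps.
* Refinement: segments of 3 steps (2 supported), three coordinate-descent
  sweeps, slope-continuation lookahead of one segment, tail frozen once
  remaining target mass falls below $10^{-4}$.
* Accumulator state grid: 200 cells per tally (cell width must not exceed
  $\sigma/2$); increments discretized by CDF differences.
* Degenerate boundaries (upper meets lower) truncate the solve with a
  warning; remaining mass is assigned at the touch step to the boundary
  nearest the expected surviving position.
* All stochastic components take a single integer seed and restore the
  caller's RNG state.

## A worked example

```{r example, eval = FALSE}
# boundaries that make a diffusion equivalent to a race model
eq <- equate_models(acc_spec(mu = 0.05, sigma = 0.1), inversion_config())
glance(eq)
autoplot(eq)

# empirical-style pipeline on synthetic data
d <- simulate_weibull_rts(2000, p_choice = 0.55, seed = 7)
res <- fit_boundaries_empirical(d, n_start = 10)
res$gof
autoplot(res)
```
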