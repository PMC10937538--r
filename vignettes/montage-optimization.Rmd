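---
title: "Designing multichannel tES montages by L1-fitted, L1-penalized linear programming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multichannel tES montages by L1-fitted, L1-penalized linear programming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tesmontage)
```

## The optimization problem

Transcranial electrical stimulation injects a weak current pattern
$\mathbf{y}$ (mA) through $L$ scalp electrodes; a lead field matrix
$\mathbf{L}$ maps it linearly to the volumetric current density (A/m²) at
discretized brain locations, three Cartesian components per node. Given a
target location and direction, the rows of the system split into a
*focused* block $\mathbf{L}_1$ — the projection of the target node's
components onto the desired direction — and a *nuisance* block
$\mathbf{L}_2$ holding everything else. The montage should reproduce a
target density $\mathbf{x}_1$ (norm 3.85 A/m², an approximation of the
motor-axon excitation threshold) on the focused block while keeping the
nuisance field small and the currents safe.

The package solves

$$
\min_{\mathbf y}\;
\bigl\lVert \mathbf L_1\mathbf y-\mathbf x_1 \bigr\rVert_1
+\sum_{m=1}^{M}\max\{\lvert\nu^{-1}(\mathbf L_2\mathbf y)_m\rvert,\,\varepsilon\}
+\alpha\,\zeta\,\lVert\mathbf y\rVert_1
\quad\text{s.t.}\quad
\lvert y_\ell\rvert\le\gamma,\;
\lVert\mathbf y\rVert_1\le\mu,\;
\textstyle\sum_\ell y_\ell=0,
$$

with $\zeta=\lVert\mathbf L\rVert_1$ and $\nu=\lVert\mathbf x\rVert_\infty$
fixed scalings of the system. The two hyperparameters are the L1
regularization weight $\alpha\ge 0$ and the nuisance threshold
$\varepsilon\in[0,1]$: nuisance components below $\varepsilon\nu$ in
magnitude sit on the threshold floor and stop influencing the
minimization (the indices above it form the *constraint support*). The
safety constants default to $\gamma = 2$ mA per channel and $\mu = 4$ mA
of total dose, with zero net current always enforced.

`build_l1l1_lp()` encodes this as a linear program by the epigraph
construction: majorants $t$ (fit residuals), $r$ (nuisance magnitudes,
bounded below by $\varepsilon$) and $u$ (channel magnitudes) give
$2L+T+M$ variables and paired $\pm$ inequality rows. The
$\sum_m r_m \ge M\varepsilon$ floor contributes an additive constant
region only — it never moves the argmin — but the reported objective keeps
it, so printed objective values are comparable across
$(\alpha,\varepsilon)$. Variable splitting ($y = s - p$) would be the
standard alternative encoding; the epigraph form was chosen because it has
fewer variables and carries the channel bounds directly.

Montages are scored by the intensity
$\Gamma=\mathbf x_1^{\!\top}\mathbf L_1\mathbf y/\lVert\mathbf x_1\rVert_2$
(A/m², the achieved density along the target) and the focality
$\Theta=\Gamma\,/\,(\lVert\mathbf L_2\mathbf y\rVert_2/\sqrt M)$
(intensity per unit RMS nuisance density). A montage that silences the
nuisance field exactly while hitting the target has $\Theta=\infty$; the
package returns that sentinel rather than clamping.

## The reciprocity reference and the metacriterion

$\Gamma$ is linear in $\mathbf y$: $\Gamma(\mathbf y)=\mathbf b^{\!\top}
\mathbf y$ with $\mathbf b=\mathbf L_1^{\!\top}\mathbf x_1/\lVert\mathbf
x_1\rVert_2$ the *back-projection* of the target through the lead field.
Over the safety set (zero sum, dose $\mu$, channel cap $\gamma\ge\mu/2$)
this linear functional is maximized by the bipolar pair $+\mu/2$ at
$\arg\max_\ell b_\ell$ and $-\mu/2$ at $\arg\min_\ell b_\ell$ —
the reciprocity-principle montage. `bipolar_maximizer()` implements this
rule, and the test suite verifies it against direct LP maximization of
$\mathbf b^{\!\top}\mathbf y$ on dozens of seeded systems.

The classical restricted-$K$ formulation ($s_K$, $\sigma_K$,
$\Gamma_K=\mu\sigma_K\lVert s_K\rVert_2^2$) is available in
`restricted_montage()` as a diagnostic. Two caveats a user should know.
First, $\mu s_K$ does not generally sum to zero for $K \ne 2$, so it is
not a deliverable montage; the zero-sum bipolar rule is the package's
reference maximizer. Second, $\Gamma_K$ is *non-increasing* in $K$
(appending a weaker electrode dilutes the dose:
$\Gamma_K = \mu\,\Sigma v^2/(\lVert\mathbf x_1\rVert\,\Sigma v)$ over the
$K$ largest absolute back-projections $v$), which is what the per-$K$
table of `reciprocity_report()` shows and the tests assert.

Focality maximization needs a guard: without a lower bound on intensity
the focality maximizer drifts toward vanishing currents. The
*metacriterion* $\Gamma \ge \Gamma_0$ with
$\Gamma_0 = 0.75\,\Gamma_{\max}^{\text{bipolar}}$ (the fraction is
configurable) restricts focality maximizers to lattice points that retain
at least three quarters of the bipolar intensity ceiling.

## Hyperparameter search on the dB lattice

Both hyperparameters live on decibel axes — $\alpha$ on $[-100,-20]$ dB,
$\varepsilon$ on $[-160,0]$ dB — with the amplitude convention
$x = 10^{\mathrm{dB}/20}$, chosen so that the 0 dB endpoint maps exactly
onto $\varepsilon$'s upper bound 1 (a power-convention switch,
divisor 10, is exposed as `db_divisor`). Three strategies share one
evaluator interface:

* `exhaustive_search()` evaluates the full $\kappa\times\kappa$ Cartesian
  lattice ($\kappa^2$ solves; $\kappa=15$ gives 225, $\kappa=40$ gives
  1600).
* `direct_search()` is a generalized pattern search: poll the four
  orthogonal neighbors at per-axis window distances (initially half each
  axis range), move to the best strictly improving neighbor, halve the
  windows when none improves, stop below `min_window` (range/256) or at
  `max_iter` polls. Polls falling outside the space are clipped to it.
  Cost: $1+4\cdot\text{polls}$ solves.
* `recursive_search()` lays a $\tilde K\times\tilde K$ grid over the
  space, then re-grids a sub-rectangle centered on the incumbent best
  with per-axis half-width equal to one grid step of the previous level,
  clipped to the original space, for $M$ levels: $M\tilde K^2$ solves
  (27/75/147/243 for $\tilde K = 3,5,7,9$ at $M=3$), versus $\kappa^2$
  for the exhaustive grid.

Design notes. The recursive method's printed window/step recurrences in
its block-matching ancestry are internally inconsistent as usually
typeset; the grid-renesting form above is the interpretation that
reproduces both the advertised evaluation counts and the
$O(M\tilde K^2)$ workload, and it makes level bests monotone by
construction when $\tilde K$ is odd (the incumbent is re-evaluated at the
center). Direct search uses best-improvement polling with strict
improvement, which keeps it deterministic; on a separable concave
objective a failed poll certifies the pivot is within half a window of
the optimum per axis, so termination below `min_window` brackets the
optimizer to that precision.

Every search logs each evaluation (its record, status, and montage) and
reports the $\Gamma$- and $\Theta$-maximizers, the latter only over
metacriterion-passing records — when nothing passes, the result carries
an explicitly empty focality maximizer rather than silently relaxing the
floor.

The lattice-induced uncertainty of a maximizer is estimated by
`taylor_deviation()`: finite differences on the lattice give the gradient
and Hessian at the maximizer, and the reported deviation is the largest
second-order change within the half-cell
$\{\pm h_\alpha/2\}\times\{\pm h_\varepsilon/2\}$ — what a lattice of
twice the resolution could reveal. For quadratic surfaces the estimate
is exact; boundary maximizers fall back to one-sided differences with a
warning.

## The two-stage procedure

`two_stage()` mirrors practical montage workflows on multichannel
stimulators with a limited channel count:

1. **Stage 1** runs the chosen search over the full cap with the
   intensity objective. Each electrode is scored by the largest absolute
   current it carries across the metacriterion-passing evaluations (a
   deterministic reading of "contributes the most"; ties break by
   electrode index), and the `n_active = 20` top-scored electrodes are
   kept. The incumbent best montage is rescaled to the full dose
   ($\lVert\mathbf y\rVert_1=\mu$; zero-sum patterns then respect
   $\gamma \ge \mu/2$ automatically).
2. **Stage 2** rebuilds the focused system over the kept electrodes only
   and re-runs the search with the final objective — intensity or
   focality, switchable after the fact. The winning montage is
   thresholded: channels below $10^{-3}\mu$ are zeroed and each sign side
   is scaled down to the smaller side's total, which restores an exactly
   zero net current without ever increasing a channel or the dose.

The intensity floor for stage 2 remains the one computed on the *full*
cap: the restriction cannot raise the bipolar ceiling, so this is the
stricter, reference-preserving choice. If no stage-1 evaluation passes
the floor, scoring falls back to all feasible evaluations with a warning;
fewer than two electrodes ever active is a hard error.

## The LP solver layer

No LP solver ships with the R installation this package targets, and the
algorithm-class comparison is part of the package's scope, so the layer
is self-contained with three backends behind `solver_spec()` /
`solve_lp()` and a registry (`register_solver()`) that accepts external
ones:

* **interior-point** — a Mehrotra predictor–corrector primal–dual method
  on the slack-augmented standard form, normal equations by Cholesky with
  jitter escalation, preceded by Ruiz inf-norm equilibration (the montage
  LPs mix magnitudes from $10^{-8}$ threshold floors to unit bound rows).
  Convergence is declared at relative primal/dual residuals and
  complementarity below `tol` ($10^{-8}$); when the endgame hits the
  numerical floor first, the best iterate is accepted down to a $10^{-7}$
  merit, and anything worse is reported as a failure status, never as a
  solution.
* **primal-simplex** — a two-phase dense-tableau simplex with Dantzig
  pricing and a Bland fallback against cycling.
* **dual-simplex** — starts from the all-slack basis of the inequality
  form, which is dual-feasible for the montage LPs (all costs
  nonnegative); general problems with negative costs gain dual
  feasibility through one pivot on a big-M aggregate bound row.

Every `status = "optimal"` report is re-checked against the original
constraints independently of the solver; violations beyond 10× the
tolerance downgrade the status. Iteration caps, infeasibility (including
a presolve check for contradictory bounds), and unboundedness surface as
explicit statuses, and `compare_backends()` sweeps instance families
across backends, flagging any optimal pair whose objectives disagree by
more than $10^{-6}$ relative. Wall-clock time is recorded for interest
but intentionally drives no test or decision — it is hardware-bound.
On a small seeded lattice roughly 1 evaluation in 200 still ends in a
failure status at extreme $(\alpha,\varepsilon)$ corners; these are
reported in the trace as such, which mirrors how solver studies on this
problem behave, and the searches simply skip them.

## The synthetic head model

Real lead fields come from segmented MRI and finite-element solvers with
calibrated conductivities; none of that is desk-reproducible, so the
generator builds a transparent stand-in: electrodes from a built-in
128-entry 10-10 table placed on the unit sphere by the
azimuthal-equidistant convention (the classic 10-20 sites first, then the
remaining 10-10 and 10-5 intermediate rows), nodes sampled quasi-uniformly
in the concentric ball of radius `inner_radius = 0.82` (the brain
compartment; defaults of 128 electrodes and 563 nodes mirror a realistic
study), and per-electrode point-monopole kernels
$J(p;e)=(p-e)/(4\pi\lvert p-e\rvert^3)$, all scaled by one fixed constant
(0.65) chosen once so that a mid-depth target's bipolar intensity is of
order 0.1 A/m² at the 4 mA dose — the magnitude realistic models produce
near threshold. Nodes falling within 0.02 head radii of an electrode are
rejected and resampled.

What the stand-in reproduces: linearity, smooth distance decay, a
plausible intensity scale, and the full pipeline's behavior over it. What
it does not: tissue conductivity contrasts, boundary conditions, and the
reciprocal voltage structure of a bounded head. One visible consequence:
with homogeneous monopole kernels the two *largest-magnitude*
back-projections often sit on the same side of the target (the nearest
electrodes dominate), so the textbook "first two entries of the
reciprocity ordering" rule coincides with the true constrained maximizer
only for favorable (tangentially oriented) targets; the package's
zero-sum $\arg\max/\arg\min$ rule is correct in both cases and is what
everything else references. Passing tests on this generator therefore
validate the optimization machinery, not any clinical claim about real
heads.

Tangential components at target nodes are assigned to the nuisance block:
only flow along the prescribed direction is "focused", and off-direction
flow at the target is as unwanted as flow elsewhere. Multi-node targets
share the amplitude with equal weights normalized to
$\lVert\mathbf x_1\rVert_2$.

## Numerical choices and problem sizes

Ties in electrode scoring and in $\arg\max/\arg\min$ selections break by
lowest index; search maximizers keep the first-evaluated of equal values;
strict improvement is required in pattern search. Degenerate inputs are
governed by explicit contracts: empty nuisance blocks are allowed but
flagged, $\Theta$ with zero nuisance returns the infinity sentinel, an
all-equal back-projection yields a degenerate bipolar result with
$\Gamma_{\max}=0$.

The bundled test suite and the acceptance script run on reduced problem
sizes chosen to exercise every code path at interactive speed: systems of
16–32 electrodes with 20–40 nodes for lattice work (a 15×15 lattice is a
few hundred interior-point solves of ~200-row LPs), 10–14 electrodes for
the 50-system reciprocity oracle and the 20-instance cross-backend
family, and the full 128/563 default only where a single construction is
needed. The acceptance script reports, per seed: the bipolar ceiling, the
exhaustive/recursive/direct maximizers and their workload counts, the
two-stage montage's intensity, focality, dose, and channel count, and the
cross-backend agreement spread.

## Limitations

* The spherical monopole generator is a stand-in; nothing here validates
  clinical dosing.
* The dense-tableau simplex backends are appropriate for the desk-scale
  LPs they serve (hundreds of rows); the interior-point backend is the
  default and scales further, but a 128-electrode, 563-node lattice
  search is a batch job, not an interactive call.
* The dB convention (20 vs 10) is a modeling switch the literature leaves
  undefined; results quoted in dB must state it.
* At extreme hyperparameter corners individual solves can end in a
  failure status; traces record them and downstream summaries exclude
  them explicitly.
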