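---
title: "Methods: semi-quantitative regulatory-network simulation in rnmsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-quantitative regulatory-network simulation in rnmsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rnmsim` models a signed, directed protein-interaction network — here the
soluble-factor regulation of nucleus pulposus cells (NPC) in the
intervertebral disc — as a system of ordinary differential equations
obtained by fuzzy-logic interpolation of Boolean rules. This vignette
records the model, its assumptions, the numerical and design choices, and
what the synthetic fixtures do and do not establish.

## The model

Each node $n$ carries an activation level $x_n \in [0,1]$, a normalised
pseudo-concentration, not a physical concentration. Regulated nodes follow

$$\frac{dx_n}{dt} = A(\omega_n) - \gamma_n x_n,$$

a sigmoid production term driven by the aggregate regulator input
$\omega_n$, balanced by first-order decay. The aggregate input uses the
classic fuzzy-logic composition: with activator sum
$s_a = \sum_k \alpha\, x_{a_k}$ and weight $W_a = \sum_k \alpha$ (inhibitors
analogous),

* only activators: $\omega = \frac{1+W_a}{W_a}\cdot\frac{s_a}{1+s_a}$,
* only inhibitors: $\omega = 1 - \frac{1+W_i}{W_i}\cdot\frac{s_i}{1+s_i}$,
* both: the product of the two factors.

Each factor is a saturating, monotone map of the regulator levels into
$[0,1]$; the product form makes any fully active inhibitor set veto any
activator set ($\omega \to 0$), the behaviour expected of dominant
inhibition. The result is clipped to $[0,1]$ against floating-point
rounding.

The activation response is the gain-$h$ sigmoid

$$A(\omega) = \frac{-e^{0.5h} + e^{-h(\omega-0.5)}}
                   {\bigl(1-e^{0.5h}\bigr)\,\bigl(1+e^{-h(\omega-0.5)}\bigr)},$$

with a *product* in the denominator. The two denominator factors are
sometimes typeset as a sum in the literature describing this model family;
only the product form satisfies the anchor identities $A(0)=0$,
$A(0.5)=0.5$, $A(1)=1$ on $[0,1]$, so the product form is what the package
implements and what the test suite pins down. `activation_response()`
evaluates an algebraically equivalent form (numerator and denominator
divided by $e^{0.5h}$, using `expm1`) that avoids overflow for large gains;
beyond roughly $h = 100$ the function saturates to machine precision at the
extremes, which is why the strict-monotonicity tests run at
$h \in \{0.5, 1, 10, 50\}$ and the steep-gain test only asserts
non-decrease.

### Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `h` | sigmoid gain (dimensionless) | 10 | steep enough to be switch-like, smooth enough for stable integration |
| `gamma` | decay rate (per model time unit) | 1 | sets the time scale; with $A \le 1$ it also bounds $x$ by 1 |
| `alpha`, `beta` | activator/inhibitor weights | 1 | uniform weights; the composition is monotone regardless of their value |
| `t_end` | integration horizon | 30 | typical convergence horizon for these systems |
| `t_max` | extension cap | 300 | ten horizons before declaring non-convergence |
| `ss_tol` | steady-state threshold on $\max_n |dx_n/dt|$ | 1e-6 | comfortably below any biologically meaningful level difference |
| `rel_tol`/`abs_tol` | integrator tolerances | 1e-6 / 1e-8 | an order below `ss_tol` |

Model time is artificial: no mapping to physical seconds is attempted, and
none of the analyses depend on one.

### Input nodes and clamping

A node with no regulators has no defined $\omega$. Letting it decay to zero
would silence every root of the network, contradicting the way sustained
stimulation experiments are run, so input nodes *hold their initial value*
(an implicit clamp) and `integrate_to_steady_state()` warns once about
them. Clamped nodes are handled exactly: their coordinates of the initial
state are overwritten with the clamp value and their derivatives are held
at zero, so there is no solver chatter around the constraint and the
clamped value is exact at every output time.

### Integration

The default integrator is the adaptive Runge–Kutta 4(5) pair
(`deSolve::ode(method = "ode45")`); a fixed-step classical RK4 at
`rk4_dt = 0.01` is provided as a cross-check mode, and the suite asserts
the two agree within $10^{-4}$ per coordinate on the toy motifs. If the
steady-state criterion is not met at `t_end` the horizon is extended in
`t_end`-sized chunks up to `t_max`; the final state is flagged converged or
not, and unconverged runs are never silently dropped anywhere downstream.
Forward invariance of $[0,1]^n$ holds analytically ($dx_n/dt \ge 0$ at
$x_n = 0$ and $\le 0$ at $x_n = 1$ when $\gamma = 1$); solver rounding is
trimmed by clipping to the cube.

## Baseline ensembles

The baseline protocol integrates `n_runs = 100` initial conditions drawn
uniformly from $[0,1]^n$, run $k$ using its own Mersenne-Twister stream
seeded `seed_base + k − 1` (seeds 0..99 by default). This makes every run
individually reproducible and the whole ensemble bit-reproducible, which
the acceptance tests assert.

Steady states are grouped into attractors by single-linkage clustering
under the Chebyshev (max-coordinate) metric with tolerance 0.01: two states
are the same attractor if no coordinate differs by more than 1% of the
activation scale along a connecting chain. The tolerance is a package
choice (no canonical value exists) and is exposed as `cluster_tol`. The
dominant-attractor fraction is the largest cluster's share of *all* runs,
so unconverged runs count against dominance; they are excluded from
clustering and reported separately.

## Perturbation, rescue, and comparison

Perturbations start from the baseline's steady states, not from fresh
random states: run $k$ of the perturbed ensemble continues run $k$ of the
baseline with the clamp set applied, pairing the ensembles run-by-run.
Rescue experiments first equilibrate the degenerate clamp set (e.g. TNF = 1,
or TNF and IL-1β co-stimulation as one set), then layer the rescue clamps
on the degenerate steady states (`mode = "sequential"`, the default;
`"simultaneous"` applies both sets at once from the healthy baseline). A
rescue clamp on a node the degenerate set also clamps overrides the
degenerate value — stimulating a factor the degenerate state held low is
precisely the point of a rescue.

Node-wise comparison uses the two-sided Mann–Whitney U test with
$U = \min(U_1, U_2)$: the exact null distribution when
$\min(n_1, n_2) \le 20$ with no ties, and the normal approximation with tie
correction otherwise; $\alpha = 0.05$, with no multiple-testing correction
(each node is reported on its own). Two refinements matter in practice:

* samples whose pooled range is below `equal_tol = 1e-5` are declared
  identical ($U = n_1 n_2/2$, $p = 1$, direction "unchanged"). Re-integrating
  an already-converged run moves every coordinate by $\sim e^{-30}$-scale
  amounts in the same direction; rank tests would read that deterministic
  rounding drift as perfect separation. Differences below the solver
  tolerance are not signal.
* direction is the sign of the median shift, also subject to `equal_tol`.

Phenotype calls contrast the mean activation of an anabolic group
(structural proteins, growth factors) with a catabolic group (degrading
enzymes, pro-inflammatory cytokines); the call is pro-anabolic or
pro-catabolic only when the indices differ by more than `margin = 0.1`,
otherwise balanced. The margin is a package choice for a qualitative call
and is exposed.

## Factorial sensitivity screening

`full_factorial()` enumerates all $2^p$ level combinations (levels 0/1,
last factor fastest). Each row is used as an *initial condition* — factor
nodes start at their levels, all other nodes at the background state — and
the system relaxes freely; factors are never clamped during the
integration. The background defaults to a declared constant (0.5) and the
recommended choice is the baseline ensemble's per-node medians, which is
what the acceptance script uses; it is a parameter, not an inference.

Effects are screened by fixed-effects factorial ANOVA on ±1-coded
contrasts: every main effect and (by default) every second-order
interaction has one degree of freedom with contrast sum of squares
$SS_e = (\mathbf{c}_e^\top \mathbf{y})^2 / N$; the within mean square is the
residual after removing all modelled effects. The reported statistic is
$F = (MSB/MSW) \times 100$ — the $\times 100$ is presentational scaling for
Pareto charts — while p-values come from the *unscaled* ratio on
$(1, N-1-n_\text{eff})$ degrees of freedom, since scaling the statistic
would invalidate its null distribution. "Groups" enter only at the
reporting stage: effects are computed per response node, then aggregated
over the response groups of interest (structural proteins; degrading
enzymes) by taking the maximum F and any-member significance. Responses
explained perfectly ($MSW = 0$) are flagged and sort first in the Pareto
table with $F = \infty$; ties break deterministically by effect and group
name. Only significant effects ($p \le 0.05$) enter the Pareto table;
non-significant records are retained with a flag, never dropped.

The suite validates the ANOVA against a brute-force cell-means oracle
(group rows by each effect's code, accumulate $n_g(\bar y_g - \bar y)^2$)
on all $2^3$ and $2^4$ designs with random responses, to $10^{-10}$
relative, and checks that the SS decomposition closes.

## Synthetic fixtures: what they emulate, and what they do not

No real curated corpus ships with the package; the generator builds
networks with the *statistical shape* of one:

* exact node and edge counts (33 nodes / 153 edges enriched; 31 / 59
  initial);
* exact named degree-of-connectivity values for the nodes whose
  connectivity is part of the study conditions (e.g. IL-4 = 19,
  IL-10 = 18, TGF-β = 15 in the enriched fixture; the IL-1β hub at 28 in
  the initial one), satisfied first with fresh partners preferred — a
  single constraint equal to the edge budget provably forces a star;
* hub-dominated connectivity via preferential attachment
  (`hub_bias = 1`) for the remaining edges;
* a 35% inhibitory-edge share (a typical value for signed interaction
  corpora; configurable), realised to the nearest edge;
* evidence annotations distributed so the corpus summary reproduces the
  emulated totals: 183 evidence links across 103 distinct references, 98
  links from NPC studies (50 of them from degenerate human NPC material),
  with reference pools disjoint across cell-type blocks. Where the
  emulated sub-table margins are mutually inconsistent, the fixture
  preserves the NPC subtotal (98) and the distinct-reference totals.

Two structural choices make the fixture *dynamically* faithful as well.
First, every node is guaranteed at least one regulator
(`ensure_regulated`): direction flips that preserve both endpoints' DoC
remove input nodes, because a baseline over random initial conditions is
meaningless when unregulated nodes hold their random starting values.
Second, edges are oriented predominantly forward along a random node order
(`forward_bias = 0.95`), giving a feed-forward-dominant topology with
sparse feedback; and fixture generation rejection-samples topology
candidates deterministically (candidate $j$ uses seed $+ 7919j$) until a
few probe integrations converge. The emulated system converges from random
initial conditions to a point attractor, so convergence is part of the
fixture's specification, exactly like the degree constraints; rejection
sampling is simply how a constraint that cannot be constructed directly is
hit. Everything downstream — which nodes respond to a TNF clamp, which
growth factors top the Pareto chart, the dominant-attractor share — is a
property of the generated topology. Passing tests on the fixtures
establishes that the *protocols* behave correctly, not that any biological
conclusion transfers to a real corpus; with a real interaction table
supplied via `parse_interaction_table()`, the same pipeline runs unchanged.

## Problem sizes and runtime choices

The test suite and the acceptance script run at the study's scale where
that is cheap — 100-run ensembles on the 33-node fixture, the full
$2^{15}$ cytokine design *generation* — and at reduced scale where only
correctness is at stake: the ANOVA oracle uses $2^3$/$2^4$ designs, the
Mann–Whitney oracle enumerates samples up to $n_1, n_2 \le 6$ (924
assignments at the largest), grid searches for motif fixed points use
0.05–0.25 resolution on ≤3-node systems, and the executed sensitivity
design is the $2^5$ growth-factor screen. These sizes are the package's
own choices for exhaustive-oracle tractability.

## Known limitations

* Only point attractors are characterised; sustained oscillations are
  reported as non-convergence, not enumerated as limit cycles.
* Per-edge heterogeneous weights are not supported ($\alpha = \beta = 1$
  globally), and clamp levels other than 0/1 carry no dose calibration.
* Intracellular signalling is out of scope: nodes are soluble-factor
  levels, edges phenomenological.
* The degree-constrained generator satisfies constraints greedily; extreme
  constraint sets that require backtracking are rejected as infeasible
  rather than solved.
* The initial-fixture node list reconciles printed counts that do not
  fully reconcile on their own; its membership beyond the constrained
  nodes is a fixture convention.
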