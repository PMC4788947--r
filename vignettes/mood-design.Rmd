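---
title: "Model-based tuning of an adaptation circuit by multi-objective optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based tuning of an adaptation circuit by multi-objective optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodtune)
```

## The design problem

A synthetic incoherent type-1 feed-forward loop (I1-FFL) is a three-gene
circuit in which a constitutively expressed activator A — rendered active by
binding an externally supplied inducer and dimerizing — drives both the
output gene `gC` and a repressor gene `gB`, whose product B in turn
represses `gC`. The race between fast activation and delayed repression
produces a pulse: after an inducer step the output protein C rises, peaks,
and returns towards its pre-stimulus level even while the stimulus is still
present. That property, *adaptation*, is quantified by two competing
figures of merit:

* **sensitivity** — how large the transient excursion is relative to the
  input change, and
* **precision** — how completely the output returns to baseline.

Which kinetic parameters (promoter strengths, plasmid copy numbers, RBS
strengths, degradation tags, promoter mutations) realize a prescribed
trade-off between the two? `moodtune` answers that with a multi-objective
optimization design (MOOD) workflow: simulate a reduced kinetic model,
minimize the two inverse indexes simultaneously, and post-process the
resulting Pareto-optimal set into wet-lab tuning guidelines.

## The reduced kinetic model

The model tracks nine species in nM over minutes: mRNAs and proteins of the
three genes, the intracellular and extracellular inducer, and the activating
dimer; the A-inducer monomer M is eliminated by a quasi-steady-state
approximation and enters as the non-negative root of

$$ 2 k_3 M^2 + (d_{AI} + k_{-2}) M - (k_2\,x_2 x_3 + 2 k_{-3}\, x_4) = 0. $$

The gC promoter is a hybrid: activated by the dimer ($x_4$), repressed by B
($x_6$), with basal leakage coefficients $\beta_1, \beta_2 = 0.05$. Its
transcription activity is

$$ \frac{x_4 + \beta_1\gamma_4 x_6 + \beta_2\gamma_5 x_4 x_6}
        {\gamma_2 + \gamma_3 x_4 + \gamma_4 x_6 + \gamma_5 x_4 x_6}, $$

which saturates, for large $x_6$, at a basal floor of about
$\beta_{1,2} = 5\%$ of the gC transcription capacity — an important
structural fact: repression can silence at most 95% of the promoter, so the
residual output level is ultimately set by the gene-C expression strength.
(The published rendering of this numerator ends in a dangling "+"; the
implementation uses exactly the three printed terms. All fixed constants
are the published ones; see `circuit_parameters()`.)

Transport couples the extracellular inducer pool to the cells through the
volume ratio `Kcells = Vcell * Ncells / Vmedium` (default `2.4e-4` for a
180 uL culture at OD 0.3), and the inducer decays at
$d_{Ie} = 0.0164\,\mathrm{min^{-1}}$ (half-life ~42 min).

Ten parameters are decision variables with the search ranges of
`decision_bounds()`; the gA capacity is tied to the gC one because both
genes share a plasmid.

## Objectives, constraint, pertinency

For an experiment on $[t_0, t_f]$ with an extracellular step applied at
$t_0$ (pre-step inducer is zero after equilibration):

$$ J_1 = \frac{2\,(x_9(t_f) - x_9(t_0^-))}{\int_{t_0}^{t_f} |\dot
x_8|\,dt}, \qquad
J_2 = \frac{x_8(t_f) - x_8(t_0)}{x_9(t_f) - x_9(t_0^-)}, \qquad
P = \int_{t_0}^{t_f} |\dot x_6|\,dt. $$

$J_1$ is the inverse of sensitivity (total output variation is half the
accumulated absolute derivative), $J_2$ the inverse of precision (the
normalized residual error; 0 is perfect adaptation), and $P$ caps the
repressor excursion so precision cannot be bought with unrealistic
repressor concentrations: $1 < P < 10^4$ nM. (The looser bound $10^5$
that also appears in the published problem statement is available via
`pertinency_box(P = c(1, 1e5))`.) Solutions only count as adaptive inside
the *pertinency box* $J_1 \in [10^{-3}, 200]$, $J_2 \in [10^{-4}, 20]$.

Both integrals are accumulated as extra quadrature states inside the stiff
integrator, not by post-hoc differencing, so they inherit the integrator's
error control and are independent of the output sampling grid.

## The stimulus protocol

The published problem leaves the step amplitude, $t_0$ and $t_f$ open, and
the choice matters because the inducer decays. The package's defaults
(`stimulus_protocol()`) are:

* `Ie_step = 1000` nM, applied instantaneously at $t_0 = 0$ after a
  5000-min zero-inducer equilibration;
* `tf = 100` min, i.e. ~2.4 inducer half-lives with ~19% of the step
  surviving at $t_f$.

The horizon rule is deliberate. Adaptation means the output returns *while
the stimulus persists*. If $t_f$ is pushed far beyond the inducer
half-life, the stimulus removes itself, every circuit "returns", and the
optimizer discovers a shortcut: eliminate the repressor (high $d_B$) so
that the promoter's B-dependent basal leakage disappears once the dimer is
gone. That shortcut inverts the biology the index is supposed to reward.
With `tf = 100` min the residual input is still substantial and precision
must come from feed-forward repression; the optimized fronts then
concentrate $d_B$, $k_{pB}$ and $\gamma_3$ at their lower bounds and
$\gamma_1$, $d_C$ high — the expected guideline structure. `tf` remains a
configuration knob for users who model non-decaying inducers.

## Numerics

* Stiff integration by `deSolve::lsoda` with `rtol = 1e-8`,
  `atol = 1e-10` nM; the right-hand side is compiled C, with a pure-R
  reference implementation (`circuit_rhs()`) kept as ground truth and
  cross-checked by tests (agreement ~1e-8 relative on trajectories).
* Pre-equilibration integrates from the empty state and then applies a
  Newton polish (finite-difference Jacobian on the 8 free states; the held
  inducer equation is excluded as it is identically zero). Integration
  alone leaves residuals up to ~1e-4 nM/min at protein-A concentrations of
  order $10^6$ nM; the polish brings the fixed-point residual below
  `1e-8` nM/min in all cases, and the zero-inducer fixed point
  ($x_1 = k_{mA}C_{gA}/d_{mA}$, $x_2 = k_{pA}x_1/d_A$, rest zero) is
  recovered to closed-form accuracy.
* Concentrations in $(-10^{-6}, 0)$ nM from the integrator are clipped to
  zero; anything more negative raises an error rather than being silently
  accepted.
* Under a downstream load the pool conservation $x_{10} + x_{11} = L_T$
  holds to integrator tolerance and is asserted in tests; the loaded
  equilibrium starts from the closed-form $(x_{10}, x_{11}) = (L_T, 0)$.

## The optimizer

`spmode()` is a bi-objective differential evolution in the spirit of
archive-based DE with spherical pruning:

* DE/rand/1/bin, population 50, $F = 0.5$, $CR = 0.9$ — conventional
  settings for this algorithm family; the published description fixes the
  mechanisms but not these scalars.
* An external archive keeps the pertinent, feasible, mutually
  non-dominated solutions; archive members also serve as mutation base
  vectors (probability 0.5), which is what makes the archive part of the
  evolutionary process rather than a passive store. Without this the
  10-variable problem is visibly under-converged at the 15,000-evaluation
  budget.
* Spherical pruning: objectives are normalized to the archive's
  ideal/nadir, each solution maps to one of `sectors = 100` angular
  sectors, and only the solution nearest the ideal point survives per
  sector. The *number* of archive solutions is therefore a resolution
  artifact: a converged front occupies some fraction of the sectors, and a
  different sector count yields a proportionally different count of
  reported solutions.
* Constraint handling by Deb's rules on the $P$-violation; candidates
  outside the pertinency box are barred from the archive but stay in the
  population, preserving the search gradient toward the box.
* Out-of-bounds mutants are reflected back into the box; simulation
  failures score as heavily infeasible instead of aborting the run.
* One seed drives everything; identical configurations reproduce
  bit-identical archives.

`brute_force_front()` (random or grid sampling plus feasibility and
dominance filters) provides the Monte-Carlo comparison baseline and an
exhaustive oracle: on a 2-knob reduction of the problem, no point of a
50x50 grid may dominate the archive beyond a 1% convergence margin — a
margin set by the optimizer's budget, not by integration error, which is
orders of magnitude smaller.

## From Pareto set to guidelines

The front is min-max normalized (raw scales of $J_1$ and $J_2$ differ by
an order of magnitude) and clustered agglomeratively under the Euclidean
metric with weighted-centroid (median/WPGMC) linkage — `stats::hclust`
on squared distances, as that linkage requires. By default the feature
space is the objectives only; `features = "both"` appends the normalized
parameters.

The cluster count is chosen by cutting the tree at $k = 10$ down to 2 and
counting, at each $k$, the decision variables whose Kruskal-Wallis test
(`stats::kruskal.test`, $\alpha = 0.05$) differs across clusters; the $k$
maximizing that count wins, ties toward the smallest $k$. Two properties
of this rule are worth knowing:

* With balanced, well-separated clusters it behaves as intended: on
  planted-cluster fixtures the shifted parameters are recovered as
  significant in effectively every run. *Exact* recovery (no false
  positives among the noise parameters, and $k$ exactly the planted count)
  is limited by the test level itself: with 7 null parameters per cut,
  some cut exceeds the true one by chance in a sizeable minority of seeds.
* On strongly converged circuit fronts the archive contains a few extreme
  trade-off solutions far from the bulk; centroid-family linkage isolates
  those first, so the $k = 2$ cut is typically {n-1, 1} and has no
  Kruskal-Wallis power, pushing the selected $k$ above 2. The
  high-sensitivity/high-precision split appears at the first balanced cut
  instead. This is a property of the selection rule on this front
  geometry, not of the implementation — the tests document it rather than
  hide it.

Each parameter is then classified (`extract_guidelines()`): significant →
**cluster-specific** tuning knob with per-cluster ranges; otherwise
**general** guideline if its optimized range shrank to at most 60% of the
initial interval (`shrink = 0.6`, configurable — the published criterion
"the ranges are different" is not quantified); otherwise
**unconstrained**.

## Level Diagrams and scenarios

`level_diagram()` computes the classic Level-Diagram table: per solution
the p-norm (default $p = 2$) of its normalized objective vector, reused as
the Y coordinate in every objective and parameter view, plus the cluster
label for color coding. The table is the canonical artifact; plotting
(`plot_level_diagram()`) is optional so everything stays testable
headlessly.

`knob_sweep()` re-evaluates a base solution while one parameter moves over
a (default log-spaced) grid — the wet-lab "exchange one part" experiment.
Staying "almost on top of the front" is quantified as a dominance excess
below 5% in normalized objective space (`dominance_excess()`).
`load_analysis()` re-simulates every front solution with a reversible
binding load ($K_1 = 40\,\mathrm{nM^{-1}min^{-1}}$, $K_2 = 20\,
\mathrm{min^{-1}}$, $L_T = 800$ nM by default) and reports the objective
shifts; only $|front|$ simulations are needed, which the tests assert
structurally.

## What the synthetic fixtures do and do not show

The test fixtures (`make_fixture()`) are: the convex analytic benchmark
$f_1 = \theta^2$, $f_2 = (\theta-2)^2$ with closed-form front
$f_2 = (\sqrt{f_1}-2)^2$; planted-cluster Pareto data (two objective
blobs, three parameters shifted between them, seven uniform); and
piecewise-linear pulses with known $J_1 = \Delta/h$, $J_2 =
\mathrm{residual}/\Delta$. They validate the engine, the clustering
pipeline and the functionals against independent closed forms. They do not
emulate measurement noise, cell-to-cell heterogeneity, model mismatch or
growth effects, so green tests certify the computational procedure — not
that a wet-lab implementation will match the model.

## Problem sizes used by the tests

The suite runs the benchmark at 2,000 evaluations, the 2-knob grid oracle
at 2,000 + 2,500 evaluations, and three full 10-variable runs at the
published budget of 15,000 evaluations (about 40 s each with the compiled
model); the acceptance script reruns one full-budget optimization from
scratch. Planted-cluster statistics use 40 seeds of 60 solutions.

## Known limitations

* The published gC-promoter numerator ends in a truncated "+"; only the
  printed terms are implemented. If the missing term is a constant basal
  source, low-level behavior near $x_4 = x_6 = 0$ would change.
* The archive cardinality depends on the pruning resolution
  (`sectors`), which the source description does not fix numerically.
* The stimulus protocol is a package convention (see above); absolute
  objective values shift with `tf` and `Ie_step`, though the guideline
  structure is robust across the horizons we examined.
* Only the reduced deterministic model is implemented — no stochastic
  simulation, no full mass-action model, no multi-device composition
  beyond the single binding load.
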