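---
title: "Simulation and sensitivity analysis for ODE reaction networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation and sensitivity analysis for ODE reaction networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odesens)
```

## The model class

`odesens` works with ODE models of biochemical reaction networks,

$$\dot x = f(x, p, k, t), \qquad x(t_0) = x_0(p, k),$$

where $x \in \mathbb{R}^{n_x}$ are species concentrations, $p$ are dynamic
parameters (rate constants, and any scaling or noise parameters introduced
by an estimation problem), and $k$ are fixed, condition-settable constants
(compartment sizes and experimental settings). When the model comes from an
SBML reaction network, the right-hand side is assembled as $f = S v$ from
the stoichiometric matrix $S$ and the kinetic-law flux vector $v$.
Measurements are compared against observables

$$y = h(x, p, k, t)$$

under a noise model with scale $\sigma(p, k)$; state-dependent noise is
rejected at model construction, which keeps every likelihood contribution
linear in the state perturbation and the adjoint jump conditions simple.

## Symbolic partials only; totals at runtime

The package's central design rule: **only partial derivatives are ever
derived symbolically** — the Jacobian $J = \partial f/\partial x$,
$\partial f/\partial p$, $\partial x_0/\partial p$,
$\partial h/\partial x$, $\partial h/\partial p$ and
$\partial \sigma/\partial p$, each computed once per model by
`derive_partials()`. Total derivatives such as
$dy/dp = (\partial h/\partial x)\, s + \partial h/\partial p$ are assembled
at runtime by sparse matrix multiplication and addition
(`assemble_output_sensitivity()`); no symbolic expression for $dx/dp$
exists anywhere in the package. This keeps symbolic processing cheap for
large models and makes the runtime cost of a total derivative a sparse
matrix product.

Partial derivatives are compiled to pure R closures whose bodies index
positionally into the state and parameter vectors; sparse matrices are
produced in compressed sparse column form (`Matrix::dgCMatrix`) on a
pattern fixed at compile time, so repeated evaluations are
bit-reproducible. Zero recognition uses a bounded-effort simplifier
(constant folding plus elementary identities such as $x - x \to 0$ and
$0 \cdot e \to 0$); an entry that cannot be proved zero stays in the
pattern. This trades pattern minimality for correctness: the pattern is
conservative-exact, and the test suite verifies that every entry outside a
pattern evaluates to exactly zero at randomly sampled points.

## Integration and linear solvers

Stiff integration uses the variable-order, variable-step BDF family via
deSolve, with the compiled analytic Jacobian supplied to the implicit
solver's Newton iteration; the nonstiff option is an Adams-type multistep
method. The `linear_solver` setting selects dense factorization or the
sparse direct solver (`lsodes` with the declared Jacobian sparsity). A
preconditioned Krylov option is not implemented because the underlying
solver interface does not expose user-Jacobian Krylov solves for R-level
right-hand sides; requesting `"iterative"` raises an error rather than
silently falling back.

Defaults are `rtol = 1e-8`, `atol = 1e-12`, `max_steps = 1e5`. Tolerances
bound the local error per step; against closed-form solutions of the
linear fixture catalogue the realized global error is well below
$10\,\mathrm{rtol}$, which is the acceptance margin used throughout the
tests.

Every simulation carries a cubic Hermite interpolant over its internal
output grid (values plus $f$ at the nodes, hence $C^1$), used to replay
the state trajectory during backward (adjoint) integration. The grid is
the union of the requested output times and `interp_points` (default 201)
uniformly spaced nodes. With $\mathcal{O}(\Delta t^4)$ interpolation error
this contributes well below the $10^{-4}$ cross-method agreement budget
for desk-scale problems; models with very sharp transients may need more
nodes.

## Steady states

`find_steady_state()` tries damped Newton on $f(x) = 0$ first (analytic
Jacobian, step halving down to $2^{-8}$), falling back to simulation with
expanding time horizons when Newton stalls or the Jacobian is singular —
the typical signature of conservation laws, as in the reversible
conversion fixture where $A + B$ is conserved. Convergence uses the
weighted RMS criterion of the underlying solver family,

$$\left\|f\right\|_{\mathrm{wrms}} =
\sqrt{\tfrac{1}{n_x}\sum_i \left(\frac{f_i}{\mathrm{atol}\,c +
\mathrm{rtol}\,c\,|x_i|}\right)^2} < 1,$$

with multiplier $c$ (`ss_tol_factor`, default 10). The method actually
used (`newton`, `simulation`, `newton_after_simulation`) is recorded in
the result.

## Sensitivity methods

**Forward.** The state ODE is augmented with one linear ODE per parameter,
$\dot s_j = J s_j + \partial f/\partial p_j$, integrated jointly with the
state; the Newton iteration matrix of the augmented system is the
block-diagonal repetition of $J$ (the standard simultaneous-corrector
approximation — the iteration matrix need not be exact for the BDF method
to converge). Output sensitivities are assembled at the requested times
from the partials. Cost scales with the parameter count.

**Adjoint.** For a discrete-data negative log-likelihood
$\mathcal{J}(p) = \sum_i g_i(y(t_i), \sigma, p)$ the gradient is computed
with one backward integration: $\dot\lambda = -J^\top \lambda$ between
datapoints, a jump $\lambda \leftarrow \lambda + (\partial g_i/\partial
x)^\top$ at each datapoint, the quadrature $q = \int \lambda^\top
(\partial f/\partial p)\,dt$, and

$$\nabla_p \mathcal{J} = q + \sum_i \left(\frac{\partial g_i}{\partial y}
\frac{\partial h}{\partial p} + \frac{\partial g_i}{\partial \sigma}
\frac{\partial \sigma}{\partial p}\right) + \lambda(t_0)^\top
\frac{\partial x_0}{\partial p}.$$

The backward pass replays $x(t)$ through the forward interpolant rather
than re-integrating from checkpoints; desk-scale trajectories fit in
memory and the interpolation error is absorbed by the cross-check budget.
Cost is nearly independent of the parameter count.

**Steady-state.** At an equilibrium with nonsingular Jacobian the implicit
function theorem gives $s^\ast = -J^{-1}\,\partial f/\partial p$ with one
factorization and $n_p$ solves. A singular Jacobian triggers a fallback
that simulates the augmented forward system until the sensitivities stop
moving; the result is flagged with the path taken. Whether a
conservation-law reduction would be preferable is an open design question;
the fallback was chosen because it needs no structural analysis and its
error is controlled by the integration tolerances.

**Finite differences** (`finite_difference_gradient`) exist purely as a
testing oracle and for the `check-gradient` command; the default is
central differences with step $10^{-5}\max(|p_j|, 1)$.

## PEtab objective

`load_petab()` assembles an estimation problem from a PEtab v1 bundle.
Observable and noise formulas may contain per-measurement placeholder
overrides; every distinct fully substituted (formula, noise, distribution)
triple becomes one compiled output channel, so all partial derivatives —
including those of estimated noise parameters — are available
symbolically. Channels are ordered by a canonical sorted key, which is one
of two ingredients of the order-invariance contract.

Supported noise distributions are normal and log-normal,

$$g_i = \tfrac12\left(\frac{y_i - \bar y_i}{\sigma_i}\right)^2 +
\tfrac12\log(2\pi\sigma_i^2),$$

with the log-normal case applying the same on log-transformed values plus
$\log \bar y_i$. Other distributions are rejected at load time.

Per condition, the pipeline is: optional pre-equilibration (steady state
under the pre-equilibration condition seeds the main phase; with forward
sensitivities the seed includes the steady-state sensitivities), optional
fixed-duration pre-simulation with its own overrides, then the main
simulation at measurement times. A measurement at $t = 0$ uses the
post-pre-equilibration/pre-simulation initial state without integration.
With the adjoint method the pre-equilibration contribution is the
steady-state adjoint linear solve $J^\top \xi = -\lambda(t_0)$ (falling
back to the forward steady-state sensitivities when $J$ is singular);
adjoint combined with pre-simulation is not supported — pre-equilibration
is the only supported combination, and requesting the other raises an
error.

A condition override that pins a *dynamic* parameter to a number removes
that parameter's influence for the phase, implemented by masking the
corresponding columns of $\partial f/\partial p$, $\partial h/\partial p$,
$\partial x_0/\partial p$ and $\partial\sigma/\partial p$. Overrides that
reference another parameter are resolved by value; gradient attribution
through cross-phase parameter references of the dynamics is out of scope
here (placeholder references in observable and noise formulas are handled
fully).

Conditions are evaluated independently and accumulated in sorted key
order, with measurement contributions summed in a canonical (time,
channel, value) order — the reported value and gradient are bit-identical
under any permutation of table rows, which is the contract that makes
parallel evaluation over conditions legal. Estimation-scale gradients
apply the chain rule per parameter scale ($\cdot\,p\ln 10$ for log10,
$\cdot\,p$ for log). Failing conditions either abort with a message naming
them (default) or, with `on_failure = "inf"`, yield an infinite objective,
the behaviour line-search optimizers prefer.

## The fixture catalogue and what passing tests show

The synthetic fixtures define the study conditions of the test and
acceptance suites:

| fixture | structure | noise sd | why it is there |
|---|---|---|---|
| `decay` | $\dot A = -k_1 A$, $A_0 = 1$, $k_1 = 1$ | 0.1, estimated | closed forms; estimated noise scale |
| `conversion` | $A \rightleftharpoons B$, $k = (1, 2)$ | 0.05 | conservation law, singular Jacobian |
| `synthesis_degradation` | $\dot X = a - bX$, $(a,b) = (2,4)$ | 0.05 | steady states, two-phase experiments |
| `lotka_volterra` | $(\alpha, \beta, \delta) = (1.5, 1, 3)$ | 0.05 | nonlinear, oscillatory |
| `linear_chain(n)` | $k_i = 0.5 + 0.25\,i$ | — | banded Jacobian, expm reference |

PEtab bundles place 8–24 measurements on $t \in [0.25, 4]$ with
independent Gaussian noise at the stated scales — the regime of a
well-identified, densely sampled kinetics experiment. Parameter recovery
is checked over ten seeded replicates against 3 standard errors from the
observed Fisher information. These generators emulate measurement noise
and condition structure; they do not emulate model misspecification,
outliers, partial observability or practical non-identifiability, so a
passing suite demonstrates correctness of the computed quantities, not
robustness of estimation on real data. Problem sizes (≤ 5 states, ≤ 4
parameters, ≤ 50 output points, 10 recovery replicates) were chosen so
the whole suite exercises every code path in a few minutes on one core.

## Numerical choices and degenerate inputs

* Singularity detection uses `rcond < 1e-12` plus factorization failure;
  both routes lead to the documented fallbacks rather than errors where a
  fallback exists.
* A single requested timepoint yields a trajectory without integration;
  empty observable sets produce zero-width output matrices.
* Compartment sizes are recorded as fixed parameters and their numeric
  value is folded into amount-rate kinetic laws and amount initial values
  at import, establishing a single concentration convention; unit
  annotations are ignored (values taken at face). Condition overrides of
  compartment sizes therefore do not rescale rates and multi-compartment
  reactions are rejected.
* SBML species with `boundaryCondition` or `constant` true get zero
  stoichiometry rows; assignment rules on parameters are substituted to a
  fixed point (cycles are an error); rate rules may promote parameters to
  states.
* `simplify_expr` never rewrites across associativity, so sparsity
  patterns can only be conservative, never too small.

## Known limitations

Events, delays, algebraic rules and DAEs are out of scope, as are
second-order sensitivities, Laplace noise, PEtab v2, prior terms and
steady-state ($t = \infty$) measurements. The expression compiler is an
R-closure backend: fast enough for desk-scale models, but it does not
emit compiled-language source. Adjoint gradients combined with
pre-simulation are rejected (see above).
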