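---
title: "Enzyme cost minimization: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enzyme cost minimization: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzcost)
```

## The model

`enzcost` answers a narrow, well-posed question: given a metabolic
network, a flux profile `v` (mM/s), kinetic and thermodynamic constants,
and physiological bounds on metabolite concentrations, which metabolite
and enzyme concentration profiles realize those fluxes at the lowest
total enzyme cost?

The key modeling move is to treat the metabolite log-concentrations
`x_i = ln(c_i / 1 mM)` as the free variables and the enzyme levels as
derived quantities. Reversible rate laws factorize as

$$v = E \cdot k_{cat}^{+} \cdot \eta^{rev}(\Theta)\cdot
      \eta^{kin}(c)\cdot\eta^{reg}(c),$$

with the driving force $\Theta = \ln(K_{eq}/Q)$ (unitless, in RT units)
controlling the reversibility efficiency $\eta^{rev} = 1 - e^{-\Theta}$,
and with saturation and allosteric terms in $(0,1]$. Inverting gives the
per-reaction enzyme demand $E_l(x) = v_l / (k^{+}_{cat,l}\,
\eta^{rev}_l\,\eta^{kin}_l\,\eta^{reg}_l)$ and the total cost
$q(x) = \sum_l h_l E_l(x)$ with burden weights $h_l$.

Two facts make this tractable. First, the feasible set is a convex
polytope in `x`: box constraints from concentration bounds (P-faces) and
linear constraints $\Theta_l(x) \ge \varepsilon$ from the second law for
every active reaction (E-faces). Second, $q$ is convex on that polytope
for all the rate-law families implemented here (this is exercised
numerically in the test suite on thousands of random segments rather
than assumed). The demand diverges as a reaction approaches equilibrium,
so E-faces repel the optimum; bound faces do not, so optima may sit on a
P-face.

### Assumptions

* Fluxes are given and are not themselves optimized; they may come from
  flux balance analysis or isotope tracing, and they need not be
  stationary. Reactions are re-oriented so active fluxes are positive.
* Every flux is enzyme-catalyzed. Zero-flux reactions are dropped from
  cost and constraints rather than forced to equilibrium: only the
  active sub-network is modeled, and a silent reaction imposes no
  thermodynamic constraint on it.
* Boundary metabolites with known levels are clamped. The choice of
  which metabolites to clamp is scientifically important (a free
  cofactor lets the optimizer buy cost reductions the rest of the cell
  would have to pay for), but it is the user's modeling decision.
* Allosteric regulation enters only as noncompetitive inhibition,
  `1/(1 + c_I/K_I)` per listed inhibitor. Other mechanisms can be
  supplied as custom factors but must keep `-ln eta` convex in `x`, or
  the convexity guarantee is lost.

## Cost-function tiers

The tier system lets the model degrade gracefully with data
availability:

| tier | needs | kinetic factor |
|------|-------|----------------|
| `EMC0` | fluxes | none (cost = sum of fluxes) |
| `EMC1` | `h`, `kcat⁺` | none (capacity only) |
| `EMC2S` | + `K_eq` | 1 |
| `EMC2SP` | + `kcat⁻` | `1/(1 + e^{-Θ}·kcat⁺/kcat⁻)` |
| `EMC3S` | + `K_M` | `S/(1+S)` |
| `EMC3SP` | + `K_M` | `S/(1+S+P)` |
| `EMC4CM` | + `K_M` | common modular denominator |

Here `S` and `P` are the pooled mass-action terms
$\prod_i (s_i/K_{M,i})^{|n_i|}$ and $\prod_j (p_j/K_{M,j})^{|n_j|}$.
Stoichiometric coefficients enter as exponents $|n_{il}|$ throughout;
cooperativity beyond stoichiometry is not modeled. Each tier is a lower
bound on the next, so even a data-poor tier gives a defensible lower
bound on the true cost.

One wrinkle deserves a note: the product-sensitive reversibility tier
`EMC2SP` formally needs only the ratio `kcat⁺/kcat⁻` besides `K_eq`,
because by the Haldane relationship its kinetic factor
`S/(S+P)` collapses to `1/(1 + e^{-Θ}·kcat⁺/kcat⁻)`, a function of the
driving force alone. We implement it in that Haldane-substituted form
and expose `kcat⁻` explicitly in the parameter set, since a `K_eq`-only
parameterization cannot express it. The identity is verified in the test
suite by comparing the two forms at random profiles.

## Parameters that matter

* **Standard concentration** – 1 mM; all `x` are natural-log mM, all
  equilibrium constants are unitless at that standard.
* **RT** – fixed at 2.4790 kJ/mol (25 °C) when converting Gibbs energies
  given in kJ/mol. Temperature-dependent workflows should convert before
  loading.
* **`epsilon`** (default 1e-9, unitless) – minimal driving force
  enforced on E-faces. The cost itself diverges at Θ → 0 and acts as a
  natural barrier, so `epsilon` exists only to keep the linear program
  strictly feasible; per-reaction force floors can be set with
  `theta_min` where a user wants to exclude near-equilibrium operation
  outright.
* **`K_M` default prior** – 0.1 mM, the geometric mid-range of typical
  Michaelis constants, used when a reactant's `K_M` is absent. Filled
  values are flagged in `params$km_filled` so saturation-tier results
  can be audited, and they enter parameter balancing with a deliberately
  weak precision weight (0.01 vs 1 for observed values).
* **Burdens `h_E`** – default 1 per reaction (cost = total enzyme
  concentration). `protein_mass` uses molecular masses in Da, making `q`
  a mass concentration in mg/l and enabling pathway specific activities
  `A_pw = v_pw/q` in mmol/s per mg; `chain_length` divides the
  approximate residue count (`m_l`/110 Da) by its median, which is the
  normalization used for relative cost comparisons. Amino-acid
  composition costing is out of scope. A nonlinear convex `h(E)` can be
  supplied per reaction.
* **Regularizer** – `lambda * ||x - x_hat||^2` with
  `lambda = 1e-6 · q(MDF point)` and `x_hat` the midpoint of the
  log-bounds. The displayed objective is a *squared* norm although a
  plain norm would also preserve convexity; the squared form is smooth
  everywhere, which the quasi-Newton inner solver needs. The default
  weight is small enough to leave strictly convex tiers unchanged at the
  reported precision (checked in the tests), while making the flat tiers
  (`EMC0`/`EMC1`) and force-only tiers (`EMC2`) reproducible: there the
  cost is constant or depends on `x` only through a few linear
  combinations, so without the tie-breaker the reported profile would be
  solver-dependent.

## Numerical choices

* **Linear programs** (MDF, feasibility, extreme points, slice centers)
  are solved with the two-phase simplex from the `boot` package behind a
  small wrapper that shifts variables to the nonnegative orthant. Sizes
  here are tiny (tens of variables), where the simplex is exact and
  dependable.
* **The convex program** is solved with `stats::constrOptim` (logarithmic
  barrier, inner BFGS with the analytic gradient) over the free
  coordinates only; fixed metabolites are substituted into the constraint
  offsets. The start point is the MDF solution, which by construction
  maximizes the minimum constraint slack — reusing an operation the
  method needs anyway, instead of a separate Chebyshev-center
  computation. The barrier weight is 1e-8, so solutions carry an O(1e-8)
  interior bias; outside the feasible set the objective is `+Inf`, which
  makes line searches safe against the cost's own singularity at
  E-faces. If the deterministic start fails, a seeded multi-start over
  convex mixtures of extreme points is tried; the seed is recorded and
  only used in that fallback.
* **Tolerance ranges**: the nearly optimal set
  `{x : q(x) <= (1+alpha)·q_opt}` is convex. Metabolite endpoints are
  exact: the inner function `m(a) = min{q : x_j = a}` is convex in `a`,
  and the endpoint is the root of `m(a) - q_tol`, found by
  `uniroot` with warm-started inner solves. Enzyme lower endpoints are
  exact convex minimizations (increasing quadratic penalty on the cost
  budget, inside the polytope barrier). Enzyme *upper* endpoints are a
  heuristic — the maximum of a convex function over a convex set is
  attained at extreme points we do not enumerate — computed as the best
  of the metabolite-endpoint solutions plus a penalized local ascent,
  and tagged `"heuristic"` in the output.
* **Degenerate inputs**: an all-fixed model yields a zero-dimensional
  polytope and a closed-form solution; `alpha = 0` collapses all
  tolerance ranges to the optimum without computation; `Theta <= 0` at a
  requested evaluation point raises a typed infeasibility error naming
  the reaction; an empty polytope raises an error carrying an
  irreducible infeasible subset of driving-force constraints found by a
  greedy deletion filter.
* **Parameter balancing** is a linear least-squares projection in log
  space. The free coordinates are per-metabolite formation energies (RT
  units), `ln kcat⁺` and `ln K_M`; `K_eq` and `kcat⁻` are derived, so
  Haldane and Wegscheider identities hold to machine precision by
  construction. Gauge freedom in the formation energies (only
  differences are observable) is resolved by the minimum-norm solution,
  which provably does not move any derived constant; if an actual output
  quantity is undetermined by the observations, the fit refuses with an
  instruction to supply priors rather than silently pick one.
* **Sign convention**: feasibility is encoded as `Θ_l · v_l > 0` — after
  orientation, `Θ_l ≥ ε` for all active reactions. When stating the same
  condition through the Gibbs energy one must flip the sign
  (`sign(v_l) = −sign(Δ_r G′_l)`); formulations that omit that minus sign
  appear in the literature, so both forms of the driving force are
  computed and cross-checked in the tests.

## The synthetic-data generator

`random_model()` draws formation energies first and derives equilibrium
constants, guaranteeing thermodynamic consistency; `K_M` and `kcat⁺` are
log-normal around 0.1 mM and 10/s (typical orders of magnitude for
central metabolism); `kcat⁻` follows from Haldane. Boundary levels are
placed to leave one RT of driving force per reaction step, and
feasibility is verified before the model is returned. Monte-Carlo
sensitivity uses log10-sd 0.2 for `kcat⁺` and `K_M`, 0.05 RT for
formation energies, 15% relative flux noise (sign-preserving), and ±5%
uniform variation of clamped metabolite levels — magnitudes chosen to
represent typical experimental uncertainty on each quantity type.

What the generator does *not* emulate: correlated parameter errors (a
full Bayesian posterior over balanced parameters is out of scope — the
sampler perturbs free coordinates independently), shared cofactors
coupling distant pathway segments, regulation beyond noncompetitive
inhibition, and measurement bias. Passing tests therefore demonstrate
correctness of the optimization and its invariants on consistent,
well-scaled inputs; they do not demonstrate that real proteomes are
cost-optimal, which is exactly the hypothesis the cost-optimality test
is designed to interrogate on real data.

The profile-sampling defaults follow the same logic: local profiles use
sd 0.05 on the natural-log scale; broad profiles are convex combinations
of the `2m` coordinate-extreme points with symmetric Dirichlet(1)
weights — flat over the simplex, the least-informative choice given that
no particular mixing distribution is canonical; and 1000 profiles per
class, enough that the median broad-profile error is stable at the
precision the comparison needs.

## Problem sizes used by the shipped tests

The suite runs on the three-reaction toy chain and random chains of 5–6
metabolites: large enough to exercise every code path (branching, fixed
metabolites, degenerate polytopes), small enough that the full suite,
including 1000-segment convexity sweeps, 1000-profile recovery
experiments over 20 seeds, and grid-search cross-checks, completes in a
few minutes on one core. Scaling to networks with tens of reactions
changes nothing structurally — cost and gradient evaluation are linear
in network size and the program stays convex — but the dense simplex
LP wrapper and `constrOptim` would be the first components to swap for
sparse equivalents on genome-scale models.

## Known limitations

* Enzyme upper tolerance bounds are heuristic (see above) and can
  under-estimate the true range on strongly non-isotropic level sets.
* `EMC4` is implemented for the common modular rate law only;
  direct-binding and other modular variants are not included.
* Preemptive enzyme expression across multiple conditions, non-enzymatic
  and dilution reactions, analytic (Hessian-based) tolerance
  approximations, and control-coefficient theory are out of scope.
* SBML import/export and automated retrieval of kinetic constants from
  databases are not provided; the SBtab-style TSV tables are the
  exchange format.
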