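---
title: "Stability from bipartite cycles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability from bipartite cycles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclostab)
```

## The model and its assumptions

`cyclostab` analyses the local stability of steady states of autonomous
ODE networks written in reaction form,
$\dot x_j = \sum_k v_k(x)\, s_{jk}$, with real reaction functions $v_k$
and constant stoichiometric scalars $s_{jk}$. Everything the first-order
analysis needs is the transition matrix
$H_{ij} = \partial f_j / \partial x_i$ at the steady state, which factors
as $H = R\,S$: a Jacobian matrix of reaction monotonicities
($r$, species $\to$ reaction edges) times a stoichiometry matrix
($s$, reaction $\to$ species edges). The signed directed bipartite graph
of these edges is the *influence topology* (the DSR graph of chemical
reaction network theory).

Three standing assumptions:

* the system is autonomous and the analysis is first-order about a steady
  state — driven or non-autonomous subnetworks are out of scope and the
  level decomposition explicitly flags them;
* each edge of a *single* influence topology has a definite sign. Unknown
  monotonicities (`?`) are representable, but every downstream operation
  refuses them: callers must expand to the $2^u$ fixed-sign topologies
  first (`expand_sign_assignments()`), because a superposed sign is a
  *set* of topologies, not one;
* reduced parameters $\rho_i$ are strictly positive symbols; all sign
  information lives in the topology. A parameter crossing zero is a
  change of topology, not a point in one phase space.

The central identity is the bipartite form of Sachs' theorem: the
principal minor $b_q$ of $H$ equals the sum over all sets of pairwise
non-overlapping bipartite cycles of total species-length $q$ of the
product of their weights, with a factor $(-1)$ per even-length cycle.
"Non-overlapping" means no shared species *and* no shared reaction —
products that reuse a reaction cancel identically under the permutation
sum, which the test suite verifies by comparing against brute-force
principal subdeterminants of $H$. The characteristic coefficients are
$a_q = (-1)^q b_q$, the Hurwitz determinants $\Delta_q$ follow, and the
Routh array counts unstable roots.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| edge weights | positive magnitudes, symbolic or rational | fresh symbols (Jacobian), 1 (bare-signed stoichiometric) | symbolic minors stay fully general; bare stoichiometric signs mean the modeller already scaled that edge |
| `resolution` | grid points per phase-space axis | 201 | fine enough that zone boundaries localise to well under the visual cell size; tests use 21–101 to keep the default run fast |
| zero tolerance (numeric path) | $|\Delta| \le 10^{-9}(1 + \text{running magnitude})$ | — | only for float input; exact inputs use exact zeros |
| `max_cycles` | cycle-enumeration guard | 10000 | combination search is exponential in cycle count; desk-scale networks stay far below |
| `exhaustive_limit` | canonicalization switch-over | 14 nodes | $2^{14}$ sign strings is still instant; beyond that a greedy fixpoint is used and may be a local optimum |

## The three reductions

1. **Stoichiometric scaling** sets one stoichiometric edge per reaction to
   $\pm 1$, multiplying the reaction's Jacobian edges by the absorbed
   factor — a pure redefinition of $v_k$ that leaves $H$ entrywise
   unchanged. The choice matters: the package searches all per-reaction
   selections (guarded at $10^5$) for the one minimising the final
   dimensionality, breaking ties lexicographically, since no principled
   rule beyond "try them" exists.
2. **Cycle compaction** groups edges by their cycle-membership *barcode*:
   edges lying in exactly the same set of cycles only ever appear in the
   minors through their product, so each group collapses to one
   parameter. This is exact, not an approximation — the suite checks each
   cycle's weight re-expressed over group parameters against its original
   edge product.
3. **Temporal scaling** rescales time by $\beta = |q_0|^{1/z}$ for a
   chosen group containing $z \ge 1$ Jacobian edges; every eigenvalue
   divides by $\beta > 0$, so root counts are invariant. The default unit
   is the Jacobian-bearing group with the lexicographically smallest
   barcode — the choice is genuinely arbitrary, and the classical
   fixtures pass the conventional unit explicitly so that their reduced
   expressions match the familiar forms parameter-for-parameter.

The final dimensionality is $d = (S - m) + J - c - 1$, with $c$ the
dimensions removed by compaction (including parameters on no cycle, which
cannot influence any minor).

## Numerical choices

* **Exact arithmetic.** All symbolic work runs in a small multivariate
  polynomial ring over the rationals built into the package, with
  integers held in doubles and every operation guarded against exceeding
  $2^{53}$, where exactness would silently end. Routh zero-string logic
  branches on exact zeros, so this is load-bearing, not cosmetic.
* **Determinants by cofactor expansion.** Hurwitz matrices are expanded
  along the column with the most exact zeros. At desk scale
  ($n \le 7$) this is exact and division-free; fraction-free elimination
  schemes buy nothing here and would need multivariate exact division.
* **Grid signs.** Phase-space scans evaluate the determinants in double
  precision and re-decide any value inside the relative tolerance by
  exact rational evaluation at the rationalized grid point
  (denominators $\le 10^4$). If even the exact route would overflow
  $2^{53}$, the point is reported as a boundary (sign 0) rather than
  guessed. High-degree determinants at extreme grid corners are the only
  place this occurs.
* **Degenerate Routh sequences.** A trailing zero string truncates the
  array; an interior or leading string of $p$ zeros (always odd for real
  polynomials) contributes $(p+1)/2$ changes plus a parity correction
  from the flanking signs; an all-zero sequence returns a distinguished
  *indeterminate* verdict — a pure even-cycle topology genuinely carries
  no first-order information, and reporting $k = 0$ there would be
  wrong.
* **Ties and determinism.** Cycle order is (length, canonical key) with
  each cycle rotated to its smallest species; sign-assignment expansion
  is lexicographic with `+` before `-`; scaling-choice ties break
  lexicographically. Identical inputs give byte-identical reports.

## What the generators emulate — and what they do not

`random_topology()` draws small fixed-sign networks (1–2 inputs and
outputs per reaction, small-rational weights) so that cycle algebra stays
exact and property ensembles (cycle expansion vs. brute-force minors,
Routh vs. eigenvalue counts, reduction invariance, negation orbits) can
run by the hundreds in seconds. `random_instantiation()` draws edge
magnitudes log-uniformly on $[0.1, 10]$, a realistic dynamic range for
rate sensitivities. Neither generator emulates mass-action structure,
conservation laws, or the sparsity patterns of curated biological models;
the classical fixtures cover those qualitative regimes instead. Passing
tests therefore demonstrate the correctness of the calculus, not the
field-realism of any particular random ensemble. The test and acceptance
ensembles use networks with up to 5 species and 6 reactions, matrices up
to $6\times 6$, grids up to $101^2$, and trajectory demonstrations at a
fixed RK4 step of $10^{-2}$ over horizon 100 — sizes chosen because every
claimed digit is exact or oracle-checked at them.

## Design decisions where the design was open

* **Canonical sign form.** Negating a node flips its incident edge signs
  without changing any cycle sign. A greedy one-node-at-a-time descent is
  order-dependent and can stall when only a *pair* of negations improves
  the sign string, which would make "same orbit, same canonical form"
  false; the package therefore minimises over all $2^{n+m}$ negation
  subsets up to 14 nodes (instant) and falls back to a greedy fixpoint
  beyond, documented as a local optimum.
* **Steady-state projections are kept verbatim.** The fixtures store the
  literature's closed-form mappings onto the reduced parameters even
  where re-derivation disagrees. Two cases are flagged in the bundles:
  the Sel'kov $b_2$ (the $\sigma_2$ 2-cycle term enters with $+$ by
  direct expansion, not $-$; the bundle marks the published string
  `expected_to_differ` and the tests assert the difference is exactly
  $2\sigma_2\rho_1\rho_3$), and the Lotka–Volterra map
  $\rho_3 = 1/\sigma_1$ (direct differentiation at the printed steady
  state gives $\rho_3 = 1$ for every $\sigma_1$, the familiar neutral
  center; the published map is used for the projection and the
  discrepancy is recorded in the bundle notes).
* **Single n-cycle closed forms.** The compact closed form for the last
  two determinants of a single odd $n$-cycle is often quoted with the
  sign $(-1)^{(n+1)/2}$; the determinant expansion and Orlando's product
  agree on $(-1)^{\lfloor n/4\rfloor}$ instead (they coincide at
  $n = 3, 5$ and part at $n = 7, 9$). The fixtures carry the verified
  form; the unstable-root count
  $k = \tfrac12\left(n + (-1)^{(n-1)/2} c_n\right)$ is unaffected and
  checked against the eigenvalue oracle for all odd $n \le 9$.
* **Orlando's ultimate determinant.** The product form for $\Delta_n$
  disagrees in sign with the identity $\Delta_n = a_n \Delta_{n-1}$ for
  odd $n$; the identity is what the determinant definition satisfies, so
  `orlando_check()` returns $a_n \Delta_{n-1}$.
* **Hurwitz reductions ($\Gamma$).** Single-parameter aggregates that
  linearise an instability boundary (e.g. a ratio of two reduced
  parameters) are only reported when a symmetry or an explicit
  factorisation proves them; there is no general algorithm, so the
  package detects exchange symmetries (exact substitution over all
  permutations of up to 6 parameters) and offers $\Psi$ aggregates from
  their orbits, nothing more speculative.

## Known limitations

* First-order analysis only: a Hopf *candidate* zone is a necessary
  condition; no center-manifold or normal-form computation is attempted,
  and indeterminate (all-zero) verdicts are returned as such.
* Non-overlapping combination search is exponential in the number of
  cycles; the guard refuses pathological graphs beyond $10^4$ cycles.
* The exact grid path degrades to a declared boundary (sign 0) when
  rationals exceed $2^{53}$; a big-integer backend would remove this
  ceiling.
* Steady-state *solving* for arbitrary user rate laws is out of scope;
  only the fixtures ship closed-form projections.
* Decomposition canonicalization does not resolve architectural
  degeneracies (distinct graphs with identical cycle intersection
  structure), nor does the package attempt to enumerate a fundamental set
  of cycle-only topologies.
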