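# cyclostab

Steady-state stability of reaction networks, read directly off their
**influence topology** — the signed directed bipartite species–reaction
(DSR) graph.

## The problem

For an autonomous ODE network `dx_j/dt = f_j(x_1, ..., x_n)` written as
sums of reactions times stoichiometries, `f_j = sum_k v_k s_jk`, local
stability of a steady state is governed by the transition (community)
matrix `H_ij = ∂f_j/∂x_i`. The Routh–Hurwitz conditions say the state is
asymptotically stable iff every Hurwitz determinant `Δ_1, ..., Δ_n` of the
characteristic polynomial is positive, and the number of sign changes in
the Routh array `(a_0, Δ_1, Δ_2/Δ_1, ..., Δ_n/Δ_{n-1})` counts the
unstable eigenvalues exactly.

The useful structural fact is that every coefficient involved is a
principal minor `b_q` of `H`, and `b_q` is a signed sum of products of
pairwise **non-overlapping bipartite cycles** of the influence topology
(Sachs' theorem, in the bipartite form where no combination may reuse a
species *or* a reaction). So stability is a property of the graph: its
cycles, their signs, and a handful of reduced parameters. `cyclostab`
implements that calculus exactly:

* **topology** — build/validate the signed bipartite graph, `?` signs for
  unknown monotonicities with deterministic expansion, JSON and DOT
  serialization, `H = R·S` assembly;
* **cycle algebra** — simple bipartite cycle enumeration, non-overlapping
  combinations, principal minors `b_q`, all in an exact rational
  multivariate polynomial ring (zero detection is exact, never a
  tolerance);
* **Routh–Hurwitz** — symbolic Hurwitz determinants, their negative
  monomials (the destabilising "multiplicative topologies"), Orlando
  cross-checks, and unstable-root counting including zero-string
  degeneracies;
* **parameter reduction** — stoichiometric scaling (one stoichiometric
  edge per reaction to ±1), cycle compaction (edges with identical
  cycle-membership barcodes collapse to one parameter), temporal scaling
  (one Jacobian-bearing parameter to ±1), down to
  `d = (S − m) + J − c − 1` strictly positive parameters `ρ_i`;
* **phase space** — 1D/2D grid scans over `ζ = (2/π) atan(ρ)`, zone
  classification by determinant sign pattern, per-zone unstable-root
  counts and Hopf-candidate flags, ggplot output;
* **decomposition** — orphan/childless node classification,
  upstream/downstream levels (strongly connected components) with
  per-level verdicts, and node-negation canonical sign forms;
* **fixtures** — the classical networks (Jenkin–Maxwell governor,
  van der Pol, Lotka–Volterra, Brusselator, Sel'kov, Repressilator, single
  n-cycles) with their published reduced expressions and steady-state
  projections, plus eigenvalue and trajectory oracles.

## Worked example: Maxwell's governor

```r
library(cyclostab)
gov <- make_classical_network("jenkin_maxwell")
gov$reduced
#> <reduced_topology> d = 2 surviving parameter(s); unit q0 (sign -), beta = |r3*sigma1*sigma2|
#>   rho1     = r1 / beta
#>   rho2     = r2 / beta
gov$reduced$hurwitz
#> <hurwitz_result> n = 3
#>   Delta_1 = rho1 + rho2
#>   Delta_2 = -rho1*rho2 + rho1*rho2^2 + rho1^2*rho2
#>     negative terms: -1*rho1*rho2
#>   Delta_3 = -rho1^2*rho2^2 + rho1^2*rho2^3 + rho1^3*rho2^2
#>     negative terms: -1*rho1^2*rho2^2
```

Ten original parameters reduce to two: `Δ_2 = ρ1 ρ2 (ρ1 + ρ2 − 1)`, so the
governor is stable exactly when `ρ1 + ρ2 > 1`; the lone negative monomial
`−ρ1 ρ2` is the 3-cycle product `c_0·c_3`, the structure that can
destabilise it. Inside the wedge:

```r
evaluate_reduced(gov$reduced, c(rho1 = 1/4, rho2 = 1/4))$routh
#> <routh_count> k = 2 unstable root(s)

map <- classify_zones(scan_phase_space(gov$reduced, axes = c("rho1", "rho2"),
                                       resolution = 101))
attr(map, "zone_table")
#> # A tibble: 2 × 5
#>    zone pattern     k n_cells any_hopf
#>   <dbl> <chr>   <int>   <int> <lgl>
#> 1     1 +--         2    1558 TRUE
#> 2     2 +++         0    8643 FALSE
```

Two zones: a stable region and a wedge with two unstable roots, entered
through a Hopf boundary (`Δ_2` and `Δ_3` cross zero together while `Δ_1`
stays positive) — the onset of growing oscillations Maxwell analysed.
`autoplot(map)` draws the phase space with the `Δ_1`/`Δ_2`/`Δ_3` =
black/red/blue shading convention.

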