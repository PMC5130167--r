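# vascbranch

Do vascular networks branch optimally or randomly? `vascbranch` is an R
package for analyzing the branching geometry of embedded vascular trees —
the kind of per-vessel tables produced by angiographic segmentation
software (id, parent, 3-D endpoints, radius, centerline length, child
count) — and for confronting the observed sibling asymmetries with two
families of models:

* **local optimality** — place each branching junction J so as to minimize
  either construction material, `H = Σ h_i l_i` with `h_i ∝ r_i`
  (surface area) or `h_i ∝ r_i²` (volume), or dissipated pumping power,
  proportional to the hydraulic equivalent impedance
  `Z_eq = Z_0 + (1/Z_1 + 1/Z_2)⁻¹` with Poiseuille `Z = 8μl/(πr⁴)`;
* **constrained randomness** — resample every junction uniformly inside a
  spatial constraint region that grows from the local endpoint triangle,
  through two intermediate sequential schemes (triangles updated top-down;
  daughter-midpoint balls built bottom-up), to the whole-network minimum
  enclosing sphere, always keeping topology, terminal tips and the source
  fixed.

The material-cost optimum is a weighted Fermat point with a complete
degeneracy classification: the interior solution
`cos θ0 = (h0² − h1² − h2²)/(2 h1 h2)` (and cyclic) applies only when no
vessel's cost dominates the other two (`h_i ≥ h_j + h_k`) and the
stationary angles fit inside the endpoint triangle; otherwise the junction
collapses onto an endpoint, eliminating a vessel. Pure power-cost
minimization at a single junction *always* collapses — branching becomes
explicable only once downstream impedances `c_1, c_2` enter, which rescales
the daughter costs by `1/(k+1)²` and `k²/(k+1)²`, `k = c1/c2`. The package
implements both the first-order analytic region classification of the
`(c1, c2)` plane and the exact numeric minimization, plus their comparison.

Distributions of length asymmetry `λ_l`, angle asymmetry `λ_θ` (each
smaller-over-larger) and raw angles are compared via moments with bootstrap
standard errors, kernel-density peaks, binned Kullback–Leibler divergence
with bootstrap p-values, and junction-level Pearson correlation.

A synthetic-tree generator (Murray-law radii `r0^d = r1^d + r2^d`,
near-symmetric radius splits, wide sibling length ratios, optional
tortuosity) makes the whole pipeline testable without any data download,
including an exactly-optimal tree construction for parameter-recovery
tests. See the methods vignette (`vignettes/branching-optimality.Rmd`) for
the model details and design choices.

## Worked example

```r
library(vascbranch)
net <- generate_tree(mouse_like_spec(seed = 7))   # 633-bifurcation synthetic tree
net
#> Vascular network: 1267 vessels, 633 bifurcations, 634 terminal tips (root: v0001)

st <- run_study(net, n_realizations = 25, seed = 7, B = 500)
st
#> Branching-asymmetry study: 633 junctions
#> Comparison table (lambda_l / lambda_theta means):
#>            source     n lambda_l_mean lambda_l_kl_p lambda_theta_mean lambda_theta_kl_p
#> 1            real   633         0.711         1.000             0.864             1.000
#> 2 mc_surface_area   629         0.684         0.002             0.956             0.002
#> 3       mc_volume   631         0.757         0.002             0.951             0.002
#> 4           local 15825         0.620         0.002             0.708             0.002
#> 5   intermediate1 15825         0.603         0.002             0.751             0.002
#> 6   intermediate2 15825         0.620         0.002             0.634             0.002
#> 7          global 15825         0.834         0.002             0.793             0.002
```

Each row summarizes one λ distribution: the real network (its
self-comparison p-value is 1 by construction), the two material-cost
optimal predictions over the same junctions (`n` counts non-degenerate
junctions), and the four random ensembles (25 realizations × 633
junctions pooled). The mean `λ_l` ordering — global (0.834) far above
local (0.620) — shows how the global constraint drives length ratios
toward spurious symmetry, while local/intermediate randomness keeps the
broad length asymmetry. Per-junction detail:

```r
st$degenerate_fraction$volume      # fraction of junctions whose volume-cost
#> [1] 0.003                       # optimum collapses onto an endpoint
st$pearson$volume$r                # junction-level actual-vs-optimal angles
#> [1] 0.412
```

The weak junction-level correlation alongside the good network-level
moment agreement is the substantive point: network-wide distributions are
compatible with material-cost optimality even where individual junctions
are poorly predicted by it.

Lower-level entry points: `read_network()` / `write_network()`
(`angicart_csv`, SWC), `junction_geometry()`, `solve_optimal_junction()`,
`pc0_minimize()`, `pc1_plane_scan()`, `simulate_network()`,
`run_ensemble()`, `kl_bootstrap_pvalue()`.

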