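---
title: "Optimal and constrained-random branching geometry of vascular trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal and constrained-random branching geometry of vascular trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascbranch)
```

## The question and the model

Segmented angiographic data (micro-CT, MRI) yield rooted trees of
cylindrical vessel segments: per vessel an id, a parent, proximal and distal
3-D endpoints, a radius, a centerline length, and a child count. At a
bifurcation, a parent of radius $r_0$ splits into daughters of radii $r_1,
r_2$. `vascbranch` asks whether the *position of the branching junction* —
and with it the sibling asymmetries in length ($\lambda_l$) and in
parent–daughter angles ($\lambda_\theta$), each defined as the
smaller-over-larger ratio — looks like the outcome of a local optimality
principle or of spatially constrained randomness.

The optimization framework fixes the three *unshared* endpoints
($V_0$ for the parent, $V_1, V_2$ for the daughters) and the radii, and
moves only the shared junction $J$. Branching angles are indexed by the
non-adjacent vessel: $\theta_0$ between the daughter chords, $\theta_1$ and
$\theta_2$ between the parent chord and the opposite daughter chord. Angles
are computed from the full vessel chords $J \to V_i$, not near-junction
tangents: chords are what tie angles to lengths, they are less sensitive to
developmental meandering of the centerline, and they involve no arbitrary
offset choice. Only magnitudes are used, so planar predictions compare
directly with non-planar empirical junctions.

## Material-cost optimization and its degeneracies

The material cost of the junction is $H = \sum_i h_i l_i$ with
$l_i = |J - V_i|$ and cost-per-length $h_i \propto r_i$ (surface area,
vessel-wall material) or $h_i \propto r_i^2$ (volume, blood). This is the
weighted Fermat problem. The stationary interior solution is

$$\cos\theta_0 = \frac{h_0^2 - h_1^2 - h_2^2}{2 h_1 h_2},$$

and cyclically for $\theta_1, \theta_2$. Two degeneracies make blind use of
the formula wrong, and both are classified before it is applied:

* **cost dominance** — if $h_i \ge h_j + h_k$, deleting vessel $i$
  ($J = V_i$, $l_i = 0$) always wins (equivalently, some cosine falls
  outside $[-1, 1]$);
* **triangle condition** — if the stationary $\theta_i$ is smaller than the
  triangle's interior angle at $V_i$, the stationary point lies outside the
  triangle and the constrained optimum is again $J = V_i$.

Radii obeying a generalized Murray law $r_0^d = r_1^d + r_2^d$ with
$d \in [2, 3]$ can never trigger cost dominance in either mode (a property
test checks this over $10^4$ random Murray-consistent triples).
`murray_exponent()` recovers $d$ per junction by bisection.

Interior optima are found by damped Weiszfeld iteration on the convex $H$
in the plane of $V_0 V_1 V_2$ (the optimum of a sum of distances to three
points lies in their plane, so projecting first is exact even for
non-planar empirical triangles). An independent oracle
(`numeric_fermat_oracle()`: dense barycentric grid, pattern-search
refinement, Nelder–Mead polish) cross-validates both the optimum and the
classification; the polish step matters because the cost surface develops a
narrow anisotropic valley when the optimum hugs a vertex, which defeats
axis-aligned refinement alone.

## Power-cost optimization

Power loss for steady Poiseuille flow through a vessel is $\dot Q^2 Z$ with
$Z = 8\mu l / (\pi r^4)$. The package's default impedance units drop the
constant $8\mu/\pi$ (it rescales every term and never moves an argmin);
physical units are available via `impedance_model("physical", mu)`.
Impedances combine hydraulically, not additively: siblings in parallel
(equal pressure drop across the daughters is assumed throughout), parent in
series,

$$Z_{eq} = Z_0 + \left(\tfrac{1}{Z_1} + \tfrac{1}{Z_2}\right)^{-1}.$$

**PC-0 (single junction).** Minimizing $Z_{eq}$ alone always collapses the
junction onto one of the three unshared endpoints, for any radii — the
costliest path is eliminated entirely. `pc0_minimize()` verifies this
numerically (grid plus refinement; every strictly interior sample exceeds
the best vertex value). Biologically this predicts no branching at all, so
a single-junction power principle cannot explain observed geometry.

**PC-1 (downstream impedances).** Adding constants $c_1, c_2$ in series
below the daughters,
$\tilde Z_{eq} = Z_0 + ((Z_1+c_1)^{-1} + (Z_2+c_2)^{-1})^{-1}$, and
expanding to first order in $Z_i/c_i$ gives a weighted-Fermat cost with
rescaled daughter weights $\tilde h_1 = h_1/(k+1)^2$,
$\tilde h_2 = h_2 k^2/(k+1)^2$, $k = c_1/c_2$ (the additive constant
$c_1 c_2/(c_1+c_2)$ has zero gradient and is dropped). Both rescaling
factors are below 1, so downstream load is what makes non-degenerate
branching possible. Because the rescaled weights depend on $(c_1, c_2)$
only through $k$, the analytic region boundaries are rays $c_1 = k^* c_2$
through the origin; `pc1_boundary_lines()` locates every $k^*$ by sign-scan
and bisection over the six degeneracy margins. `downstream_equivalent_impedance()`
computes the actual subtree impedances these constants stand for (postorder
recursion with a strictly positive terminal impedance per tip, since even a
capillary has nonzero impedance).

`pc1_plane_scan()` compares the analytic labels with exact numeric
minimization over a $(c_1, c_2)$ grid (default $[0,20]^2$). The two agree
everywhere except in a band along each boundary ray whose width scales like
$Z/c$: the exact boundary is displaced by a first-order-in-$Z/c$ amount in
$k$. In the shipped test geometries that band still covers roughly 8% of
the cells with $\min(c_1,c_2) \ge 2$; agreement reaches ~96% for
$\min(c) \ge 8$ and 100% for $\min(c) \ge 14$. The mismatch is a property
of the first-order approximation, not of the solvers — a brute-force dense
grid confirms the numeric labels in disputed cells. Users comparing the two
routes should therefore read the agreement as scale-dependent rather than
as a single percentage.

## Constrained-random simulation schemes

Four schemes resample every junction while keeping topology, terminal tips
and the source point exactly fixed:

* **local** — uniform in the junction's original triangle
  $(V_0, V_1, V_2)$, independently per junction;
* **intermediate1** — top-down sweep; each junction uniform in the triangle
  of its parent's already-updated endpoint and the daughters'
  not-yet-updated endpoints. Each junction is *exactly* coplanar with its
  sampling-time triangle (the simulator records those triangles), but
  final-network planarity is only approximate, because a junction's
  daughters move after it was placed — exact planarity of every final
  triangle is impossible when both ends of the tree are pinned;
* **intermediate2** — bottom-up sweep; uniform in the ball centered at the
  daughters' current endpoint midpoint with radius equal to their
  separation. The upstream endpoint has no influence, and junctions gain
  genuine 3-D freedom (positive planarity for most junctions);
* **global** — uniform in the exact minimum enclosing sphere (Welzl's
  algorithm) of all original nodes.

Sampling uses the barycentric square-root construction for triangles and
the $u^{1/3}$ radial law for balls; both are tested against closed-form
uniformity properties. Each (scheme, realization) pair gets its own derived
32-bit seed from the master seed, so any realization is reproducible in
isolation and ensembles are order-independent. Ensembles default to 100
realizations.

Simulated vessels carry chord lengths — the schemes move endpoints and know
nothing of centerline tortuosity — whereas empirical $\lambda_l$ uses the
centerline lengths of the input table. This asymmetry is deliberate and
documented; for the synthetic fixtures (uniform tortuosity) it cancels in
the ratios.

## Statistical comparison

`summarize_distribution()` reports mean, sample SD and bias-corrected
(adjusted Fisher–Pearson) skewness, with SE(mean) analytic and SE(SD),
SE(skewness) from a seeded bootstrap (B = 1000). Distributions are compared
by discrete Kullback–Leibler divergence over fixed bins — 20 equal bins on
$[0,1]$ for ratios, 30 on $[0,\pi]$ for angles, with a Jeffreys-style half
pseudo-count per bin so disjoint supports stay finite. The direction is
D(model ‖ real). The bootstrap null draws with-replacement resamples of
half the real sample size and measures their divergence from the full real
sample; the p-value is the fraction of null draws at least as large as the
observed divergence (+1/(B+1) continuity). A model identical to the real
data thus gets a large p-value, a disjoint one gets $\le 1/(B+1)$. The
half-size resample and the bin counts are package conventions, fixed in
configuration for reproducibility; published tables built with other
(unstated) conventions are reproduced in pattern, not digit-for-digit.
Density peaks use a Gaussian KDE argmax (Silverman bandwidth, 512-point
grid); for bimodal samples the higher mode is returned. Junction-level
agreement is a plain Pearson correlation between actual and predicted
angles, excluding degenerate junctions.

## Synthetic data

`generate_tree()` grows a binary tree breadth-first (to a fixed depth or an
exact bifurcation count), with Murray-split radii around an even flow split
(radius ratios concentrated near 1, as in real vessels), wide uniform
sibling chord ratios (length ratios broadly spread — the empirical
contrast the analysis hinges on), branching-angle draws around 2.2 rad, and
an optional uniform tortuosity factor. The `mouse_like_spec()` preset has
633 bifurcations, matching the scale of a segmented mouse-lung arterial
tree. What the generator does *not* emulate: spatial space-filling,
radius-dependent angle correlations, measurement noise, and heterogeneous
tortuosity — so green simulation tests certify the pipeline's mechanics,
not anatomical realism.

`generate_mc_optimal_tree()` inverts the closed form: at each junction the
daughters are placed along directions making exactly the optimal angles
with the parent chord, in a randomly oriented plane. Every junction is then
the stationary point of the weighted-Fermat cost of its *final* triangle,
so an end-to-end re-analysis must recover the constructed angles to
numerical precision (the shipped check demands Pearson r > 0.999 and hits
max errors near 1e-11). A draw-then-reoptimize construction cannot achieve
this, because optimizing a junction after its daughters' endpoints were
used upstream invalidates the parent's optimality. `perturb_network()`
jitters junctions at a chosen positional SD (tips and source fixed,
per-vessel tortuosity preserved) for noise-robustness curves.

## Numerical choices

* Weiszfeld iteration: convergence when the step falls below 1e-12 or
  10,000 iterations; iterates touching a vertex are nudged toward the
  centroid (the interior classification guarantees the optimum is not
  there).
* Triangle minimizers: barycentric grid (vertices included), pattern-search
  refinement that shrinks only on failure to improve, Nelder–Mead polish
  with clamped-projection penalty. Vertex collapse is declared within
  1e-6 of the triangle diameter.
* Boundary ties in classification resolve to the vertex; coordinate
  continuity and chord checks use 1e-6 length-unit tolerances.
* Planarity is the point–plane distance of $J$ scaled by the mean chord
  length $\overline{|JV_i|}$ — a dimensionless, vessel-symmetric choice
  fixed here because the originating figure's exact denominator is not
  stated in text.
* Degenerate draws in simulation (collinear triangles, coincident daughter
  endpoints) keep the original junction and are logged rather than
  erroring.

Problem sizes in the shipped tests — 500 random Fermat instances, 200 PC-0
geometries, two 100×100 plane scans, four 100-realization ensembles on the
633-junction fixture — were chosen as the smallest sets that exercise each
claim with stable statistics.

## Limitations

Pulsatile (Womersley) flow, asymmetric sibling pressure drops, joint
multi-junction optimization, and radius optimization are out of scope;
radii are fixed inputs everywhere. Image segmentation is upstream of this
package: it starts from vessel tables (`angicart_csv` or SWC). Units are
never interpreted — all coordinates, radii and lengths must share one
length unit.
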