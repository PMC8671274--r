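---
title: "Two-stage construction of His-Purkinje system models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage construction of His-Purkinje system models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modelling problem

Ventricular activation in a healthy heart is orchestrated by the
His-Purkinje system (HPS): a specialized fast-conducting network that
carries the impulse from the atrio-ventricular node through the His bundle
and the bundle-branch fascicles into a dense sub-endocardial Purkinje
network, which couples to the working myocardium at discrete
Purkinje-ventricular junctions (PVJs). For patient-specific simulation two
representations are useful at different stages of a twinning workflow:

1. a **fascicle-based model** — five disc-shaped earliest activation sites
   (EAS) fired at prescribed timings inside a fast-conducting
   sub-endocardial (SE) layer. It is cheap to build and re-fit, which makes
   it the natural representation while parameters are being identified
   against a measured 12-lead ECG;
2. a **Purkinje-based model** — a topologically realistic network grown as
   recombinant fractal trees, with a His bundle, stochastic PVJs and
   transmural junction extension. It is the representation of choice once
   parameters are fixed, because it behaves correctly in scenarios the
   surrogate cannot capture faithfully (retrograde activation, antidromic
   propagation, junctional delays).

`hpstwin` implements the automated replacement of the first representation
by the second on a common anatomical reference frame, together with the
machinery needed to verify that the replacement preserves the activation
sequence and the ECG: a graph eikonal activation solver and a 12-lead
pseudo-ECG pipeline. Because no patient data ships with the package, an
idealized biventricular geometry generator provides the test bed.

## Anatomical reference frame

All spatial parameters are expressed in universal ventricular coordinates
(UVC): apicobasal $z \in [0,1]$, transmural $\rho \in [0,1]$ (0 at the
endocardium), rotational $\varphi \in (-\pi, \pi]$ and a ventricular label
$\nu \in \{-1, +1\}$. The septum belongs to the LV coordinate system
($\nu = -1$) and its RV-facing surface carries $\rho = 1$; this matches the
convention in which the RV septal root location is written with
$\rho = 1.0,\ \nu = -1$. Because of that convention, "endocardial" logic
never tests $\rho$ directly but a derived normalized endocardial depth
`d_endo` that is zero on every endocardial surface, including the RV-facing
septal face.

The inverse mapping from a UVC coordinate to a mesh node is a nearest-node
query. The metric is a documented choice (the field's tooling delegates
this to a k-d tree without specifying one): $\nu$ must match exactly, then
the Euclidean metric in $(z, \rho, \varphi/\pi)$ with equal weights and the
rotational distance measured on the circle; ties break to the lowest node
index, which makes the mapping deterministic.

## Synthetic geometry

The generator builds a truncated thick-walled prolate ellipsoid (LV) and a
thinner partial shell (RV free wall) lifted off the LV epicardium over a
septal sector, enclosing a crescent-shaped RV cavity that tapers to zero at
the attachment rims and opens at the base. Hexahedral blocks are subdivided
into tetrahedra with the Kuhn (path-simplex) pattern, which is translation
invariant and therefore conformal across the whole structured grid,
including the azimuthal wrap; collapsed pole cells at the apex inherit
conformity after degenerate simplices are dropped. Default dimensions
(60 mm long axis, 20/28 mm LV endo/epi radii, 3.5 mm RV wall, 8 mm maximal
cavity width, 3.5 mm target edge length) give a mesh of roughly 3,400
nodes and 14,000 tetrahedra — deliberately desk-scale; every quantity the
package reports is computed at this scale. UVCs are assigned analytically
from the construction parameters, so the frame is exact rather than the
solution of a Laplace problem; computing UVCs on arbitrary patient meshes
is out of scope.

What the synthetic anatomy does *not* emulate: fibre architecture (the
activation model defaults to isotropic conduction), valve openings other
than a flat base, trabeculation, papillary muscles, and any subject
specificity. Tests passing on this geometry demonstrate the correctness of
the algorithms, not fidelity to any particular heart.

## Fascicle-based model

The SE layer is the node set with $z \in [s_{z,\min}, s_{z,\max}]$ and
`d_endo` $\le s_\rho$ (defaults 0.15, 0.9, 0.1 — the last corresponding to
approximately a one-element-deep endocardial shell at the default
resolution). Discs are grown geodesically on the SE surface graph rather
than as Euclidean balls, so they hug the curved endocardium; the disc
radius is `delta_rad` (default 0.05) times the apicobasal endocardial arc
length of the respective ventricle, which keeps the parameter
anatomy-relative. Firing times `t_his` default to the published baseline
(19.86, 24.81, 26.25, 37.30, 41.94 ms for lv_af, lv_sf, lv_pf, rv_sf,
rv_mod).

## Purkinje-based model

**His bundle.** Straight Cartesian legs connect the mapped bifurcation
coordinates ($b_{h,0} \to b_{h,1} \to \{b_{h,lv}, b_{h,rv}\}$, the RV side
via the apical mid-septal waypoint $b_{h,rv,mid}$, then to the five roots),
sampled at the cable resolution; each sample is snapped to the nearest SE
surface node when one lies within two edge lengths. The basal trunk between
$b_{h,0}$ and the bifurcation runs mid-wall where no SE node is nearby;
those samples stay on the straight path, reflecting the intramural course
of the proximal His bundle. Each leg is an independent node chain; where
more than two legs would depart one node, the attachment cascades one node
down the first child chain, so a trifurcation becomes two staggered
bifurcations and the two-offspring cap holds by construction.

**Fractal growth.** Each fascicle network grows on its territory (the
LV or RV endocardial SE surface). Generation 1 is a single branch from the
root; afterwards every active tip spawns up to two branches deflected by
$\pm\psi$ about the local surface normal. Branch length is drawn from
$\mathcal N(\mu, \sigma\mu)$ truncated to $[0.25\mu, 4\mu]$ — $\sigma$
(printed unitless next to $\mu$ in micrometres) is interpreted as a
*relative* spread. Branches advance in sub-steps of the cable resolution;
each sub-step direction blends the branch direction with a repulsion term
pointing away from the nearest non-ancestor node,
$d = \widehat{(1-r)\,d_{rot} + r\,d_{rep}}$, and is re-projected onto the
SE surface (nearest surface node and its area-weighted normal). A sub-step
passing within half a resolution of an existing same-fascicle node collides
and merges (if the target has fewer than two parents), producing the
recombinant mesh topology; the number of collisions is not otherwise
restricted. Tips drifting off the SE band are truncated. Growth stops when
the coverage estimate — the fraction of the territory's SE surface nodes
within $\mu$ of the network — reaches `delta_cov`, or at a generation cap
(default 40). The mapping from `delta_cov` to growth steps is a documented
choice: coverage-based stopping is the simplest mechanism that makes
`delta_cov` = 0 mean no growth and 1 mean complete coverage.

Numerical details that matter: the repulsion search uses a spatial hash
with an interaction range of eight cells of size $\mu$ (≈ 17 mm at
baseline) — beyond that range repulsion is negligible and is skipped; the
exclusion list for both repulsion and collision is the branch's own last
three nodes, preventing self-repulsion artifacts; each fascicle grows on
its own named RNG substream derived from the master seed, so fascicles are
reproducible independently.

**PVJ placement.** The linear junction density is
$\lambda = \delta_{cov}/\mu$. Each fascicle network is traversed depth-first
from its root, accumulating the arc distance $d$ since the last junction;
at each node a junction is accepted with probability $\min(1, \lambda d)$ —
a linear hazard, the simplest law consistent with a distance-dependent
probability at mean spacing $1/\lambda$. Accepted junctions split the host
segment at its midpoint and hang a transmurally oriented stem there. His
segments never receive junctions.

**Transmural extension.** From each stem base a ray along the inward
endocardial normal finds its paired point on the next geometric surface
(distance $D$, found by triangle-ray tests over all other boundary
surfaces). The stem is extended to
$\ell = \mathrm{clamp}(s_\rho D \max(0.25, g),\ 0,\ 0.95 D)$ with
$g \sim \mathcal N(1, \sigma)$, re-discretized at the cable resolution, and
the junction couples to the nearest tissue node. Junctions whose ray finds
no paired surface (a handful near the basal rim) are dropped with a
warning and a count.

## Activation

First-arrival activation is computed on a directed weighted graph: tissue
edges are the tetrahedral mesh edges augmented with 2-ring diagonals to
reduce the metrication error of a graph eikonal solve (on a rod, far-end
times converge to length/velocity within 5% under two refinements);
network edges are bidirectional cable segments at the Purkinje velocity;
PVJ couplings are *asymmetric directed edges* — network to tissue at the
anterograde delay (8 ms), tissue to network at the retrograde delay (3 ms)
— so a single multi-source Dijkstra solve captures orthodromic/antidromic
and anterograde/retrograde interplay simultaneously. In fascicle mode the
SE-layer edges conduct at the Purkinje velocity; a subtlety is that a
2-ring diagonal can connect two sub-endocardial nodes *through* the wall
(the septum has endocardium on both faces), so fast conduction additionally
requires the pair to share a sub-endocardial neighbour, keeping the fast
subgraph on the surface. In Purkinje mode the SE tissue keeps the
myocardial velocity, since activation stems from the network itself.

Scenarios: under sinus rhythm the fascicle model fires its discs at
`t_his` while the Purkinje model starts from the His root at time zero;
under RV apical pacing both representations are paced from the mapped
coordinate $(0.3, 0, 0, +1)$ and the fascicle model keeps its fast SE layer
conductive with no timed sources, replicating retrograde activation of the
HPS surrogate (as a continuum, it has no junctional delay — the
representation has no junctions). The activation times of the five mapped
root nodes in the Purkinje model are the analogue of `t_his`; the matched
study design feeds them back as the fascicle firing times.

## Pseudo-ECG

Transmembrane voltage is modelled as a fixed action-potential template
shifted by the local activation time, $v(x,t) = T(t - \tau(x))$. The
template is the two-variable Mitchell-Schaeffer model (defaults
$\tau_{in} = 0.3$, $\tau_{out} = 6$, $\tau_{open} = 120$,
$\tau_{close} = 150$ ms, $v_{gate} = 0.13$) integrated from rest with a
suprathreshold stimulus and normalized; an analytic tanh upstroke is
available as a fallback. Electrode potentials use the infinite homogeneous
conductor approximation,
$\phi_e(t) = \frac{1}{4\pi}\sum_{el} (-\nabla v)\cdot\nabla\frac{1}{\|x_{el}-x_e\|}\,V_{el}$,
which replaces a torso lead-field model: torso geometry and conductivities
are external to the algorithmic content here, and relative QRS morphology
comparisons survive the simplification. Because element gradients are
linear in nodal voltages the sum collapses to a fixed coefficient matrix
times the nodal voltage time courses, making the trace evaluation a single
matrix product. Standard 12 leads derive from the Wilson central terminal;
the derivation identities $I - II + III = 0$ and $aVR + aVL + aVF = 0$ hold
to machine precision by construction and are asserted in the tests.

Post-processing applies a zero-phase (forward-backward) low-pass at 60 Hz
— zero-phase so that alignment is not biased by filter group delay. With a
reference trace, one global shift maximizing the summed cross-correlation
over all leads is applied, then one amplitude factor uniform across all
leads; the measured-data preset (50 Hz notch, 0.5 Hz high-pass, 60 Hz
low-pass) is provided separately. The alignment criterion is a documented
choice; the comparison reports per-lead Pearson correlation and RMSE
without thresholding.

## Reproducibility and scale

Every stochastic stage derives a named substream from one master seed
(growth per fascicle, PVJ placement, transmural extension), so the full
pipeline is bit-reproducible and any stage can be re-run independently.
Artifacts carry no timestamps; stage timings go to the message stream
only, keeping output files byte-stable. On-disk CARP-style text formats
use 0-based node indices per that format's convention; in-memory indices
are 1-based as usual in R.

Problem sizes used throughout the package's own studies: the default
synthetic mesh (≈ 3,400 nodes), baseline growth (≈ 70,000 network nodes,
≈ 12,000 junctions across the five fascicles), 150 ms of activity sampled
at 2000 Hz. These sizes keep a full two-representation, two-scenario study
with ECG comparison in the low minutes on a single core.

## Known limitations

* The fascicle/Purkinje equivalence is assessed on the idealized geometry;
  subject-specific anatomies will shift the root timings and coverage.
* Conduction is isotropic by default; transversely isotropic conduction
  requires a fibre field the synthetic geometry does not provide.
* Repolarization is not modelled: the pseudo-ECG is meaningful for the QRS
  complex only.
* The eikonal solver returns first-arrival times; source-sink mismatch,
  wavefront curvature effects and rate dependence are outside its scope.
* Segments created by collisions or degree-cascading may slightly exceed
  the nominal cable resolution (bounded by 1.25 of it); the His bundle
  respects the resolution exactly.
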