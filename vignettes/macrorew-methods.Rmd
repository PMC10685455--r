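---
title: "Methods: reweighted ensemble analysis for macrocycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reweighted ensemble analysis for macrocycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macrorew)
```

## The model

Dual-boost accelerated MD modifies the potential twice: the dihedral
energy and the total potential each get a boost

$$\Delta V(v) = \frac{(E - v)^2}{\alpha + E - v} \quad (v < E), \qquad
  \Delta V = 0 \quad (v \ge E),$$

which raises basins below the threshold $E$ and leaves barrier tops
untouched; $\alpha$ (kcal/mol) controls how aggressively the basin floor
is flattened. A frame sampled on the boosted surface represents the
canonical ensemble only after reweighting by $e^{\beta\,\Delta V}$ with
$\beta = 1/(k_B T)$ and $k_B = 0.0019872$ kcal/(mol K). `macrorew`
assumes the per-frame boost energies are available (an aMD engine logs
them) and that the trajectory contains the solute only, already imaged
and stripped of solvent.

### Reweighting and its truncation

The exponential estimator is exact but noise-amplifying: a handful of
high-boost frames can dominate the weight vector. The package therefore
defaults to the Maclaurin (Taylor-at-zero) truncation of the exponential
at order 20,
$$w_i \propto \sum_{n=0}^{20} \frac{(\beta\,\Delta V_i)^n}{n!},$$
which approaches the exponential from below, monotonically in the order.
The truncation bias is a known analytic quantity: the relative error of
the order-20 partial sum is below $10^{-15}$ at $\beta\Delta V = 1$,
below $10^{-4}$ up to $\beta\Delta V \approx 8$, and grows steeply
beyond (about $1.6\times 10^{-3}$ at $\beta\Delta V = 10$). For the
moderate boosts this workflow targets, the truncation is far below
sampling noise while strongly damping weight variance. Exponential mode
is retained (`weight_params(mode = "exponential")`) and is used by the
test suite as the exact oracle.

Two conventions are configuration, not physics facts, because an aMD log
does not pin them down:

* **Temperature** defaults to 300 K (`weight_params(temperature = )`);
  $\beta$ follows from it.
* **Which boost enters the weight.** Dual boost implies both components
  act on the sampled frame, so the default exponent uses
  `dv_dihedral + dv_total`; either component alone is selectable
  (`component = "total"` / `"dihedral"`).

Exponential weights are computed as $e^{x - \max x}$ so large boosts
cannot overflow; the shift cancels on normalization. Weights are always
returned normalized to sum 1.

### Free-energy surfaces

$F_{bin} = -k_B T \ln(p_{bin}/p_{max})$, so the most probable bin sits
at exactly 0 kcal/mol. Empty bins are *unoccupied* — flagged and `NA`,
never assigned an arbitrary energy cap — because "no samples" is
information about sampling, not about the free energy. Histogram bins
are half-open $[lo, hi)$ with the last bin closed; values outside the
grid accumulate into a reported overflow bucket rather than silently
vanishing.

### Dual-boost parameter selection

`dual_boost_params()` implements the standard sizing conventions:
dihedral threshold offset 3.5 kcal/mol and smoothing 0.7 kcal/mol per
freely movable backbone dihedral (both overridable); potential threshold
$E_{tot} = \langle V \rangle + c \cdot N_{atoms}$ with $c = 0.2$
kcal/mol per atom for water-like solvents and $c = 0.56$ for DMSO, whose
larger number of internal degrees of freedom calls for a higher boost
ceiling. With zero movable dihedrals the dihedral window collapses to
the average dihedral energy ($E_{dih} = \langle V_{dih}\rangle$); the
smoothing parameter is kept positive in that degenerate case because the
boost functional requires $\alpha > 0$.

## Dihedral PCA

Each torsion angle is mapped to $(\sin\theta, \cos\theta)$ — features
continuous across the ±180° wrap, ordered sin-before-cos per torsion (an
arbitrary but documented choice). PCA is the eigendecomposition of the
covariance of mean-centered features. Two decisions matter:

* **Fit unweighted, reweight the density.** The PCA axes are fitted on
  all frames without weights; the per-frame weights enter afterwards,
  when densities on the PC plane are histogrammed. This keeps the axes a
  fixed geometric frame on which differently weighted ensembles,
  trajectory halves and repeat runs are directly comparable. A weighted
  fit (`fit_pca(weights = )`, using the unbiased frequency-weight
  covariance, which reduces exactly to the sample covariance under
  uniform weights) is available but off by default.
* **Determinism.** Each component's largest-magnitude entry is made
  positive, eigenvalues are sorted descending, and K-means clusters are
  relabeled by decreasing population, so repeated runs and cross-solvent
  comparisons name the same things the same way.

Several trajectories may be concatenated before fitting so that
ensembles share axes ("combined" PCA); projection of new data onto a
fitted model is `project_pca()` / `predict()`.

K-means uses Lloyd iterations (`stats::kmeans`, up to 500) from a
k-means++-style initialization drawn with a caller-supplied seed, making
the clustering a pure function of `(coords, k, seed)`. The default six
centroids follow the workflow's standard setting for aqueous macrocycle
ensembles; `k` is never chosen automatically. Representative frames
minimize the Euclidean distance to the centroid, ties broken by lowest
frame index. `match_external_representative()` maps a reference point
(e.g. a representative from another solvent) to the nearest cluster; if
no centroid lies within a configurable radius (default infinite) the
single nearest frame is returned and flagged as a frame fallback.

## Intramolecular hydrogen bonds

A donor–acceptor pair is in contact in a frame iff

1. heavy-atom distance $\le$ `d_max` (default 3.5 Å),
2. D–H···A angle (at the hydrogen) $\ge$ `angle_min` (default 90°),
3. bond-graph separation $\ge$ `min_separation` (default 3).

All cutoffs are inclusive; the angle comparison carries a $10^{-9}$
degree epsilon so geometries constructed exactly at the boundary are not
lost to floating-point rounding. The defaults are interpretations, made
explicit and configurable:

* The 3.5 Å cutoff is measured **heavy atom to heavy atom** — the
  conventional choice of contact-map tools — with `distance_from =
  "hydrogen"` available.
* 90° is deliberately permissive: the aim is to capture unconventional
  short-range IMHBs that a 120–150° criterion would discard, while the
  distance cutoff still limits low-energy contacts.
* `min_separation = 3` prevents covalently adjacent polar atoms from
  counting themselves as hydrogen-bonded.

Donors are N/O atoms with at least one bonded hydrogen (one entry per
N–H/O–H pair); acceptors are oxygens plus lone-pair nitrogens, with
amide nitrogens excluded and H-bearing nitrogens treated as donors only
— the conventional assignment for peptide-like molecules. Occupancy is
the weighted count $\sum_f w_f \cdot [\text{contact in } f]$, so a
contact map is exact given exact weights. The polar/apolar comparison
subtracts maps element-wise and classes each pair short-range when donor
and acceptor residues are adjacent around the macrocycle ring (cyclic
sequence separation ≤ 1, minimum over the two ring directions), a
structural reading of "neighbors" that needs no tuned distance.

## Convergence diagnostics

The workflow's convergence questions are made quantitative:

* **2D-RMSD**: optimal-superposition (Kabsch) RMSD between all sampled
  frame pairs, heavy atoms only, default 1 ns stride.
* **Split-half**: the trajectory is cut at the midpoint (odd counts give
  the first half the extra frame, noted in the report); each half's
  weights are renormalized; contact maps and reweighted PC densities are
  compared on *shared* axes — the PCA is fitted once on the full
  trajectory and both halves use one histogram grid. Contact divergence
  is the max absolute occupancy difference (in [0, 1]); density
  divergence is the Jensen–Shannon divergence in bits (in [0, 1]).
* **Cross-run overlap**: histogram intersection
  $\sum_b \min(p_a, p_b)$ of reweighted densities on a shared grid, 1
  for identical densities, 0 for disjoint support. The original
  workflow judged "resembles" visually; the numeric pass mark here
  (overlap ≥ 0.7) is implementation policy, configurable, and chosen so
  that independent runs of a well-converged synthetic ensemble pass with
  a wide margin while disjoint conformational spaces fail decisively.

## Conformer-averaged charges

Partial charges fitted to a single conformation inherit that
conformation's electrostatics — a problem when the fitting structure is
a high-free-energy one. Averaging element-wise over several
independently generated conformers (default expectation 10; fewer is
accepted with a warning) damps those errors. Averaging is plain
per-atom arithmetic mean — no symmetry-equivalence re-averaging, which
an upstream RESP fit handles. Validation checks the charge total
against the molecular formal charge (default tolerance $10^{-4}$ e),
and `charge_spread()` ranks atoms by their conformer-to-conformer
standard deviation.

## The synthetic-data generator

Every consumer of real aMD data has a synthetic counterpart with planted
truth:

* `toy_macrocycle()` builds a ring of simplified amide units (N, H, Cα,
  C, O), closed through a secondary amine and an alkyl linker, with
  idealized bond lengths on a circle. It is a *topological and
  geometric* stand-in: donors, acceptors, ring adjacency and bond-graph
  separations behave like a real semipeptidic macrocycle's, but the
  geometry carries no force-field energetics.
* `sample_boosted_potential()` runs 1D Metropolis on the *boosted*
  surface $V + \Delta V(V)$ and logs the exact per-step boost. Because
  Metropolis has the exact boosted stationary distribution, exponential
  reweighting must recover the analytic Boltzmann moments — the
  reweighting oracle. The canonical test condition is a harmonic well
  ($V = \tfrac12 k x^2$, $k = 1$ kcal/mol/Å², 300 K) boosted with a
  threshold 2 $k_BT$ above the mean potential and $\alpha = k_BT$ — a
  strong flattening whose boosts stay in the regime the Maclaurin
  truncation is meant for.
* `plant_torus_clusters()` draws cluster centers uniformly on the
  torsion torus and adds wrapped Gaussian noise of standard deviation
  $1/\sqrt{\kappa}$ radians (the von-Mises large-$\kappa$ limit), with
  multinomial population assignment.
* `plant_hbond_trajectory()` schedules frames between two template
  geometries per planned pair — contact formed (2.9 Å, 165°) or broken
  (5.5 Å) — so the *weighted* occupancy equals the target. The schedule
  is a greedy largest-weight-first subset: exact for uniform weights
  with integer counts and for weight vectors designed to sum to the
  target, otherwise the nearest achievable value is reported with a
  warning and becomes the ground truth. The base geometry is expanded
  (heavy skeleton scaled, terminal atoms kept at bond length) until no
  unplanned pair can be in contact, and the generator verifies the
  realized contacts before emitting frames.

All generators are pure functions of their arguments including the
seed, and restore the caller's RNG state.

What passing these tests does **not** show: correctness on real MD data
with force-field correlations, partial solvent exposure, imaging
artifacts or boost-log/trajectory misalignment — the generator plants
statistics, not mechanics. The I/O layer validates lengths and units at
the boundaries precisely because those are the real-data failure modes.

## Numerical and interface conventions

* Units are fixed: Å, kcal/mol, ns, Kelvin, elementary charge.
* Atom indices are 1-based everywhere inside the package — the R-native
  convention (as in bio3d) — with PDB serials mapped on read and torsion
  files read as 1-based. Cluster labels run 1..k.
* Dihedrals follow the IUPAC sign convention, wrapped to (−180, 180]
  with exact −180 mapped to +180 (one canonical representative).
* Boost-log parsing uses a configurable column map; the default is a
  two-column (dihedral, total) layout, and `dialect = "amber"` selects
  the amd.log column order.
* K-means++ seeding nudges exact duplicate seed points apart by 1e-8 so
  Lloyd iterations start from k distinct centers.
* Degenerate inputs fail loudly: zero-variance features, collinear
  dihedral quadruples, all-frames-in-one-bin surfaces, missing explicit
  hydrogens, negative boosts.

## Problem sizes

The verification suite sizes its simulations for tight bounds at
interactive runtimes: $10^5$ Metropolis steps for the reweighting oracle
(variance recovered within 5%), $10^4$ frames for the planted torus
clusters (populations within 2%), $2\times10^4$ frames for split-half
bounds (< 0.05 occupancy, < 0.02 bits), 100 random frames for the
brute-force hydrogen-bond equivalence, and $4\times10^5$ points for the
2D harmonic free-energy surface check ($R^2 > 0.99$ against the
analytic form).

## Known limitations

No periodic-box handling or solvent (solute-only input is assumed); no
Gaussian-approximation or dynamical reweighting variants; no tICA/UMAP
embeddings or automatic cluster-count selection; no energetic H-bond
scoring, C–H donors or solvent bridges; no RESP fitting (charge tables
are consumed, not derived); trajectory writing only in multi-frame XYZ.
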