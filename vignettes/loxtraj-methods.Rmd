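---
title: "Geometric and energetic analysis of lipoxygenase-DHA complexes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric and energetic analysis of lipoxygenase-DHA complexes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loxtraj)
```

## Scope and model

`loxtraj` analyses the output of molecular simulations of
lipoxygenase-fatty acid complexes; it computes descriptors, labels and
ensemble statistics from coordinates and from per-snapshot energy
tables, and deliberately computes no energies of its own. The chemistry
it is built around is the hydroperoxidation of docosahexaenoic acid
(DHA, 22 carbons, six *cis* double bonds at Δ4, Δ7, Δ10, Δ13, Δ16,
Δ19): hydrogen abstraction from a bis-allylic methylene (C9, C12 or
C15) by the Fe(III)-OH⁻ cofactor, O₂ addition to the resulting planar
pentadienyl radical, rotation of the peroxyl chain, and
retro-abstraction from the Fe(II)-H₂O cofactor.

Coordinates are in ångströms, angles in degrees, energies in kcal/mol
throughout. Atom addressing is 1-based everywhere, matching both R
convention and PDB serials, so config files carry PDB serials
unchanged.

## Descriptors

*Distances* are Euclidean; group-group contacts are closest-atom
minima, with ties broken toward the lowest index pair. No angular
hydrogen-bond criterion is applied: contact series report distances
only, and a single definition (minimum over heavy atoms) is used for
side-chain stacking rather than centroid variants, to avoid dialect
drift.

*Plane-plane angles* use oriented normals, `n = (b - a) x (c - b)` for
the ordered triple `(a, b, c)`, and are **not** folded to [0°, 90°].
The ordering of the triple is part of the contract: the pentadienyl
criterion distinguishes configurations below and above 90°, which a
folded angle cannot. The documented pairs for DHA are
(C10, C11, C12)/(C12, C13, C14) and (C7, C8, C9)/(C9, C10, C11).

*Dihedrals* follow the IUPAC convention (cis = 0°, trans = 180°, sign
by the standard atan2 form), and are rejected as degenerate when three
consecutive atoms are collinear (cross-product norm below 1e-9).

*Superposition RMSD* uses the Kabsch algorithm via SVD with the
determinant correction, so the rotation is always proper. Alignment
uses the selection handed in (substrate carbons by default); no
implicit exclusion of any domain is applied, because the upstream
protocol for such exclusions is not part of this package's contract.

*Domain motion* is tracked by two scalars: the distance between
unweighted geometric centres, and the angle between the eigenvectors of
the largest eigenvalue of each domain's gyration tensor (the centred
second-moment matrix, unweighted — mass weighting adds nothing for
pseudo-atoms and is not specified by the upstream protocol). Axes are
unsigned, so this angle folds to [0°, 90°]. A relative eigenvalue gap
below 1e-6 raises an "axis ambiguous" error rather than returning an
arbitrary direction.

## Stereochemistry

Z/E at a double bond is read from the substituent torsion: |torsion| at
or below 90° is Z. The tie at exactly 90° is measure-zero; assigning it
to Z keeps the rule a closed/open partition.

The two-letter pentadienyl label reads the two formal double bonds of
the radical span (first letter about `(Ca, Ca+1)`, second about
`(Ca+2, Ca+3)`), plus a planarity score: the maximum out-of-plane
deviation from the least-squares plane through the five span carbons. A
least-squares plane (smallest eigenvector of the centred moment matrix)
is used instead of any three-atom plane so that coordinate noise is
averaged rather than amplified.

R/S at a centre uses declared substituent priorities and the
signed-volume rule: with unit vectors u₁, u₂, u₃ from the centre to the
three highest-priority substituents, t = (u₁ x u₂) · u₃, and t < 0 is
R. No general CIP engine is implemented — the analyses need a handful
of centres whose priorities are declared in the config — and the sign
convention is anchored by a hand-assigned worked example kept in the
test-suite (a bromochlorofluoromethane-like centre), eliminating
convention drift. Pro-R/pro-S labels promote the assessed hydrogen
above its geminal partner and reuse the same rule.

One design point deserves emphasis: the default neighbour priorities at
DHA's bis-allylic methylenes are **C11 > C13 at C12, C10 > C8 at C9,
and C14 > C16 at C15**. These were verified two independent ways
(manual hierarchical-digraph analysis, and an external CIP
implementation run on the generator's own coordinates with deuterium
substitution). The decision falls seven to ten spheres deep in the CIP
digraph and is *not* simply "carboxyl side first": at C9 the Δ16 double
bond on the tail side outranks the distant carboxylate. With these
priorities, the antarafacial-addition construction below yields the
*S* product, as it must.

Face classification fits the least-squares plane through the radical
span and compares the signed side of the probe (attacking/peroxyl
oxygen) with that of the reference (cofactor hydroxide oxygen):
opposite sides are antarafacial. Probes within 1e-6 Å of the plane are
rejected as undefined.

## Reactivity and energetics

A frame is *precatalytic* for a candidate hydrogen when its distance to
the hydroxide oxygen is **strictly** below the threshold (default
4.0 Å); the plane-angle regime uses the same strict rule at 90°. Strict
inequalities follow the "smaller than" wording of the criteria being
operationalised; values exactly at a threshold are not counted.

The ensemble barrier statistic is the Boltzmann-exponential average
ΔE‡ₐᵥ = −k_B·T·ln((1/N)Σᵢ exp(−ΔE‡ᵢ/k_B·T)) with
k_B = 0.0019872 kcal mol⁻¹ K⁻¹ and T defaulting to 300 K, the
production-simulation temperature; 300 K reproduces the packaged
hALOX12 ensemble averages to their printed precision, which is asserted
in the tests. It is evaluated with a min-shift for numerical stability,
so the low-temperature limit degrades gracefully to the minimum. The
packaged pigALOX15-mini-LOX ensemble is known to recompute about
0.3 kcal/mol below its accompanying printed average; the summary
reports the recomputed value and sets a `discrepancy` flag rather than
asserting equality, since the origin of the printed value cannot be
re-derived from the table itself.

Energy ladders accumulate stationary points from ordered steps
(TS = preceding minimum + ΔE‡, product = preceding minimum + ΔE), with
explicit inter-step offsets for changes of reference (e.g. the energy
falloff on O₂ approach). The relation between any global reference zero
and a step's own reactant is ambiguous in general, so the ladder takes
offsets as inputs and makes no attempt to reconcile references itself.

The reorganisation step of the retro-abstraction (rotation of the
peroxo group from the antarafacial to the suprafacial side) has no
natural scalar coordinate; it is tracked via per-frame face
classification rather than an invented coordinate.

## The synthetic generator

The generator exists so that every analysis has testable ground truth.
It emulates, with idealised geometry, the statistical structure of the
study's trajectories:

* a 22-carbon chain built from internal coordinates (C=C 1.33 Å, C-C
  1.50 Å, C-H 1.09 Å, sp² angles 120°, sp³ 109.47°, double-bond
  torsions 0°/180° by config, single bonds at an alternating ±120°
  skew). These constants are documented idealisations, not force-field
  values; the analyses need topology-correct geometry only;
* inter-plane-angle regimes steered by the single-bond torsion of the
  bis-allylic motif, inverted numerically (the torsion-angle map is
  monotone on [-180°, -60°], covering plane angles of roughly 60-120°);
  the achieved angle, not the target, is recorded as ground truth;
* an "abstraction" operation that rebuilds the span as the planar
  s-trans radical; the Δ12-forming torsion goes to the planar form
  reached by the smaller rotation of the terminal plane's normal onto
  the first plane's ±normal — below 90° that is the parallel (E)
  continuation, above it the antiparallel (Z) one. This reproduces the
  angle-criterion direction by construction;
* cofactor placement by least squares against target H-O distances
  (multi-start BFGS); geometrically infeasible target sets degrade to
  the best fit with the residual recorded in the ground truth and a
  warning. Scheduled precatalytic shares default to 74%/73%/10% for
  H12proS/H9proR/H15proS with near/far distance bands of 2.8-3.5 Å and
  4.5-5.5 Å — bands chosen once so that placement residuals cannot move
  a frame across the 4.0 Å threshold;
* two rod-like Gaussian domains (500 points, aspect 10, transverse
  scale 1.5 Å) re-centred and re-aligned after sampling so the
  constructed centre distance and axis angle are exact; defaults are
  the closed-state values 42.3 Å/38.2° with a scheduled opening event
  to 47.2 Å/58.8° at 70% of the trajectory;
* the O₂ candidate grid: positions at an exact radius (default 3.0 Å)
  along the six signed axes and six in-plane bisectors. Whether both
  signs of each bisector should be used is ambiguous in placement
  protocols, so the direction set is configurable and the 12-direction
  set is the default;
* i.i.d. Gaussian coordinate noise added *after* all events, so ground
  truth is always the noiseless value; a single RNG stream per
  trajectory, seeded explicitly, makes fixtures bit-reproducible.

What the generator does **not** emulate: force-field energetics,
solvent, protein sequence content, realistic domain shapes, or any
correlation structure between frames (frames are independent draws
around the scheduled parameters). Consequently, passing recovery tests
demonstrates that the analyses measure what they claim on
topology-correct geometry with realistic noise — not that the package
would reproduce any particular simulation's output, which would require
the simulation itself.

Published trajectory-level numbers (precatalytic shares, contact-mean
distances, domain metrics) appear in tests and in the acceptance script
only as *construction targets* whose recovery is checked; they are
never claims about re-derived simulation data.

## Problem sizes and tolerances in the test-suite

Property tests run 200-1000 random geometries per invariant at fixed
seeds. Trajectory-level checks use 100-200 frames, 500-point domains,
and noise levels σ ∈ {0, 0.05, 0.1, 0.2} Å — sizes at which recovery
tolerances (0.5 Å on centre distance, 2° on axis angle, binomial
intervals on shares) are comfortably resolved while the whole suite
stays desk-scale. Oracle comparisons are held to 1e-9 relative for
closed-form descriptors and 1e-3 Å against the brute-force rotation
grid for superposition.

## Known limitations

* Only multi-model PDB is supported as a trajectory container; other
  formats would be thin adapters over the same contract.
* PDB round-trips quantise coordinates at the format's 1e-3 Å
  precision; in-memory pipelines keep full precision.
* No automatic classifier for "U-shaped" vs "twisted" binding modes is
  provided — the descriptors (head-tail distance, C17-C18 torsion) are
  exposed, but the literature gives no quantitative criterion worth
  hard-coding.
* Interatomic distances alone do not predict regioselectivity (the
  H9-OH⁻ mean can undercut H12-OH⁻ while the barrier ordering goes the
  other way); the package reports descriptors and does not rank
  reactivity.
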