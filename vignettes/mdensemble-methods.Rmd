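---
title: "Models and numerical choices in mdensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in mdensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`mdensemble` packages the trajectory-comparison workflow used to contrast
two conformational states of a protein assembly — superposition/RMSD,
essential dynamics with free-energy landscapes, dynamical
cross-correlation, persistence-contact community networks, ion solvation
analysis, ensemble clustering, and an MM–GBSA-style energy decomposition.
This vignette records the models behind each stage, the parameters that
matter, and the numerical decisions a maintainer would otherwise have to
reverse-engineer from the code.

## Structures, trajectories and selections

Structures are parsed from PDB (via `bio3d`) into an atom table plus a
flat coordinate vector; ATOM and HETATM records are both kept, so waters
and ions are ordinary atoms. Alternate locations collapse to a single
conformer — highest occupancy wins, ties break by altloc letter — giving a
deterministic topology. Residue numbering is never rewritten, so literature
residue labels (Asp56, Glu104, ...) map directly onto selections.
Trajectories are a frames × 3N coordinate matrix bound to a topology;
multi-model PDB (plain text, round-trippable) and binary DCD are read.
XTC is not supported: no installed R reader exists, and transcoding to DCD
is routine. A truncated multi-model file fails with the index of the last
complete frame rather than silently shortening the ensemble.

Selections use a small AND-of-clauses grammar (`name`, `resno`, `resname`,
`chain`, `element`, `water`, `protein`, `ion`, `calpha`, `noh`). Unknown
chain or residue-name tokens are errors that list what is available;
typos in numeric ranges should not silently select nothing.

## Superposition and RMSD

Rigid-body fits use the Kabsch algorithm: SVD of the 3 × 3 covariance of
centered coordinates, with the determinant correction that excludes
reflections, so the rotation is always proper. Geometry with a
second singular value near zero (collinear atoms) is rejected. RMSD is
geometric (unweighted) over Cα-style selections — mass weighting changes
nothing for single-element selections and is deliberately omitted. The
test suite holds the SVD route to a quaternion-eigenvalue implementation
(an algebraically independent solution of the same problem) at 10⁻⁸ Å on
random instances.

Time series fit each frame on a *fit selection* and report RMSD on a
*report selection*; this separation lets one fit on a stable domain and
read deformation elsewhere. Replicas are pooled frame-by-frame with equal
weight for the headline mean ± SD, and per-replica summaries are attached,
because published shaded-band figures rarely say which convention they
used — emitting both costs nothing. An equilibration discard is a knob
with default 0.

## Essential dynamics and the free-energy landscape

PCA diagonalizes the full 3n Cartesian covariance of the fitted selection
(sample covariance, n−1 denominator), not per-residue scalar fluctuations.
Eigenvector signs are fixed by making each vector's largest-magnitude
component positive; otherwise projections flip between runs of an
eigensolver. Eigenvalues are clamped at zero (rank-deficient ensembles are
legal) and variance fractions sum to one.

The landscape is a Boltzmann inversion of the binned (PC1, PC2) density:
ΔG = −k~B~T·ln(ρ/ρ~max~), k~B~ = 0.0019872 kcal mol⁻¹ K⁻¹, T = 300 K by
default (the usual production temperature). The most occupied bin is
exactly 0 and empty bins carry `NA` — a sentinel, not an energy. The grid
is 80 × 80 over the data extent by default (`fel()`); the demo pipeline
uses 30 bins because its ensembles are small.

Basins are found by a watershed/persistence pass: occupied bins are
processed in order of increasing energy; regions merge at their saddle,
and a merged basin is reported only if its depth below the saddle clears
`depth_threshold`. Disconnected occupied islands — inevitable in sparsely
sampled tails, where single-count bins float free of the main blob — are
measured against the occupied-grid maximum ("sea level") instead of a
saddle. The deepest surviving basin is always reported. The default
threshold of 1.2 kcal/mol (≈ 2 k~B~T at 300 K) is chosen so that a
sampling island must out-populate a single-count bin by e² ≈ 7-fold before
it counts as structure; genuine substates in the two-state fixtures sit
several k~B~T deep and are unaffected. Ties at the global minimum (two
bins with identical maximal counts) belong to one basin once they merge;
only the surviving root is exempt from the threshold.

## Dynamical cross-correlation

C~ij~ is the normalized covariance of full 3-vector displacements about
the ensemble mean, c~ij~ = ⟨Δr~i~·Δr~j~⟩, computed per axis with matrix
cross-products and verified against a brute-force triple loop at 10⁻¹²
on small instances, and against `bio3d::dccm` as an established
independent implementation. One node per residue at its Cα. Atoms with
positional variance below 10⁻¹² Å² (frozen, or frames identical after
fitting) get `NA` rows rather than a division by zero. Display masking
blanks |C| < 0.4 — strictly below, so a coefficient exactly at the cutoff
survives — and always keeps the diagonal.

Fitting before correlation matters and is the default for real data: an
unremoved rigid translation saturates the matrix at +1 (a property the
tests assert). The synthetic generators, however, emit frames already
expressed in the reference frame, with no rigid-body diffusion to remove.
For such data the correlation-recovery analyses call `dccm(...,
reference = NULL)`: superposition would otherwise *bias* the estimate,
because subtracting the fitted common mode of a block-correlated
displacement field shifts every pairwise correlation (for the 2 × 12-block
target with intra 0.7 / inter −0.5, the fitted estimate lands near −0.69
rather than −0.5 — an estimator artifact, not a generator error). Real
trajectories need the fit because rigid diffusion dominates; generated
ensembles need its absence because there is nothing to remove.

Replica handling mirrors the RMSD stage: pooled frames by default, with
the mean of per-replica matrices available, since publications rarely say
which they plot.

## Dynamic network and communities

Nodes are residues; an edge requires any heavy-atom pair of the two
residues within 4.5 Å in *strictly more than* 75% of frames (both numbers
are config). The heavy-atom criterion follows the dynamic-network
literature; a Cα–Cα criterion at 4.5 Å would leave the graph almost
edgeless. Sequence neighbors (i, i±1 on a chain) are excluded so backbone
adjacency does not dominate betweenness. Edge distances are
D~ij~ = −ln|C~ij~|: strongly coupled (or strongly anti-coupled) residues
are close; the absolute value keeps D defined and non-negative, and the
natural log is a pure convention — any base rescales all distances and
preserves shortest-path orderings. Zero-correlation edges would be
infinitely far and are dropped with a warning.

Community detection is Girvan–Newman: repeatedly remove the edge of
maximum shortest-path betweenness (weighted by D when present;
a config flag, since topology-only betweenness is also defensible),
recompute, and keep the component partition of maximum Newman–Girvan
modularity. Modularity is evaluated on the original unweighted graph, so
the quantity being maximized is the same one the exhaustive test oracle
maximizes. Ties in betweenness break by lexicographic edge id and
equal-modularity partitions resolve to the earliest (coarsest) — both
purely for determinism. Communities smaller than three residues are
omitted from the reported partition. Girvan–Newman is a divisive
heuristic: its dendrogram need not contain the global
maximum-modularity partition for every graph (rings are a classic
counterexample), so oracle equivalence is asserted on a curated suite of
clique-based community graphs up to ten nodes, where the optimum is in
reach and exhaustive enumeration (Bell(10) = 115,975 partitions) is
feasible.

Difference contact network analysis holds the community partition of the
anchor state fixed, maps the second state's edges onto it, and reports the
signed change in inter-community connection strength, where strength is
the summed *contact persistence* of edges joining two communities.
Persistence, a contact probability, is the natural "strength"; −ln|C| is a
distance and summing it would invert the semantics. The result is exactly
antisymmetric under swapping the states.

## Ion solvation

g(r) is a distance histogram normalized by the exact shell volume
(4π/3)(r₂³−r₁³) — not the 4πr²dr approximation — frame count, center
count, and bulk density (target count over box volume unless overridden).
Minimum-image distances are used when an orthorhombic box is present;
r~max~ must then fit in half the box. The running coordination number
n(r) is the cumulative raw count per center-frame, so it is exact rather
than a quadrature of g. Defaults: 0.05 Å bins, r~max~ 8 Å.

`coordination_number()` evaluates n at the first minimum of a smoothed
g(r) after the first peak; if no peak rises above g = 1.5 it refuses and
asks for an explicit cutoff rather than guessing. Coordination-mode
catalogues list every oxygen within 3.0 Å (default; a sweep over
2.6–3.2 Å is available) categorized as sidechain, backbone (atom name
O/OXT) or water oxygen; a bidentate carboxylate legitimately contributes
two records. Water hydrogens are never counted — the relevant
ion–water distance is to the oxygen.

The package ships `synthetic_calcium_site()`, an *idealized* EF-hand
calcium site: pentagonal-bipyramidal sevenfold coordination at 2.4 Å
carrying the canonical ligand identities of calmodulin's second N-lobe
EF-hand (sidechain Asp56/Asp58/Asn60/Asp64, backbone Thr62, bidentate
Glu67). It is constructed geometry for exercising the scan — not
deposited crystal coordinates — and is labelled synthetic everywhere.

## Ensemble clustering

The pairwise frame metric is post-superposition RMSD. Clustering is the
deterministic GROMOS neighbor-count scheme: the frame with the most
neighbors within the cutoff (2.0 Å default) seeds a cluster, it and its
neighbors leave the pool, repeat; ties go to the lower frame index. The
representative of a cluster is its medoid — the member minimizing summed
intra-cluster RMSD — which the tests verify exhaustively. Cross-state
comparisons require selections that map residue-for-residue and error
with the mismatches listed. Note that a state difference which is a pure
rigid motion is invisible to this metric by construction; deformations
must be internal.

## MM–GBSA energy decomposition

Single-trajectory protocol: complex, receptor and ligand geometries come
from the same frame, so internal gas-phase terms cancel and ΔE~gas~
reduces to receptor–ligand cross terms. Per frame:

* ΔE~ele~: Coulomb sum k~e~ q~i~q~j~/(ε~r~ r~ij~), k~e~ = 332.0636
  kcal mol⁻¹ Å e⁻², ε~r~ = 1 (solute dielectric).
* ΔE~vdW~: 12-6 Lennard-Jones with R\*~ij~ = R\*~i~+R\*~j~ and
  ε~ij~ = (ε~i~ε~j~)^1/2^; the pair minimum is exactly −ε~ij~ at R\*~ij~.
* ΔG~GB~: pairwise generalized Born,
  −½(1/ε~in~−1/ε~out~)k~e~Σq~i~q~j~/f~GB~ with
  f~GB~ = [r² + a~i~a~j~exp(−r²/4a~i~a~j~)]^1/2^ and f~GB~(i,i) = a~i~.
  Effective radii a come from Hawkins–Cramer–Truhlar pairwise
  descreening (offset 0.09 Å, scale 0.8, both config); an isolated atom
  recovers its intrinsic radius exactly, anchoring the analytic Born-ion
  limit, and the long-range pair term approaches screened Coulomb. Radii
  are recomputed separately for complex, receptor and ligand — that
  difference *is* the desolvation penalty.
* ΔG~nonpolar~ = γ·ΔSASA + b with γ = 0.0072 kcal mol⁻¹ Å⁻² and b = 0.
  SASA is Shrake–Rupley with a deterministic golden-spiral point set
  (960 points default), so results are bit-reproducible; the quadrature
  is rotation-invariant only to its discretization error, which the
  tolerance of the corresponding test reflects.

Dielectrics default to ε~in~ = 1, ε~out~ = 78.5 and the probe to 1.4 Å.
The per-frame identities ΔE~gas~ = ΔE~vdW~+ΔE~ele~ and
ΔG~solv~ = ΔG~GB~+ΔG~nonpolar~ hold to 10⁻⁹ by construction and are
asserted. The solute entropy term is recorded as "not computed" — normal-
mode analysis is out of scope. Two totals are reported, with and without
the nonpolar row: printed end-point-energy tables are split on whether
their ΔG~binding~ row includes the surface-area term (summing a published
unbound column −1840.20 − 191.96 + 1945.76 reproduces its printed −86.40
exactly only when the surface-area row is excluded), so the package
refuses to privilege either convention. `energy_table()` rebuilds a
decomposition from printed per-term rows so published tables can be
re-aggregated and differenced; `aggregate_and_compare()` yields per-term
ΔΔG between states.

Parameters arrive as a plain per-atom table (charge, R\*, ε, GB radius) —
documented text, trivially constructed for toys — rather than through
force-field file parsing; the calcium ion constants recorded in the demo
configuration are R\* = 1.79 Å, ε = 0.0140 kcal/mol.

## The synthetic generators: what they emulate, and what not

`generate_correlated_ensemble()` draws frames as reference + correlated
Gaussian displacements. The same N × N correlation matrix is applied
independently to x, y and z (isotropic per particle), which makes the
displacement-vector correlation — the quantity the DCCM estimates —
*exactly* the target matrix. Correlated draws use the symmetric
eigendecomposition square root Σ^1/2^ = VΛ^1/2^V′, fixed here as part of
the generator contract: any square root gives the same statistics, but
only a stable choice gives bit-identical streams across versions.
Specs are validated (symmetry, unit diagonal, positive semi-definiteness,
positive amplitudes) before any frame is produced, and identical
spec + seed yields byte-identical trajectories.

`generate_two_state_ensemble()` mixes two such ensembles with Bernoulli
labels returned for validation. `generate_solvation_toy()` fixes an ion,
places a jittered shell at the stated radius, and fills the box with an
ideal-gas bulk (uniform, no excluded volume except the shell sphere), so
g = 1 in the bulk is analytic. The bulk count is density × box volume;
placement is by rejection sampling with bounded retries, and a spec whose
exclusion sphere swallows the box fails loudly.

What the generators deliberately do not emulate: force fields, water
structure, thermostats, time correlation (frames are independent draws),
rigid-body diffusion, or anharmonicity. Passing tests therefore
demonstrate that the analysis machinery recovers known statistical
structure, not that any biological conclusion about a real system is
reproduced — the original microsecond trajectories would be required for
that, and the ensemble-scale numbers of such studies (RMSD means,
variance fractions, absolute binding energies, water-peak positions from
explicit solvent) are documented here as descriptive context only.

## Pipeline, demo conditions and problem sizes

One YAML config drives both states, guaranteeing the bound/unbound
contrast is computed under identical parameters. YAML is used because it
is the plain-text config format with an installed R parser; the config
contract (defaults filled, unknown keys rejected with a nearest-match
hint, lossless round-trip) is unaffected by the surface syntax. Stages
run in dependency order; a failed stage marks dependents `blocked` rather
than silently skipping them, and the numeric payload of a report is
byte-identical across runs at a fixed seed (timings and paths live
outside the compared payload).

The shipped demo is a 24-particle, two-block system (4.2 Å grid blocks
meeting at an interface), 400 frames per state, displacement amplitude
0.3 Å, intra-block correlation 0.7, inter-block −0.2 (bound) vs −0.5
(unbound), and a 6 Å interface shift in the unbound reference that severs
the inter-block contacts — a miniature of the "weakened interface, more
anti-correlated inter-domain motion, weaker binding" phenotype. Heavier
statistics (10⁴ frames) are used where Monte-Carlo convergence is the
point (correlation recovery to ±0.05); these sizes keep the full suite
within a couple of minutes on one CPU and were chosen once, as study
conditions, not tuned against outcomes.

## Known limitations

* PDB only for structures (no mmCIF), multi-model PDB/DCD for
  trajectories, orthorhombic boxes only for minimum-image distances.
* Girvan–Newman is exact only against its own modularity criterion on
  community-structured graphs; no weighted-modularity or alternative
  community methods.
* The GB model is a single pairwise-descreening variant; no PB solver,
  no salt term, no normal-mode entropy.
* Clustering offers the GROMOS scheme only; linkage methods are out of
  scope.
* The synthetic ensembles are statistically, not physically, realistic —
  see above.
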