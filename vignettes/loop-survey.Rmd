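---
title: "Surveying TTA/UUA propeller-loop conformations in telomeric G-quadruplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying TTA/UUA propeller-loop conformations in telomeric G-quadruplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4loops)
```

## The problem

The single-stranded 3' overhang of human telomeric DNA,
5'-(TTAGGG)~n~, folds into G-quadruplexes: stacks of planar G-quartets
held together by Hoogsteen hydrogen bonds around central potassium
ions.  In every crystal structure of the human telomeric quadruplex
determined to date -- native DNA, the RNA (TERRA) analogue, and the
complexes with quadruplex-binding ligands -- the fold is parallel, and
the TTA (or UUA) spacer triplets form *propeller* loops running along
the outside of the three-quartet core.  The core is nearly rigid across
all of these structures; essentially all of the conformational
variability lives in the loops.  Characterizing that variability
matters for structure-based design of quadruplex-binding small
molecules: a docking campaign that treats the loops as rigid is
sampling only one of at least a dozen experimentally observed loop
shapes.

`g4loops` implements the survey machinery for these loops end to end:

1. **structure input** -- PDB/mmCIF parsing into per-chain residue
   records, with modified-residue normalization (e.g. the brominated
   uridines used for crystallographic phasing), alternate-conformer
   resolution, and automatic location of G-tracts and the
   (T|U)(T|U)A triplets between them;
2. **geometry** -- the six backbone torsions and the glycosidic
   torsion, endocyclic sugar torsions, pseudorotation analysis, base
   planes and Kabsch superposition;
3. **loop typing** -- a twelve-class base-stacking classifier;
4. **statistics** -- the structure-set census, pucker-frequency tables
   and torsion profiles;
5. **synthetic structures** -- generators that build every input the
   test suite needs, so the whole pipeline is verifiable offline.

## Torsions and sugar pucker

Backbone torsions follow the standard nucleic-acid definitions
(alpha: O3'(i-1)-P-O5'-C5' through zeta: C3'-O3'-P(i+1)-O5'(i+1)), and
the glycosidic torsion chi is O4'-C1'-N9-C4 for purines and
O4'-C1'-N1-C2 for pyrimidines.  All angles are reported in degrees on
`(-180, 180]` with the IUPAC sign convention.  Angles whose defining
atoms are absent (chain termini, disordered residues) are returned as
`NA` rather than failing, so terminal loop residues keep whatever
subset of their torsions is defined.

Sugar conformation is summarized by the Altona--Sundaralingam
pseudorotation parameters.  With the five endocyclic torsions
$\nu_0 \ldots \nu_4$ of the furanose ring, the phase $P$ and amplitude
$\tau_m$ satisfy

$$\tan P = \frac{(\nu_4 + \nu_1) - (\nu_3 + \nu_0)}
                {2\,\nu_2\,(\sin 36^\circ + \sin 72^\circ)},
  \qquad \nu_2 = \tau_m \cos P,\; \tau_m > 0.$$

The implementation recovers both as
$\tau_m\sin P = ((\nu_4+\nu_1)-(\nu_3+\nu_0)) / (2(\sin36^\circ+\sin72^\circ))$
and $\tau_m\cos P = \nu_2$, so `atan2` fixes the quadrant even when
$\nu_2 = 0$ (then $P$ is exactly 90 or 270 degrees) and the transform
inverts the cosine model exactly.  A flat ring (all $\nu_j = 0$) has no
defined phase and is reported as `NA`.  Pucker classes are the ten
36-degree decades of the pseudorotation wheel, C3'-endo at
$[0^\circ, 36^\circ)$ through C2'-exo at $[324^\circ, 360^\circ)$; any
phase is first normalized modulo 360.

```{r pucker}
sugar_pucker(build_ring(phase_P = 162, amplitude_tau_m = 38))
```

## The twelve loop types

Loop shapes are classified from three pairwise relations between the
base planes of the loop residues L1, L2 (T or U) and L3 (A):

* **stacked**: centroid distance at most `d_stack` (5.0 A),
  interplanar angle at most `a_stack` (30 deg), and lateral offset --
  the centroid separation projected into the mean plane -- at most
  `o_stack` (2.5 A);
* **perpendicular**: interplanar angle at least `a_perp` (60 deg) with
  centroids within `d_near` (7.0 A);
* **close / away**: centroid distance within or beyond `d_close`
  (6.5 A).

The twelve type descriptors are qualitative, so these cutoffs are the
package's own operational choices, anchored on
standard pi-stacking geometry (3.3--3.6 A ring separation, small
offset) with slack for crystallographic variation; every one of them
is a `loop_thresholds()` parameter, which makes sensitivity to the
cutoffs a one-argument experiment.  Base-plane normals carry no sign,
so interplanar angles are folded onto `[0, 90]`.

The rulebook matches the fingerprint (stacked set, perpendicular set,
proximity pattern) against the twelve rows.  Three ambiguities are inherent in the descriptors and are handled
explicitly:

* **Type 1 sub-types.**  The dominant native arrangement stacks the
  adenine on the first T/U.  The central residue either sits
  perpendicular to the adenine (sub-type `1a`) or stacks on its outer
  face (`1b`).  Both are reported with a sub-label but count as type 1
  in every statistic.
* **Types 10 and 12** have identical qualitative descriptors (central
  residue stacked under the adenine, first residue away).  Without
  further information the classifier returns the honest ambiguity set
  `{10,12}`; with an exemplar library it assigns the type whose
  exemplar minimizes the all-heavy-atom RMSD after superposition.
* **Types 6 and 8** differ only in chemistry: the same geometry is
  type 6 for a TTA loop and type 8 for the UUA (RNA) loop.
  Types 5 and 7 differ in the proximity partner of the first residue
  (close to both stacked bases versus close to the central one only),
  which the fingerprint resolves deterministically.

A fingerprint matching no row (for instance three mutually stacked
bases) is reported as `unclassified`, and a loop with an undefined
base plane is never typed.  Loops are typed per crystallographically
unique copy; nothing is averaged across copies.

```{r typing}
tri <- build_triplet(10)
assign_loop_type(loop_fingerprint(tri))
assign_loop_type(loop_fingerprint(tri),
                 exemplars = build_exemplar_library(), loop = tri)
```

## Quartet-core superposition

Structures are compared by superposing the twelve core guanines (four
tracts of three) on a reference with the Kabsch algorithm, using the
ten guanine base heavy atoms (N9, C8, N7, C5, C6, O6, N1, C2, N2, N3).
Base atoms only: the comparison targets the stacked quartets
themselves, so sugars and backbone -- which vary with pucker -- are
deliberately excluded.  A parallel quadruplex has four-fold rotational
symmetry, making the tract labelling arbitrary; the alignment
therefore tries all four cyclic permutations of the tract
correspondence and reports the best.  Reflections are suppressed by
the usual determinant correction, degenerate (collinear) inputs are
computed but flagged, and multi-model (NMR-style) ensembles get one
result per model plus the ensemble mean via
`quartet_core_rmsd_ensemble()`.

Recomputing cross-structure alignment statistics for the real
telomeric quadruplex entries requires the deposited coordinates
themselves, which the package deliberately does not ship; `run_analyze(dir, reference = "1kf1")` on a directory
of downloaded entries recomputes the full table.  Offline, the test
suite pins the properties any correct alignment must have: exact
self-identity, invariance under four-fold relabelling, argument
symmetry, and agreement with a brute-force rotational search on small
point sets.

## Census and consensus statistics

`census()` aggregates per-structure records into the survey totals
(structures, typed loops, distinct types, type-1 occurrences, distinct
space groups after whitespace normalization, mean resolution to two
decimals).  `pucker_frequency()` tabulates pucker classes by loop
residue role with percentages to one decimal, always alongside the raw
counts, and `consensus_match()` tests a loop against the native
consensus triplet C1'-exo, C3'-endo, C2'-endo.  The package ships the
structure-set census and the per-loop pucker assignments of the 19
surveyed crystal structures as plain CSV fixtures, so every one of
these statistics is recomputable without network access:

```{r census}
census(load_census_fixture())
pucker_frequency(load_pucker_fixture("type1"), "type1")
```

Torsion aggregation uses circular statistics (`circular_mean()`,
`circular_sd()`), so wrap-around pairs like 179 and -179 degrees
average to 180 rather than 0.  Raw per-loop traces remain the primary
output -- nothing is averaged across crystallographically unique
copies -- and the circular summary rows are marked as derived extras.

## The synthetic generators

The generators exist to make every geometric claim testable without a
single download, and their design reflects that purpose:

* `build_chain()` places atoms by internal coordinates
  (bond length, bond angle, torsion), so re-measuring any targeted
  torsion on the noise-free output reproduces it to numerical
  precision (the round-trip tests assert 1e-6 degrees).  Bond lengths
  and angles are fixed chemically plausible standards.
* `build_ring()` realizes a requested pseudorotation state by placing
  pentagon atoms with out-of-plane displacements proportional to
  $\cos(P + 144^\circ(j-2))$, then calibrates phase and amplitude
  against the package's own measurement.  Ring closure is approximate
  by construction, hence the documented tolerance of 2 degrees for
  amplitudes in the 30--45 degree range (in practice the calibration
  converges far tighter); amplitudes outside that range warn.
* `build_triplet()` poses idealized bases realizing each of the twelve
  descriptor rows under the default thresholds, and
  `build_toy_quadruplex()` assembles a 22-nucleotide parallel
  quadruplex -- the native unimolecular sequence layout -- with an
  exactly four-fold-symmetric core and any three loop rows.

What the synthetic structures do *not* emulate is just as important:
there is no force field, no crystal packing, no solvent, no B-factor
or occupancy structure beyond defaults, and loop backbones in the
triplets are dummies.  Tests passing on synthetic inputs therefore
demonstrate the correctness of the geometry, classification and
bookkeeping, not the empirical distribution of loop types in real
crystals; the latter enters through the shipped census fixtures and,
when coordinates are available, through `run_analyze()` on the real
entries.

## Numerical choices and degenerate inputs

* Angles live on `(-180, 180]`; exact -180 is folded to +180.
* Orthogonality of rotations is asserted to 1e-9, angle round trips to
  1e-6 degrees; these tolerances are stated in the tests that use
  them.
* Collinear torsion quadruples, flat rings, and bases with fewer than
  three ring atoms all return explicit undefined signals (`NA` or
  `NULL`), never fabricated numbers.
* Alternate conformers: the highest-occupancy copy wins; exact ties go
  to altloc "A".
* A residue counts as *poorly resolved* -- and its loop is excluded
  from statistics, with the exclusion logged -- when any of the nine
  backbone/sugar atoms (P, O5', C5', C4', C3', O3', C1', C2', O4') or
  any six-membered base-ring atom is missing.  Crystallographic
  depositions flag disordered loops without a uniform criterion; this
  atom-completeness rule is the package's concrete, reproducible one.
* Unknown residue names are excluded loudly (warning plus exclusion
  record), never silently coerced; the alias table for modified
  residues is an editable CSV.

Problem sizes in the shipped tests are chosen to keep the default
suite fast while exercising every code path: 200-spec round-trip
sweeps for the chain and ring builders, 20 brute-force superposition
cross-checks on 4--6-point sets, and toy quadruplexes for the
end-to-end runs.

## Known limitations

* The stacking thresholds are operational definitions; borderline real
  loops can legitimately fall on either side of a cutoff, which is why
  every threshold is exposed.
* Generalized (Cremer--Pople) puckering, helicoidal base-pair
  parameters and groove geometry are out of scope.
* The classifier describes loop geometry only; it says nothing about
  ligand chemistry, binding modes, crystal packing or energetics.
* mmCIF support covers the coordinate records; header metadata
  (resolution, space group) is currently extracted from PDB-format
  headers only.
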