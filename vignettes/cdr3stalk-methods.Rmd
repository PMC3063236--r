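---
title: "Methods: geometry, mutation modelling and entropy of the CDR3β stalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, mutation modelling and entropy of the CDR3β stalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdr3stalk)
```

This vignette records how each computation in the package is defined,
which knobs it exposes, and where its limits are.  It states no result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The question being operationalised

The CDR3β of most TCR β chains opens with `CASS`; the serine at IMGT
position 107 is buried in the stalk of the loop.  TRBV13-2 (mouse) and
TRBV12-5 (human) instead carry `CASG`.  Three linked computational
claims make the glycine interesting: (1) CASG and CASS receptors have
indistinguishable stalk geometry, so nothing moves in to compensate
for the missing side chain; (2) consequently an unfilled cavity sits
where the serine hydroxymethyl would be, and an in-silico G107S drops
into it at a canonical rotamer without moving any other atom while
picking up hydrogen bonds; (3) in dynamics, the substitution lowers
the conformational entropy of the loop.  Each claim maps to one module
below.

## Anchoring IMGT positions

Crystal structures use author numbering, not IMGT numbering, and label
chains inconsistently, so β-chain identity and the CDR3β sequence are
explicit inputs (a manifest row), never auto-detected.  `anchor_imgt()`
locates the unique occurrence of the CDR3β sequence in the chain;
its first residue is the conserved C104, its fourth the G/S under
study, and the loop range runs through IMGT 119 where the chain is
long enough.  Y40 is found either at an explicit author number or as
the unique tyrosine in a configurable author-number window (default
30–50); position 42 is two residues downstream in chain order.  A
chain without a locatable tyrosine yields `pos40 = NULL` and distance
*b* becomes `NA` — that is data, not an error (several deposited CASS
structures lack a usable Y40).  When a manifest's stated chain does
not carry the CDR3β, the pipeline falls back to a scan over all chains
and accepts a unique match, logging the correction; the printed CDR3β
sequences are the only ground truth available for chain assignment.

Alternate locations keep conformer A (the `bio3d` reader's
convention); HETATM records and waters are excluded; nonstandard
residues translate to `X` and cannot anchor.

## The stalk distance triple

`measure_stalk()` takes distance *a* from Cα(107) to the *nearest*
backbone carbonyl carbon among countercurrent-strand residues.  The
countercurrent strand is defined operationally as the anchored loop
residues from IMGT position 104 + ⌈L/2⌉ through 119 (L = loop length),
which excludes positions 104–108 and the apex, so a sequence
neighbour can never be selected.  The chosen partner and the three
nearest candidates are attached to the result for diagnosis, because
the original measurements were taken interactively and the partner
choice per structure is not recorded anywhere.  Distance *b* uses the
tyrosine side-chain hydroxyl oxygen (OH), not the backbone O — the
hydrogen-bonding partner of the serine hydroxyl.  Group summaries use
the sample standard deviation (n−1); this convention reproduces the
published ±0.16/±0.53 cells exactly, an n denominator does not.
Values are reported at two decimals, matching the printed precision.

```{r stalk}
summarize_groups(reference_distances())[, 1:8]
```

## Geometry kernels and their thresholds

All cutoffs live in one `geometry_config()` object and every function
takes it as an argument:

* hydrogen bonds: heavy-atom donor–acceptor distance in [2.4, 3.5] Å
  and an antecedent–atom–partner angle ≥ 90° at both ends, waived for
  an atom whose covalent antecedent is not in the supplied set.
  Crystal structures lack hydrogens, so the criterion is heavy-atom
  only; the interactive tool used for the original bond lists never
  published its thresholds, so no attempt is made to reproduce those
  lists atom-for-atom — only the specific bonds the analysis turns on.
* van der Waals radii: Bondi (C 1.70, N 1.55, O 1.52, S 1.80 Å);
  clashes are pairs closer than the radius sum minus a 0.4 Å
  tolerance.
* cavity probe: the free radius at a point is
  min(d(center, atom) − r_vdw(atom)) over the environment; a gap is
  present when a probe of radius 1.4 Å (water-sized) fits.  The probe
  is used only as a before/after contrast around side-chain placement:
  absolute free radii depend on how the environment is chosen, and at
  a site engineered for hydrogen bonding a partner oxygen at ~3 Å
  already bounds the free radius near 1.5 Å.

Superposition is the Kabsch least-squares fit (SVD with a determinant
correction, so always a proper rotation), optionally weighted; it is
validated against a brute-force search over rotations in the test
suite, and degenerate (collinear, n < 3) inputs are rejected.

## Rigid-backbone G107S modelling

The structural claim is existential — the serine fits *somewhere*
canonical without anything else moving — so the mutator deliberately
does less than a modelling suite: the backbone is frozen, Cβ is built
from ideal internal coordinates (1.53 Å, tetrahedral angles, enforced
L-chirality; three backbone points are planar and carry no chirality
of their own, so the constructor always places the L side), and Oγ is
scanned over χ₁ ∈ {−60°, 60°, 180°}.  Continuous χ₁ optimisation or
neighbour repacking would overstate the method.  Clash scoring exempts
the mutated residue's own atoms and the backbone of its sequence
neighbours (the 1-2/1-3 bonded shell across the peptide bond);
everything else in the structure is environment.  A placement is
feasible iff it has zero clashes; among feasible placements the best
has the most hydrogen bonds, then the lowest maximum overlap, then χ₁
closest to gauche⁻ (the most common serine rotamer).  `apply_placement()`
appends the two new atoms and renames the residue — every original
coordinate is carried over bit-for-bit, which the tests assert.

Self-consistency check: applied at an existing serine, some rotamer
must land within 0.8 Å of the deposited Oγ; on ideal fixtures it is
exact, and on real structures the slack absorbs deviation of deposited
side chains from ideal internal coordinates (reconstructed Cβ atoms
sit 0.03–0.35 Å from deposited ones on a real test structure).

## Quasi-harmonic entropy

`quasiharmonic_entropy()` implements the covariance-matrix estimator:
after removing rigid-body motion, the mass-weighted covariance of the
atomic fluctuations is diagonalised, each eigenvalue λₖ (amu·Å²)
defines ωₖ = √(k_BT/λₖ), and the entropy is the quantum
harmonic-oscillator sum S = R Σₖ[αₖ/(e^{αₖ}−1) − ln(1−e^{−αₖ})] with
αₖ = ħωₖ/(k_BT), in cal·mol⁻¹·K⁻¹ at 300 K by default (the units and
mass-weighting convention of the original analysis are unstated; both
choices here are declared and fixed in one constants table).
Numerical choices:

* superposition reference: the ensemble mean, iterated twice
  (fit → new mean → refit); configurable to first-frame or none.
* eigenvalues below 10⁻⁸ amu·Å² are numerically zero (rigid-body or
  constraint modes) and are excluded from the sum; `n_modes_used`
  reports what remained.  Fitting removes six degrees of freedom, so
  an N-atom ensemble yields at most 3N−6 meaningful modes.
* fewer frames than 3N triggers a rank-deficiency warning rather than
  an error: the estimator is still defined, just noisy.

The MD simulations behind the original wild-type/mutant comparison
(4.5 ns, implicit solvent) are out of scope — this module analyses
trajectory ensembles, it does not generate physical ones.  Multi-model
PDB is the input format; frames must agree atom-for-atom, enforced
with the offending model named.

### Validation against a closed form

`make_gaussian_trajectory()` draws frames in mass-weighted mode space
with chosen per-mode variances, so the true spectrum — and hence the
true entropy — is known exactly.  The generator also returns the
first-order (delta-method) sampling SE of the estimator and its
second-order expectation shift: the mode entropy is concave in λ, so
the plug-in estimator is biased slightly low, and the tests compare
the estimate against `analytic_entropy + analytic_bias` within three
SEs.  Two subtleties worth recording:

* the delta method treats sorted sample eigenvalues as estimates of
  distinct population modes, which fails for *degenerate* spectra
  (eigenvalue repulsion spreads equal eigenvalues far beyond their
  individual sampling noise).  The validation ensembles therefore use
  a distinct geometric spectrum (0.02·1.35ᵏ amu·Å²).
* superposition removes six degrees of freedom and correspondingly
  lowers the estimate, so the closed-form comparison runs on
  pre-aligned ensembles with `fit = "none"`; the rigid-motion
  invariance property (rotated/translated frames give the same answer
  to 10⁻³ with `fit = "mean"`) is tested separately.

Validation sizes: 5 atoms (15 modes) × 2000 frames for closed-form
recovery, 400 frames for invariance properties, 48 atoms × 400 frames
for the floppy/stiff comparison in the analysis scripts — large
enough for stable spectra, small enough that the whole suite runs in
seconds.

## Synthetic fixtures

`make_hairpin()` builds two antiparallel extended strands
(φ/ψ = −139°/135°) joined by a two-residue turn whose four dihedrals
are optimised deterministically so the facing Cα–Cα separation matches
the spec (default 4.8 Å, echoing the ~5 Å crystallographic stalk
scale).  A serine stalk gets its ideal side chain at χ₁ = −60°; a
glycine stalk leaves the pocket empty by construction.  The optional
Y40 analogue is a five-residue segment (author numbers 38–42) placed
so its hydroxyl sits 3.05 Å from the idealized Oγ site along the
outward normal: inside the hydrogen-bond window, outside the
water-probe exclusion — which is what makes the fixture
simultaneously "open cavity" and "hydrogen-bond acceptor available",
the two properties the mutation tests need.  These fixtures are
geometric stand-ins: ideal bond geometry, no side chains beyond the
stalk and the Y40 analogue, a stand-in hydroxyl segment rather than a
real tyrosine ring.  Passing tests on them certifies the machinery
(anchoring, measurement, placement, scoring), not crystallographic
agreement, which is why the per-structure distance checks are tied to
the real deposited files when present.

`make_trbv_fasta()` writes V-gene sets with exact CASS/CASG/other
counts, cysteine-free elsewhere so the C104 anchor is unambiguous.
The motif anchor in `classify_motif()` is the last C-followed-by-A in
the final 16 residues — wide enough for both germline C-termini
(which end a few residues after C104) and full rearranged CDR3β
strings up to 15 residues.

All generators are pure functions of (spec, seed): byte-identical
output for identical inputs, and the caller's RNG stream is left
untouched.

## Known limitations

* The ten deposited TCR structures are inputs, not package contents;
  per-structure distance and mutation checks run only where the user
  has fetched them.  The shipped manifest's chain assignments are
  best-effort and self-correct via the unique-CDR3 scan.
* The countercurrent-strand partner rule is a reconstruction of an
  interactive measurement; if a recomputed distance *a* ever falls
  outside the ±0.05 Å rounding band of a published cell, the attached
  candidate list is the first place to look.
* Hydrogen-bond detection is geometric, not energetic, and hydrogens
  are never modelled.
* The entropy module treats trajectories as given; force fields,
  equilibration and potential energies are out of scope.
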