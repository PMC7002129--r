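---
title: "Inferring chlorophyll f binding sites in far-red Photosystem I"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring chlorophyll f binding sites in far-red Photosystem I}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chlfsites)
```

## The problem

Cyanobacteria capable of far-red light photoacclimation (FaRLiP) remodel
Photosystem I (PSI) when visible light is depleted: six core subunits are
replaced by paralogs and roughly 8% of the chlorophyll a complement is
replaced by chlorophyll f, extending light harvesting to nearly 800 nm.
Chl f differs from Chl a only by a formyl group in place of a methyl at
the C2 position of the chlorin macrocycle — two hydrogens traded for one
oxygen. At the ~3 Å resolution of current cryo-EM maps of these
complexes, that difference is invisible, so Chl f sites cannot be read
off the density. They must be inferred from circumstantial structural
evidence:

1. **Hydrogen-bond donors** poised near the C2 substituent. A formyl
   oxygen is an H-bond acceptor; a Tyr hydroxyl, backbone amide or water
   sitting 2.4–3.5 Å from the C2 substituent is positioned to select for
   Chl f over Chl a. The same logic identified Chl b (C7 formyl) in
   early light-harvesting complex II structures.
2. **Local sequence divergence.** Far-red paralogs diverge most exactly
   where pigment remodelling happens; a chlorophyll surrounded by
   low-identity sequence is more plausibly a remodelled site.
3. **Structural site changes.** Lost or gained neighbouring pigment
   sites, and changed axial ligands, mark regions the far-red form has
   rebuilt.

This package implements that inference chain — cofactor census, chlorin
geometry, donor scanning, homolog superposition and conservation
mapping — plus the internal-standard HPLC quantitation that counts how
many Chl f copies a monomer carries, and seeded generators that make
every stage testable offline.

## Pigment census and structure I/O

Coordinate files (PDB via bio3d, mmCIF via a built-in `atom_site`
reader) are reduced to a flat atom table. Alternate locations keep the
highest-occupancy copy (ties: alphabetical alt-loc id) so the census is
deterministic. Residue codes map to pigment classes through an
overrideable `ligand_code_table()`; unlisted chlorin-family codes warn
rather than silently becoming `OTHER`, because a deposition using an
unexpected Chl f code must not be miscounted. Counts report file
contents verbatim — assembly-level bookkeeping (e.g. trimer totals
that disagree with three times the monomer list) is deliberately not
reconciled.

## Chlorin geometry

* **Ring mapping.** Macrocycle atoms are mapped to IUPAC positions
  (C1–C20, N21–N24, MG) through a configurable name table; both the
  generator's literal naming and the PDB chlorophyll convention
  (C1A…CHD, NA–ND) are bundled. MG is mandatory; up to four macrocycle
  atoms may be missing (real maps drop atoms). Consecutive ring-carbon
  distances are validated against a 1.2–1.7 Å covalent envelope.
* **Ring planes** are least-squares fits through *all* mapped macrocycle
  heavy atoms (smallest singular direction of the centered coordinates),
  not the four nitrogens — robust to missing atoms and matching the
  field's informal "ring plane". The normal's sign is arbitrary, so all
  interplane angles are folded into [0°, 90°].
* **C2 substituent**: the unique non-ring heavy atom within 1.8 Å of C2
  (a C–C bond is ~1.5 Å; 1.8 Å excludes nonbonded 2.4 Å contacts).
  Zero or multiple candidates are hard errors, never guesses.
* **Stacking multimers**: chlorophyll pairs with Mg–Mg ≤ 9 Å, plus the
  transitive closure into monomer/dimer/trimer components. Stacked,
  near-parallel chlorins are the low-energy "red" antenna sites whose
  remodelling is diagnostic of far-red acclimation. No community
  standard exists for a "stacked" cutoff; 9 Å captures adjacent-ring
  pairs while excluding lattice neighbours, and is a visible, tunable
  parameter.
* **Axial ligands**: non-pigment heavy atoms 1.9–3.0 Å from MG,
  classified (His side chain, water, backbone carbonyl, side-chain O,
  lipid headgroup, other).
* **C2 crowding**: a probe oxygen is modelled 1.2 Å beyond the
  substituent carbon along the C2→substituent direction — a linear
  simplification of sp² formyl geometry (the real C=O is bent ~120°).
  Heavy atoms within 3 Å of the probe argue against a formyl group
  fitting. Both the extension and radius are arguments.

## Donor scanning and candidate scoring

Donor atoms follow a fixed table: Ser/Thr/Tyr hydroxyl O, Asn/Gln amide
N, Lys/Arg basic N, His ring N, every backbone amide N, water O. Because
deposited models carry no hydrogens, the scan is distance-only — no
donor–H–acceptor angle term. Distances are measured to the C2
substituent heavy atom as a proxy for the formyl oxygen (models built as
Chl a have no formyl O; the proxy sits up to ~0.5 Å short). The default
window, 2.4–3.5 Å, brackets the H-bond distances such structures
exhibit (≈2.5–3.5 Å); contacts ≤3.2 Å are flagged "strong". Carbonyl
oxygens in the window are reported as a separate polar-contact list and
never enter the donor score: they are acceptors, but practitioners list
them when discussing possible H-bond networks.

Candidates are ranked by an explicit additive score,

$$\mathrm{score} = w_1\,h + w_2\,(1 - c) + w_3\,s,$$

with $h$ the H-bond term (1 at ≤2.6 Å decaying linearly to 0 at 3.5 Å),
$c$ the mean windowed sequence identity of the pigment's 8 Å protein
environment, and $s$ an indicator of structural change (gained site,
changed axial ligand, or a lost/gained site within 10 Å). Missing
evidence contributes 0, so partial pipelines still rank. Equal weights
are the default; the additive form is an explicit formalization of
evidence that experts weigh qualitatively — it is a transparent scoring
convention, not a fitted model, and ties break alphabetically by site
label so output is reproducible.

## Homolog comparison

Superposition uses the Kabsch algorithm (reflection-corrected SVD) on
explicitly paired Cα atoms only; pigments are never fit targets because
pigment movement is the measurement. Chain pairings (paralog → reference)
are supplied, not guessed. Site correspondence is greedy nearest-Mg
matching under 2.5 Å (shortest distances first, each site used once);
unmatched reference sites are *lost*, unmatched query sites *gained*.
On realistically separated sites greedy matching equals exhaustive
optimal matching (tested against a brute-force oracle up to six
pigments). Conserved sites inherit the community label — reference chain
letter plus the last two digits of the reference identifier (pigment
1120 on chain A → "A20", 1402 → "A02") — and gained sites get
`<chain>new<i>`.

## Sequence conservation

The Needleman–Wunsch global aligner with affine gaps (Gotoh three-state
recursion; a gap of length $L$ costs $\mathrm{open} + (L-1)\,\mathrm{extend}$,
defaults 10/0.5, BLOSUM62 bundled) is implemented in compiled code in
this package, with a deterministic traceback (diagonal > up > left on
ties). Scores are verified against exhaustive enumeration of all gapped
alignments for short sequences. Percent identity defaults to
identities over aligned columns excluding terminal overhangs; a
`shorter_seq` mode divides by the shorter input's length instead.
Windowed identity (default 11 columns, gap columns count as mismatches)
gives the per-residue track that is mapped onto structures through the
B-factor channel and averaged over each pigment's 8 Å environment.

## HPLC quantitation

Single-wavelength chromatograms are modelled as a linear baseline plus a
sum of Gaussians, fitted by Levenberg–Marquardt (convergence at 1e-8
relative parameter change, 200 iterations). Fits that fail to converge
or that converge to non-positive amplitudes or widths are errors —
a flat trace forced to carry peaks fails loudly; a clean single peak can
fall back to trapezoidal integration. Peak areas convert to amounts by

$$M[\mu\mathrm{mol}] = \mathrm{dilution}\cdot
\frac{\mathrm{Area}[\mathrm{mOD\,min}]\cdot FR[\mathrm{ml\,min^{-1}}]}
     {\varepsilon[\mathrm{M^{-1}cm^{-1}}]\cdot l[\mathrm{cm}]},$$

with flow rate 0.5 ml/min, path 0.98 cm, and ε = 70,540 (Chl a, 665 nm),
71,110 (Chl f, 705 nm), 141,000 (β-carotene), 120,000 (echinenone),
17,900 (phylloquinone, 270 nm) M⁻¹cm⁻¹. Because PSI binds exactly two
phylloquinones, scaling all amounts so phylloquinone equals 2 gives
copies per monomer with every injection-scale factor (loading, flow,
dilution) cancelling. Chlorophyll copies can be renormalized to an
assumed total (e.g. 90) via
$\mathrm{expected}(s) = T \cdot \mathrm{copies}(s) / \sum \mathrm{copies}$.
Dilution factors outside the usual {1, 3, 5} are allowed with a warning.

**Conditioning note.** Deconvolution of two fully free $(A,\mu,\sigma)$
Gaussians is ill-conditioned when peaks merge closely: at 1.5σ
separation and 1% amplitude noise the least-squares optimum can missplit
the two areas by ~20% even though the summed area is stable. The default
channel table therefore places echinenone and β-carotene at 2.5σ
separation — resolved peaks with overlapping tails, which is how the
two carotenoids actually elute on the reversed-phase gradient — and the
merged 1.5σ case is exercised noiselessly in the tests.

## What the generators emulate — and what they do not

`build_toy_structure()` places exactly planar idealized chlorins (20
ring carbons at 1.45 Å spacing, Mg at the centroid, one substituent
carbon 1.50 Å from C2) by rigid transforms, and plants donor and axial
probe atoms at exact distances, emitting ground truth alongside. The
template is idealized rather than copied from any deposition, so
fixtures are licence-free and every geometric answer is analytic.
`simulate_chromatogram()` inverts the quantitation equation from a
chosen stoichiometry (phylloquinone fixed at 2), adds a linear baseline
and seeded Gaussian noise; the noise level is specified per channel as a
fraction of that channel's tallest peak (detectors are ranged per
wavelength), 1% by default.

Passing on these fixtures demonstrates the *operations* are exact —
planted donors recovered to 1e-9 Å, stoichiometries to 1% — not that
real structures behave so cleanly. Real depositions have thermal
disorder, missing atoms, waters invisible at 3 Å (water-mediated H-bond
networks are expected at real Chl f sites but lie beyond a water-free
scan), carbonyl-only environments, and esterifying tails the template
omits.
The synthetic monomer used in the acceptance report carries the real
complement of chlorin residues but single-atom stand-ins for
carotenoid/quinone/lipid cofactors, since only residue codes enter the
census. Simulated chromatograms omit gradient drift in retention time,
heteroscedastic detector noise and cis-isomer shoulders.

The analysis scripts (`analysis/01…07`) run the chain end to end on a
small synthetic study system: problem sizes (8 pigment sites, 24–30
residue peptides, 801-point chromatograms, 12 quantitation
determinations) were chosen so each stage's behaviour is legible in its
printed tables.

## Numerical and design choices

* Coordinates are Å throughout; residue numbering is taken verbatim from
  files (no renumbering).
* Kabsch rejects configurations whose second singular value vanishes
  (collinear input) and always returns det(R) = +1.
* The alignment traceback tie-break (diagonal > up > left) makes gapped
  strings deterministic; scores are tie-break independent.
* `percent_identity(..., "shorter_seq")` divides by the shorter
  *sequence* length, so pure terminal overhangs do not lower it; use the
  default aligned-columns mode when overhang penalties are wanted.
* Monomer selection for multi-copy files is an explicit chain list; the
  default is all chains (asymmetric units of the reference structures
  used here are single monomers).
* Degenerate inputs fail loudly by policy: zero-atom files, missing MG,
  ambiguous substituents, absent internal standard, flat traces with
  forced peaks.

## Known limitations

* No hydrogens, hence no donor-angle criterion; a donor's geometry may
  in reality point away from the formyl oxygen.
* The formyl-oxygen proxy (substituent heavy atom; linear 1.2 Å probe)
  ignores sp² bend and rotamer freedom (~0.5 Å systematic).
* Water-mediated H-bond networks are out of reach in water-free models.
* Pairwise-to-anchor alignment only; no MSA, no phylogenetics.
* Greedy site matching is optimal only when sites are well separated
  relative to the cutoff — true of photosystem pigment lattices, not of
  arbitrary point sets.
* Assignment of HPLC peaks to species is by retention window per
  wavelength channel; no spectral unmixing, no cis/trans isomer
  resolution.
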