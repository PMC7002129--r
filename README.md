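# chlfsites

Pigment-site analysis for far-red-acclimated Photosystem I structures.

## The problem

Under far-red light (700–800 nm), FaRLiP-capable cyanobacteria rebuild
Photosystem I: six subunits are swapped for paralogs and ~8% of the
chlorophyll a is replaced by chlorophyll f. Chl f differs from Chl a only
by a formyl group at the C2 position of the chlorin ring — invisible at
the ~3 Å resolution of current cryo-EM maps — so its binding sites must
be *inferred*: from hydrogen-bond donors poised 2.4–3.5 Å from the C2
substituent, from local sequence divergence of the far-red paralogs, and
from pigment sites and axial ligands that changed relative to a
white-light reference structure. This package implements that inference
chain for structural biologists working on far-red photosystems,
together with the internal-standard HPLC quantitation that counts Chl f
copies per monomer, and seeded synthetic generators so the whole
pipeline is testable offline.

## What it computes

* **Census** — PDB/mmCIF parsing and cofactor classification
  (chlorophylls a/a′/b/f, carotenoids, phylloquinone, lipids, [4Fe-4S],
  detergent) with an overrideable ligand-code table.
* **Chlorin geometry** — IUPAC macrocycle mapping; least-squares ring
  planes and interplane angles (folded to [0°, 90°]); C2-substituent
  location; stacked multimers (Mg–Mg ≤ 9 Å, connected components);
  Mg axial ligands (1.9–3.0 Å, classified); steric crowding at a
  modelled formyl-oxygen probe.
* **Chl f site scan** — donor enumeration (Ser/Thr/Tyr OH, Asn/Gln/
  Lys/Arg/His N, backbone N, water O), distance-window scan of each
  chlorophyll's C2 environment, and an additive candidate score
  `w1·hbond + w2·(1 − conservation) + w3·site_change` with the H-bond
  term 1 at ≤2.6 Å decaying to 0 at 3.5 Å.
* **Homolog comparison** — Kabsch superposition on paired Cα atoms;
  greedy nearest-Mg site correspondence (conserved/lost/gained, 2.5 Å);
  community site labels (reference chain + last two digits: pigment
  1120/chain A → "A20"); axial-ligand change tables.
* **Conservation** — in-package Needleman–Wunsch with affine gaps
  (BLOSUM62, open 10, extend 0.5), identity matrices, windowed
  per-residue identity tracks exported through the PDB B-factor channel,
  and per-pigment environment identity (8 Å).
* **Quantitation** — Gaussian peak deconvolution over a linear baseline
  and Beer–Lambert conversion
  `M[µmol] = dilution · Area[mOD·min] · FR[ml/min] / (ε[M⁻¹cm⁻¹] · l[cm])`
  with phylloquinone (exactly 2 per monomer) as internal standard, plus
  renormalization of chlorophyll copies to an assumed total.

## Worked example

Plant a tyrosine hydroxyl 2.5 Å from a chlorophyll's C2 substituent and
scan for it:

```r
library(chlfsites)
tb <- build_toy_structure(list(
  placement("B", 30, donors = list(list(
    residue_name = "TYR", atom_name = "OH",
    distance = 2.5, direction = c(1, 0.5, 1))))))
scan_c2_environment(tb$model, "B:30:")$donors
#>   residue_key residue_name atom_name              class distance strong
#> 1      Z:901:          TYR        OH SIDECHAIN_HYDROXYL      2.5   TRUE
```

The donor sits in the strong H-bonding range — exactly the signature
used to assign a Chl f site. Quantify a simulated chromatogram set at
the measured far-red stoichiometry (1% peak-amplitude noise):

```r
rep <- recover_stoichiometry(chromatogram_spec(
  stoichiometry = c(chl_a = 89.1, chl_f = 7.1, phylloquinone = 2),
  noise_frac = 0.01, seed = 7521))
rep
#> copies per monomer (phylloquinone = 2):
#>   phylloquinone  2.00
#>   chl_a          89.04
#>   chl_f          7.11
#>   chl_a_to_chl_f               12.52
renormalize_total(rep, 90)
#> chl_a chl_f
#> 83.34  6.66
```

Scaling to phylloquinone = 2 recovers ~89 Chl a and ~7.1 Chl f per
monomer; renormalizing to an assumed 90-chlorophyll total gives the
expected ~6.7 Chl f copies.

## The analysis workflow

`analysis/01…07` run the full chain on a synthetic study system (a
white-light-like reference and a far-red-like query with planted site
losses, a lost axial His, and planted donors), writing tables under
`results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

01 builds structures/sequences, 02 censuses, 03 does stacking/axial
geometry, 04 aligns paralogs and maps conservation, 05 superposes and
classifies sites, 06 ranks Chl f candidates (the planted Tyr-donor site
and remodelled sites lead), 07 simulates and quantifies chromatograms.

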