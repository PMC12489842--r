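---
title: "Methods: substrate transplantation and productive-complex validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: substrate transplantation and productive-complex validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(substrategraft)
```

## The procedure and its assumptions

NTPDases hydrolyze nucleoside tri- and diphosphates at an active site so
conserved that the substrate conformation itself is conserved: across the
solved productive complexes the nucleotide binds with the nucleoside
*anti*, the phosphate tail and nucleobase in a linear-like arrangement,
bidentate metal coordination through oxygens of two distinct phosphate
groups, near-symmetric distances from the two DXG-motif aspartates (ACR1
and ACR4) to the cofactor, and six conserved active-site waters. This
package operationalizes a simple inference: if a target NTPDase model is
in the closed, catalysis-competent state, the most reliable way to build
its substrate complex is to superpose a solved complex onto it and copy
the substrate, cofactor and conserved waters across rigidly, then verify
the result geometrically rather than energetically.

Three assumptions do the work, and all three are checkable by the
validators: (i) the target model is closed — `validate_closed_state()`
compares the overall Cα RMSD and the inter-aspartate Cγ–Cγ distance
against the template, because the ACR1/ACR4 relative position tracks the
butterfly-like interdomain motion; (ii) the active site tolerates the
canonical pose — `steric_clashes()` and the H-bond census report whether
it does; (iii) rigid transfer is meaningful, i.e. no torsional refit is
attempted (energy minimization and dynamics are explicitly out of scope
here and belong to downstream tools).

## Superposition

Residues are paired by global (Needleman–Wunsch) alignment of one-letter
sequences with BLOSUM62, gap open 10, gap extension 0.5 — the defaults of
the interactive tools structural biologists use for this task. The rigid
fit minimizes the RMSD of paired Cα atoms by the Kabsch construction: SVD
of the cross-covariance matrix with the smallest singular direction
negated when the rotation would otherwise be improper, so reflections are
excluded. Collinear point sets (second singular value below 1e-8 of the
largest) are rejected as degenerate rather than silently fit.

Outlier rejection runs for at most `cycles` rounds (default 5): after each
fit, pairs deviating more than `reject_cutoff` (default 2.0 Å) are
dropped and the fit repeated, stopping when nothing is dropped. One guard
is deliberate: at most the worst 25 % of the retained pairs are dropped
per cycle. Without the cap, a model with one displaced domain (an open
state) can place *every* pair above the cutoff on the first fit, evicting
the entire pairing at once; with it, the fit locks progressively onto the
static core, which is both more robust and what the rejection heuristic
is meant to do. Fewer than three surviving pairs is an error that reports
the last retained count.

Substrate similarity is computed in the protein-aligned frame with **no
ligand refit** — the point of the number is to measure how far the ligand
sits from the reference pose inside the site. Atom correspondence is by
canonical PDB component nomenclature: `all_common` (intersection of heavy
atoms — for purine pairs the phosphates, ribose and the nine shared ring
atoms), `phosphate_ribose`, or `nucleobase`. Which subset the benchmark
comparisons should use is genuinely open (published values do not state
it); it is therefore a parameter, with `all_common` the default, and the
analog bridging nitrogens map to each other when both ligands carry them.

## Ligand operations

*Analog conversion.* The solved complexes carry non-hydrolyzable imido
analogs; `analog_to_substrate()` performs exactly the edit the protocol
calls for — the single bridging nitrogen (N3β in triphosphates, N3α in
diphosphates) becomes the bridging oxygen, name and element updated, every
coordinate bit-identical, component code updated. Converting a
non-analog is refused rather than silently ignored, so a double
conversion cannot pass unnoticed.

*Hybrid diphosphates.* GDP and UDP have no solved productive complex;
they are assembled by fitting the GTP/UTP nucleobase onto the ADP-analog
tail and combining the fragments. Purine-onto-purine uses the nine shared
ring atoms plus C1′; pyrimidine-onto-purine uses the
glycosidic-geometry-preserving triple N1→N9, C2→C4, C6→C8 plus C1′ —
chosen because preserving the glycosidic bond geometry is the physically
meaningful constraint when the ring systems differ. Both fragments are
copied rigidly (tail coordinates exactly, base under the fitted
transform); a fit RMSD above 1.0 Å over the mapped atoms is an error
(bases too dissimilar for the stated mapping), and the resulting C1′–N
bond must land in 1.2–1.8 Å.

*Site waters.* The first hydration shell is every water oxygen within
`shell_cutoff` of the metal — default 3.2 Å, the upper bound of Ca²⁺–O
coordination chemistry; four are expected and fewer yields a result
flagged incomplete, with a warning. The catalytic water is the nearest
non-shell water on the leaving-group side of the terminal phosphorus
(positive projection onto the bridge→P axis — the in-line attack
geometry); the terminal water is the nearest remaining water within
`terminal_cutoff` (default 4.0 Å) of the terminal phosphate oxygens.
Whether the crystallographers' catalytic/terminal annotation follows
exactly this geometric rule is unknowable from coordinates alone; the
nearest-water rule is a stated approximation. Selections order by
distance rounded to 1e-6 Å with the atom serial as tie-break, making the
result invariant under record reordering.

## Validation

*Bidentate coordination* requires at least two phosphate oxygens within
the [2.0, 3.0] Å window of the metal, from two distinct phosphate groups
(bridging oxygens excluded from the groups so "distinct" is unambiguous).
*DXG motifs* are Asp-x-Gly tripeptides whose Asp Cγ lies within 6.0 Å of
the cofactor; the two nearest are reported in sequence order, and an
explicit residue-number override bypasses the search for divergent
isoforms. *Sugar pucker* follows the Altona–Sundaralingam construction:
the five endocyclic torsions ν₀..ν₄ give
tan P = ((ν₄+ν₁) − (ν₃+ν₀)) / (2ν₂(sin 36° + sin 72°)) and
τₘ = ν₂ / cos P, with C3′-endo ⇔ P ∈ [0°, 36°), C2′-endo ⇔ P ∈ [144°,
180°), anything else "other" (standard nucleic-acid windows; only the two
named classes occur in the corpus). *χ* is O4′–C1′–N9–C4 (purines) or
O4′–C1′–N1–C2 (pyrimidines), anti ⇔ |χ| ≥ 90°. The *base-plane angle* is
measured between least-squares plane normals of the ring atoms only,
folded into [0°, 90°]; ring planes rather than long axes were chosen
because a plane is well-defined for both purines and pyrimidines.
*Clashes* are non-bonded pairs closer than 0.6 × the Bondi vdW-radius
sum, with intra-residue pairs, peptide-bond C–N pairs and
metal-coordination contacts excluded. *H-bonds* use the heavy-atom N/O–N/O
criterion at 3.5 Å; a donor-hydrogen-acceptor angle ≥ 120° is additionally
required only when hydrogens exist (the crystal inputs have none, and
inventing hydrogen positions for sub-Å geometry would be noise).

The classifier's decision rule mirrors the corpus: **canonical** iff
all-common RMSD ≤ 1.5 Å *and* bidentate holds; **alternative** iff
instead the phosphate + ribose RMSD is within the threshold but the base
plane is rotated more than 45°; otherwise **nonproductive**. The 1.5 Å
default sits between the largest canonical exemplar (1.22 Å) and the
alternative mode's tail-only fit (1.64 Å), i.e. it separates the corpus's
own classes; it is a parameter, not a constant. One solved UTP complex is
reported ambiguously in the literature (canonical in one entry,
alternative-like in another); the classifier deliberately reports
geometry without asserting which is biologically right.

## Structure IO conventions

One conformer per atom: highest occupancy, ties to the lexicographically
smallest altloc — the published protocol is silent and RMSD reproduction
needs determinism. Waters are recognized purely by component code
(HOH/WAT/DOD), metals as single-atom residues with a metallic element:
format-level rules, independent of any annotation tool. Only the first
model of multi-model files is read; asymmetric-unit files are assumed
(the corpus entries' binding sites are complete in the asymmetric unit,
and which form the published analysis used is not stated). Hydrogens are
kept if present but excluded from every RMSD and distance. Author residue
numbering is preserved throughout. Transplanted residues land on a
dedicated chain ("X" by default) with fresh serials to avoid collisions.

## The synthetic fixtures, and what they do not show

`make_toy_complex()` plants the conserved geometry *exactly*: two
helical Asp-x-Gly fragments with Cγ at the planned distances (defaults
4.80 / 4.84 Å), two coordinating phosphate oxygens from distinct groups
at 2.35 / 2.40 Å, four shell waters at 2.40 Å, catalytic and terminal
waters on the leaving-group side, an idealized nucleotide at the
requested pucker (default P = 162°, C2′-endo, as in the benchmark
triphosphate complex) and χ (default −120°, anti). Idealized internal
geometry (bond lengths, angles, regular-polygon bases with exact ring
closure) is embedded as code so fixture generation never touches the
network, and the same seed always produces byte-identical files.

These fixtures are geometric test vectors, not folded proteins: they have
no realistic packing, no sequence diversity beyond the planted motifs, no
crystallographic noise, no alternate conformers, and their bases are
idealized polygons rather than chemically accurate rings. Passing tests
on them demonstrates that the geometry engine measures, transfers and
classifies correctly — not that any particular real model is closed or
that a real graft is strain-free. The crystal-corpus functions
(`substrate_similarity_table()`, `dxg_distance_survey()`,
`alternative_mode_assessment()`) run the identical code paths on real
entries once a structure cache is available.

A related numerical point: the pseudorotation closed form and a
least-squares fit of the cosine model ν_j = τₘ cos(P + 144°(j−2)) are
identical only when the torsions follow that model exactly. Real (and
synthetically puckered) five-membered rings deviate anharmonically at the
~1° level, where the two estimators legitimately differ; the test suite
therefore checks estimator agreement to 0.1° on torsion-space rings and
to 2° on full 3-D rings. The amplitude calibration of the ring builder
targets τₘ ≈ 38–40°, the range observed in nucleosides.

## Problem sizes and determinism

The offline suite exercises: toy complexes of ~112 atoms (14 scaffold
residues, 27–32 ligand atoms, 6 waters, 1 ion), superposition-recovery
Monte Carlo at 60–100 seeds with σ = 0.1 Å, 1,000 torsion-space rings
plus 200 3-D rings for the pucker oracle, and 25-restart derivative-free
rotation searches on 4–6-point sets for the Kabsch oracle — sizes chosen
so the full suite completes in about a minute while every oracle has
enough cases to be meaningful. All stochastic pieces are seeded; the
pipeline records its configuration (with a hash) in every JSON report, so
identical inputs and configuration give byte-identical reports.

## Known limitations

No structure repair, symmetry expansion or assembly generation; no
protonation, force-field typing or minimization (by design — downstream
tools own those); no sequence-independent structural alignment, so
grafting between unalignable folds is out of scope; cofactor chemistry is
Ca²⁺-only, matching the corpus convention; π-stacking is not validated
beyond geometric contacts. Clash reporting has no published "failure"
threshold to compare against — complexes that would need relaxation are
reported with their clash lists, and the decision is left to the user.
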