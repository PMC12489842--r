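Package: substrategraft
Title: Template-Based Transplantation and Geometric Validation of
    NTPDase-Nucleotide Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds "productive" ecto-nucleoside triphosphate
    diphosphohydrolase (NTPDase) substrate complexes by transplanting
    crystallographic nucleotide substrates, metal cofactors and conserved
    active-site waters from experimentally solved complexes into target
    enzyme models. Provides sequence-guided rigid superposition with
    iterative outlier rejection, analog-to-substrate conversion,
    hybrid-diphosphate construction by fragment recombination, and a
    geometric validation scheme for the canonical productive binding mode:
    bidentate metal coordination, symmetric DXG-aspartate distances,
    hydration-shell census, sugar-pucker pseudorotation, glycosidic torsion
    and base-plane orientation. A synthetic-fixture generator makes the
    whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
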