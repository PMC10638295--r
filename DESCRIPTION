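Package: comfscreen
Title: In-Silico Screening for Change-of-Metabolic-Function Enzyme Mutations
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A two-generation in-silico screen that mines somatic-mutation
    catalogs (COSMIC-style exports) for candidate change-of-metabolic-function
    (COMF) enzyme mutations. Implements recurrence/fraction hotspot filters
    with an exact binomial null model for the recurrence cutoffs, annotation
    triage (enzyme status, germline exclusion, known gain-of-function
    exclusion, protein length, alignment-column conservation), classification
    of mutated residues by minimum 3-D distance to active-site or ligand atoms
    on PDB or predicted structures, a metabolomic validation screen (per-
    metabolite Welch's t-tests with Bonferroni correction, group-vs-rest and
    mutant-vs-wild-type contrasts), a gold-standard confusion-matrix
    evaluation, and seeded synthetic-data generators for every input the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
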