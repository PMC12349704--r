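Package: macromet
Title: Automated Metabolite Identification for Macromolecules from LC-HRMS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for automated metabolite identification (MetID) of
    therapeutic macromolecules (peptides and oligonucleotides) from
    liquid-chromatography high-resolution mass-spectrometry runs.
    Implements elemental-composition algebra with aggregated isotope
    patterns and both monoisotopic-mass (MiM) and most-abundant-mass
    (MaM) peak targeting; a monomer registry with dash-notation sequence
    parsing, disulfide and head-to-tail linkages and expanded
    (atom-level) or non-expanded (monomer-level) representations; a
    biotransformation rule engine that enumerates metabolite candidates
    over several generations; backbone (a/b/c/x/y/z) and all-bond
    fragmentation with hydrogen-rearrangement variants; chromatographic
    peak detection against a blank run with Hodgkin/Pearson similarity,
    negative-control area ratios, shape-correlated filtered spectra and
    isotope-similarity gating; fragment-evidence classification into
    matches, mismatches and metmatches with intensity scoring and
    candidate ranking; multi-sample consolidation, filtering, kinetic
    profiles and reporting; and a seeded synthetic LC-MS/MS run
    generator for end-to-end validation without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mzR,
    jsonlite
Config/testthat/edition: 3
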