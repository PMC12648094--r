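Package: neoscreen
Title: Neoepitope Candidate Selection and T-Cell Response Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting spontaneous anti-neoepitope CD8+ T-cell
    responses in tumor cohorts. Implements consensus selection of somatic
    missense variants from multi-caller call sets, enumeration of mutant and
    wild-type 8-11-mer peptides from 25-residue windows, prioritization of
    candidates by MHC class I binding percentile rank and tumor expression
    (TPM), IFN-gamma ELISPOT positivity calling with a 3-standard-deviation
    rule and peptide-pool deconvolution, single-cell TCR clonotype tracking
    across tissue compartments and timepoints with exact frequency tests, a
    minimum-likelihood two-sided Fisher exact test, and a fully synthetic
    cohort generator with planted ground truth so every stage can be
    exercised without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
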