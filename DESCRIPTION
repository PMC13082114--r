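Package: uorfded
Title: Quantifying uORF-Mediated Translational Control from Ribo-Seq and
    FACS-uORF Reporter Screens
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Feature-resolved analysis of upstream open reading frame (uORF)
    translation in yeast. Reads and merges transcript-space uORF annotations,
    converts P-site-assigned ribosome footprint tracks into feature-level
    counts with 5'UTR/mORF exclusion rules, computes relative translational
    efficiencies (TE) and differential TE with a negative-binomial interaction
    test, center-of-ribosome-density (CRD) shifts, metagene profiles, and
    PARS-based secondary-structure window scores. Also implements the
    statistics of FACS-sorted massively parallel reporter assays (FACS-uORF):
    bin-based reporter expression, per-replicate Wilcoxon rank-sum comparison
    of paired wild-type and start-codon-mutant reporters with
    Benjamini-Hochberg control, consistent-significant-regulator (CSR) uORF
    calling, uORF effects and cross-strain effect ratios. Ships seeded
    synthetic-data generators for every input so all stages are testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
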