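Package: serpinscope
Title: Serpin Discovery and Reactive Center Loop Annotation for Tick
    Salivary Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based identification and annotation of serine protease
    inhibitors (serpins) in tick salivary-gland transcriptomes. Provides
    six-frame open reading frame discovery, PROSITE-style signature and
    N-terminal motif screening, localisation of the reactive center loop
    (RCL) hinge, extraction of the 21-residue P17-P4' window, P1 residue
    classification under the Schechter-Berger nomenclature with target
    protease prediction, full-length versus partial classification,
    TPM/FPKM abundance metrics with zero-TPM presence-absence partitioning
    by sex, pairwise global alignment statistics, neighbor-joining trees,
    and a seeded synthetic-data generator with a ground-truth table for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
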