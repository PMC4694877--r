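Package: ffpeconcord
Title: Concordance and Artifact Analysis for Matched Fresh-Frozen and FFPE Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing DNA sequencing results between matched
    fresh-frozen (FF) and formalin-fixed paraffin-embedded (FFPE) tissue
    samples. Implements hard-filtered consensus base calling and
    threshold-based SNV/INDEL calling from per-position pileup summaries,
    matched-pair concordance classification (concordant, discordant,
    false-positive, false-negative), orthogonal genotype-array comparison,
    characterization of formalin-induced cytosine-deamination artifact
    spectra (collapsed substitution classes, CpN/NpC context C>T rates,
    global mismatch rate, Ts/Tv), coverage/MAPQ/VAF filter sweeps, germline
    subtraction with paired somatic overlap accounting and cross-sample
    recurrence filtering, and low-pass copy-number comparison (binning, GC
    correction, log2 ratios, penalized binary segmentation, region
    harmonization, clustering and correlation). A deterministic synthetic-data
    generator emulates matched FF/FFPE pairs sharing germline/somatic/CNV
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    multcomp
Config/testthat/edition: 3
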