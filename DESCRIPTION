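Package: crisprnet
Title: Convolutional Sequence Models for CRISPR sgRNA On-Target Efficacy
    and Genome-Wide Off-Target Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts CRISPR-Cas9 single-guide RNA (sgRNA) knockout
    efficacy and genome-wide off-target cleavage profiles from a unified
    eight-channel encoding of the 23-nt guide window (one-hot nucleotides
    plus CTCF, DNase, H3K4me3 and RRBS methylation tracks). Provides a
    denoising convolutional autoencoder for unsupervised pretraining, a
    fine-tuned on-target predictor with classification and regression
    heads, a two-branch pair network for off-target site prediction
    trained with bootstrap-balanced mini-batches, activation-maximization
    saliency with nucleotide-substitution effect maps and Fisher-exact
    filtering, an NGG PAM scanner with mismatch-bounded candidate
    enumeration, a per-guide anti-OT summary score with severity-banded
    profile export, and seeded synthetic-data generators so the whole
    pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
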