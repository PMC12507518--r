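Package: motifdelta
Title: Variant Effect Scoring with Mono- and Dinucleotide Transcription
    Factor Binding Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the effect of DNA sequence variants on transcription
    factor binding using mono- and dinucleotide position weight matrices.
    Sequences flanking each variant are scanned by convolution on both
    strands, raw log-odds match scores are normalized either through the
    exact score distribution of the motif under a background model
    (probability normalization via a dynamic program over discretized
    scores) or through a per-motif min-max scheme, and per-allele scores
    are pooled (best match or average occupancy) and differenced to give a
    signed binding-change score per variant and motif.  Downstream layers
    provide elastic-net fine-tuning of the variant-by-motif score matrix
    against measured allelic effects, and per-motif gain/loss summaries
    (empirical probability of positive shift, Wilcoxon shift test,
    Benjamini-Hochberg FDR) for evolutionary variant sets.  Includes a
    deterministic simulator for genomes, motifs, planted binding sites,
    variants and effect labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
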