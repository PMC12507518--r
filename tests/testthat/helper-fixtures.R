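# Shared fixture builders (used by the variant, finetune and acceptance tests).

# Spaced SNVs (no two windows overlap) so allele-swapped scoring against the
# alt-substituted genome is a clean antisymmetry check.
make_spaced_snvs <- function(genome, n, spacing, seed = 1) {
  chars <- strsplit(as.character(genome[[1]]), "")[[1]]
  withr::with_seed(seed, {
    pos <- seq(spacing, by = spacing, length.out = n)
    ref <- chars[pos]
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), "")
  })
  tibble::tibble(chrom = names(genome)[1], pos = pos, ref = ref, alt = alt)
}

substitute_alleles <- function(genome, variants) {
  contig <- Biostrings::replaceAt(
    genome[[1]],
    IRanges::IRanges(variants$pos, variants$pos + nchar(variants$ref) - 1L),
    variants$alt
  )
  out <- Biostrings::DNAStringSet(list(contig))
  names(out) <- names(genome)[1]
  out
}

# Synthetic regression fixture: diff-like tibble of iid N(0,1) features.
make_feature_tbl <- function(n, p, seed) {
  x <- withr::with_seed(seed, matrix(rnorm(n * p), n, p))
  colnames(x) <- sprintf("M%03d", seq_len(p))
  dplyr::bind_cols(tibble::tibble(variant_id = sprintf("v%05d", seq_len(n))),
                   tibble::as_tibble(x))
}
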