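test_that("SNV windows have length 2*span-1 and indel windows differ by the allele gap", {
  genome <- simulate_genome(2000, seed = 5)
  chars <- strsplit(as.character(genome[[1]]), "")[[1]]
  w <- extract_windows("chr1", 500, chars[500], "A", genome, motif_span = 5)
  expect_equal(nchar(w$ref_window), 9L)
  expect_equal(nchar(w$alt_window), 9L)
  # 2-bp deletion: REF spans two bases, ALT removes them
  ref2 <- paste(chars[700:701], collapse = "")
  d <- extract_windows("chr1", 700, ref2, "", genome, motif_span = 5)
  expect_equal(nchar(d$ref_window), 10L)
  expect_equal(nchar(d$alt_window), 8L)
  expect_equal(substr(d$ref_window, 1, 4), substr(d$alt_window, 1, 4))
  expect_equal(substr(d$ref_window, 7, 10), substr(d$alt_window, 5, 8))
  # string surgery against the raw genome
  expect_equal(d$ref_window, paste(chars[696:705], collapse = ""))
  expect_equal(d$alt_window, paste(chars[c(696:699, 702:705)], collapse = ""))
})

test_that("windows with extra flank contain the motif-length windows centrally", {
  genome <- simulate_genome(2000, seed = 6)
  chars <- strsplit(as.character(genome[[1]]), "")[[1]]
  w0 <- extract_windows("chr1", 800, chars[800], "C", genome, motif_span = 6)
  w3 <- extract_windows("chr1", 800, chars[800], "C", genome, motif_span = 6,
                        extra_flank = 3)
  expect_equal(nchar(w3$ref_window), nchar(w0$ref_window) + 6L)
  expect_equal(substr(w3$ref_window, 4, 3 + nchar(w0$ref_window)), w0$ref_window)
  expect_equal(substr(w3$alt_window, 4, 3 + nchar(w0$alt_window)), w0$alt_window)
})

test_that("REF mismatches and boundary windows are handled per contract", {
  genome <- simulate_genome(1500, seed = 7)
  chars <- strsplit(as.character(genome[[1]]), "")[[1]]
  wrong <- setdiff(BASES, chars[400])[1]
  expect_error(extract_windows("chr1", 400, wrong, "A", genome, 5),
               "REF mismatch.*chr1:400")
  expect_warning(w <- extract_windows("chr1", 2, chars[2], "A", genome, 5),
                 "truncated")
  expect_equal(nchar(w$ref_window), 6L)  # only one base left of the variant
  motifs <- make_test_motifs(2, seed = 8)
  bad <- tibble::tibble(chrom = "chr1", pos = 400, ref = wrong, alt = "A")
  expect_error(score_variants(bad, genome, motifs), "REF allele mismatch")
})

test_that("ref == alt gives an exactly zero row; allele swap negates every entry", {
  genome <- simulate_genome(5000, seed = 15)
  motifs <- make_test_motifs(4, lengths = c(5, 8), seed = 16)
  vars <- make_spaced_snvs(genome, 12, 100, seed = 17)
  same <- vars
  same$alt <- same$ref
  d0 <- score_variants(same, genome, motifs)
  expect_true(all(as.matrix(d0[, -1]) == 0))

  for (mode in c("probnorm", "fabian", "none")) {
    d <- score_variants(vars, genome, motifs, mode = mode, pooling = "max")
    swapped <- vars[, c("chrom", "pos")]
    swapped$ref <- vars$alt
    swapped$alt <- vars$ref
    d_swap <- score_variants(swapped, substitute_alleles(genome, vars), motifs,
                             mode = mode, pooling = "max")
    expect_equal(as.matrix(d_swap[, -1]), -as.matrix(d[, -1]))
  }
})

test_that("the vectorized SNV path agrees with the per-variant path", {
  genome <- simulate_genome(4000, seed = 25)
  motifs <- make_test_motifs(3, lengths = c(5, 7), seed = 26)
  vars <- make_spaced_snvs(genome, 10, 150, seed = 27)
  fast <- score_variants(vars, genome, motifs)
  slow <- vapply(seq_len(nrow(vars)), function(i) {
    vapply(seq_len(nrow(motifs)), function(m) {
      w <- extract_windows(vars$chrom[i], vars$pos[i], vars$ref[i], vars$alt[i],
                           genome, motifs$span[m])
      d <- motifs$dist[[m]]
      pa <- pool_scores(normalize_scores(
        unlist(scan_raw(w$alt_window, d$qweights)), "probnorm", dist = d), "max")
      pr <- pool_scores(normalize_scores(
        unlist(scan_raw(w$ref_window, d$qweights)), "probnorm", dist = d), "max")
      pa - pr
    }, numeric(1))
  }, numeric(nrow(motifs)))
  expect_equal(unname(as.matrix(fast[, -1])), t(slow))
})

test_that("variants in ambiguous sequence give missing rows, not errors", {
  seqs <- Biostrings::DNAStringSet(paste0(strrep("N", 60), random_dna(200, seed = 31)))
  names(seqs) <- "chr1"
  motifs <- make_test_motifs(2, seed = 32)
  vars <- tibble::tibble(chrom = "chr1", pos = 30L, ref = "N", alt = "A")
  d <- score_variants(vars, seqs, motifs)
  expect_true(all(is.na(as.matrix(d[, -1]))))
})

test_that("dinucleotide motifs are scored through the same pipeline", {
  genome <- simulate_genome(3000, seed = 35)
  motifs <- make_test_motifs(2, lengths = 4, alphabet = "di", seed = 36)
  vars <- make_spaced_snvs(genome, 8, 120, seed = 37)
  d <- score_variants(vars, genome, motifs)
  expect_equal(dim(d), c(8L, 3L))
  expect_true(all(is.finite(as.matrix(d[, -1]))))
  # allele swap antisymmetry holds for di models too
  swapped <- vars[, c("chrom", "pos")]
  swapped$ref <- vars$alt
  swapped$alt <- vars$ref
  d_swap <- score_variants(swapped, substitute_alleles(genome, vars), motifs)
  expect_equal(as.matrix(d_swap[, -1]), -as.matrix(d[, -1]))
})

test_that("multi-allelic VCF records are split and ids follow the convention", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\trs1\tA\tG\t.\t.\t.",
    "chr1\t200\t.\tC\tA,T\t.\t.\t."
  ), path)
  v <- read_vcf_variants(path)
  expect_equal(nrow(v), 3L)
  expect_equal(v$id, c("rs1", "chr1_200_C_A", "chr1_200_C_T"))
  expect_equal(v$alt, c("G", "A", "T"))
})

test_that("Diff matrix TSV round trip preserves values, NAs and metadata", {
  genome <- simulate_genome(3000, seed = 45)
  motifs <- make_test_motifs(3, seed = 46)
  vars <- make_spaced_snvs(genome, 5, 120, seed = 47)
  d <- score_variants(vars, genome, motifs)
  d[[2]][2] <- NA_real_
  path <- withr::local_tempfile(fileext = ".tsv")
  write_diff_matrix(d, path)
  lines <- readLines(path)
  expect_true(all(startsWith(lines[1:7], "#")))
  expect_match(lines[1], "motifdelta")
  back <- read_diff_matrix(path)
  expect_equal(as.data.frame(back), as.data.frame(d))
  expect_equal(attr(back, "mode"), "probnorm")
  expect_equal(attr(back, "pooling"), "max")
})
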