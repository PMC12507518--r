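# Deterministic simulators for genomes, motifs, planted binding sites,
# variants and effect labels.  Everything is seeded explicitly so fixture
# generation is reproducible byte-for-byte; nothing external is required.

#' Simulate a random genome
#'
#' Draws i.i.d. nucleotides at the requested GC content and returns a
#' single-contig (or multi-contig) `DNAStringSet`.
#'
#' @param length Contig length in bp (>= 1000).
#' @param gc GC content in `[0, 1]`.
#' @param seed Integer seed; the result is fully deterministic given it.
#' @param n_contigs Number of contigs (`chr1`, `chr2`, ...), each of
#'   `length` bp.
#' @return A named `DNAStringSet`.
#' @export
simulate_genome <- function(length = 10000L, gc = 0.5, seed = 1L, n_contigs = 1L) {
  stopifnot(length >= 1000L, gc >= 0, gc <= 1)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n_contigs), function(i) {
      paste(sample(MONO_ALPHABET, length, replace = TRUE, prob = probs), collapse = "")
    }, character(1L))
  })
  gs <- Biostrings::DNAStringSet(seqs)
  names(gs) <- paste0("chr", seq_len(n_contigs))
  gs
}

#' Write a genome to FASTA (with index when available)
#'
#' @param genome A `DNAStringSet`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.  A `.fai` index is created alongside when the
#'   Rsamtools package is installed.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  if (requireNamespace("Rsamtools", quietly = TRUE)) {
    Rsamtools::indexFa(path)
  }
  invisible(path)
}

# Entropy (bits) of the mixture column w * e_consensus + (1 - w) * uniform.
mixture_entropy <- function(w, a) {
  p <- rep((1 - w) / a, a)
  p[1L] <- p[1L] + w
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Simulate a motif probability matrix
#'
#' Builds a random PSPM whose per-position information content is tuned
#' toward a target: each column is a mixture of a random consensus symbol
#' and a jittered uniform distribution, with the mixture weight solved so
#' the column entropy matches `2 - ic` bits (mono) or `4 - ic` bits (di)
#' before jitter.  `ic` at its maximum gives near-deterministic columns;
#' `ic = 0` gives near-uniform columns.
#'
#' @param length Number of matrix positions, in `[4, 20]` for mono (di
#'   matrices may be shorter).
#' @param ic Per-position information content target in bits.
#' @param alphabet `"mono"` or `"di"`.
#' @param seed Optional integer seed (omit to use the current RNG stream).
#' @return A probability matrix (rows sum to 1, symbol column names).
#' @export
simulate_motif <- function(length = 8L, ic = 1.0, alphabet = c("mono", "di"),
                           seed = NULL) {
  alphabet <- match.arg(alphabet)
  a <- if (alphabet == "mono") 4L else 16L
  if (alphabet == "mono") stopifnot(length >= 4L, length <= 20L)
  max_ic <- log2(a)
  ic <- min(max(ic, 0), max_ic - 1e-3)
  gen <- function() {
    w <- if (ic <= 1e-9) 0 else {
      uniroot(function(w) mixture_entropy(w, a) - (max_ic - ic),
              interval = c(0, 1 - 1e-9), tol = 1e-10)$root
    }
    rows <- t(vapply(seq_len(length), function(j) {
      cons <- sample.int(a, 1L)
      jitter <- runif(a, 0.7, 1.3)
      off <- (1 - w) * jitter / sum(jitter)
      col <- off
      col[cons] <- col[cons] + w
      col / sum(col)
    }, numeric(a)))
    colnames(rows) <- alphabet_symbols(alphabet)
    rows
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a collection of motifs
#'
#' @param n Number of motifs.
#' @param lengths Motif positions, recycled over motifs.
#' @param ic Information-content target, see [simulate_motif()].
#' @param alphabet `"mono"` or `"di"`.
#' @param seed Integer seed.
#' @return A motif tibble with the same schema as [read_motifs()].
#' @export
simulate_motifs <- function(n = 10L, lengths = 8L, ic = 1.0,
                            alphabet = c("mono", "di"), seed = 1L) {
  alphabet <- match.arg(alphabet)
  lengths <- rep_len(lengths, n)
  pspms <- withr::with_seed(seed, {
    lapply(seq_len(n), function(i) simulate_motif(lengths[i], ic, alphabet))
  })
  tibble(
    name = sprintf("SIM%02d", seq_len(n)),
    alphabet = alphabet,
    positions = vapply(pspms, nrow, integer(1L)),
    span = vapply(pspms, motif_span, integer(1L)),
    pspm = pspms
  )
}

# Score of a single full-span placement (integer-coded), used to pick the
# most damaging substitution when planting disruptive variants.
placement_score <- function(codes, weights) {
  if (ncol(weights) == 16L) codes <- encode_di_int(codes)
  sum(weights[cbind(seq_len(nrow(weights)), codes)])
}

worst_alt_base <- function(weights, site_codes, pos) {
  ref <- site_codes[pos]
  cand <- setdiff(seq_len(4L), ref)
  scores <- vapply(cand, function(b) {
    x <- site_codes
    x[pos] <- b
    placement_score(x, weights)
  }, numeric(1L))
  MONO_ALPHABET[cand[which.min(scores)]]
}

#' Plant consensus binding sites and generate variants
#'
#' Writes each motif's consensus sequence into the genome at random
#' non-overlapping positions, then emits SNVs of two classes: *disrupting*
#' variants that change one consensus base of a planted site to the most
#' damaging alternative for that motif (expected Diff sign negative for the
#' target motif), and *neutral* background SNVs placed away from every
#' planted site.  The returned truth table records each variant's class,
#' target motif and expected sign.
#'
#' @param genome A `DNAStringSet` (first contig is used).
#' @param motifs A motif tibble ([read_motifs()] / [simulate_motifs()]);
#'   log-odds weights are computed internally for the damage choice.
#' @param sites_per_motif Planted sites (and disrupting SNVs) per motif.
#' @param n_background Neutral background SNVs.
#' @param seed Integer seed.
#' @param margin Minimum distance kept between planted sites, and between
#'   background SNVs and any site.
#' @return A list: `genome` (edited `DNAStringSet`), `variants` (tibble
#'   `chrom`, `pos`, `id`, `ref`, `alt`), `truth` (tibble `id`, `class`,
#'   `target_motif`, `expected_sign`).
#' @export
plant_sites_and_variants <- function(genome, motifs, sites_per_motif = 5L,
                                     n_background = 100L, seed = 1L,
                                     margin = NULL) {
  contig_name <- names(genome)[1L]
  contig <- genome[[contig_name]]
  glen <- length(contig)
  spans <- motifs$span
  margin <- margin %||% (max(spans) + 2L)
  pwms <- lapply(motifs$pspm, to_pwm)

  withr::with_seed(seed, {
    # non-overlapping site placement by rejection sampling
    placed <- integer(0L)  # interval starts
    placed_end <- integer(0L)
    site_tbl <- list()
    for (m in seq_len(nrow(motifs))) {
      span <- spans[m]
      for (s in seq_len(sites_per_motif)) {
        ok <- FALSE
        for (try in seq_len(2000L)) {
          st <- sample.int(glen - span - 2L * margin, 1L) + margin
          en <- st + span - 1L
          if (all(en < placed - margin | st > placed_end + margin)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) abort("genome too small for the requested number of planted sites")
        placed <- c(placed, st)
        placed_end <- c(placed_end, en)
        site_tbl[[length(site_tbl) + 1L]] <- list(motif = m, start = st, end = en)
      }
    }
    consensus <- vapply(pwms, motif_consensus, character(1L))
    contig <- Biostrings::replaceAt(
      contig,
      IRanges::IRanges(vapply(site_tbl, `[[`, numeric(1L), "start"),
                       vapply(site_tbl, `[[`, numeric(1L), "end")),
      consensus[vapply(site_tbl, `[[`, numeric(1L), "motif")]
    )

    # disrupting SNVs: one per planted site
    vrows <- list()
    trows <- list()
    for (k in seq_along(site_tbl)) {
      st <- site_tbl[[k]]
      span <- spans[st$motif]
      site_codes <- encode_dna_int(consensus[st$motif])
      p_in <- sample.int(span, 1L)
      ref <- MONO_ALPHABET[site_codes[p_in]]
      alt <- worst_alt_base(pwms[[st$motif]], site_codes, p_in)
      id <- sprintf("disrupt_%03d", k)
      vrows[[length(vrows) + 1L]] <- tibble(
        chrom = contig_name, pos = st$start + p_in - 1L, id = id,
        ref = ref, alt = alt)
      trows[[length(trows) + 1L]] <- tibble(
        id = id, class = "disrupting", target_motif = motifs$name[st$motif],
        expected_sign = -1L)
    }

    # neutral background SNVs away from every planted site
    contig_chars <- strsplit(as.character(contig), "", fixed = TRUE)[[1L]]
    forbidden <- unlist(lapply(site_tbl, function(st) {
      (st$start - margin):(st$end + margin)
    }))
    pool <- setdiff(seq.int(margin + 1L, glen - margin), forbidden)
    bg_pos <- sample(pool, n_background)
    for (k in seq_len(n_background)) {
      pos <- bg_pos[k]
      ref <- contig_chars[pos]
      alt <- sample(setdiff(MONO_ALPHABET, ref), 1L)
      id <- sprintf("background_%04d", k)
      vrows[[length(vrows) + 1L]] <- tibble(
        chrom = contig_name, pos = pos, id = id, ref = ref, alt = alt)
      trows[[length(trows) + 1L]] <- tibble(
        id = id, class = "background", target_motif = NA_character_,
        expected_sign = 0L)
    }
  })

  edited <- Biostrings::DNAStringSet(setNames(list(contig), contig_name))
  list(
    genome = edited,
    variants = dplyr::bind_rows(vrows),
    truth = dplyr::bind_rows(trows)
  )
}

#' Write variants as a minimal VCF
#'
#' @param variants A tibble with `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param path Output path.
#' @param genome Optional `DNAStringSet` used to emit `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=motifdelta-%s", packageVersion("motifdelta")))
  if (!is.null(genome)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(genome),
                          Biostrings::width(genome)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                  variants$chrom, variants$pos,
                  variants$id %||% ".", variants$ref, variants$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate a complete variant-scoring study
#'
#' Convenience wrapper chaining [simulate_genome()], [simulate_motifs()] and
#' [plant_sites_and_variants()], returning prepared motifs ready for
#' [score_variants()].
#'
#' @param seed Integer seed driving every step.
#' @param genome_length,gc Genome parameters.
#' @param n_motifs,motif_length,ic,alphabet Motif parameters.
#' @param sites_per_motif,n_background Variant parameters.
#' @param mode_prep If `TRUE` (default) the returned motif tibble includes
#'   log-odds weights and score distributions via [motif_pwm()].
#' @param granularity Passed to [motif_pwm()].
#' @return A list: `genome`, `motifs`, `variants`, `truth`.
#' @export
simulate_variant_set <- function(seed = 1L, genome_length = 20000L, gc = 0.5,
                                 n_motifs = 10L, motif_length = 8L, ic = 1.2,
                                 alphabet = "mono", sites_per_motif = 5L,
                                 n_background = 100L, mode_prep = TRUE,
                                 granularity = 0.001) {
  genome <- simulate_genome(genome_length, gc = gc, seed = seed)
  motifs <- simulate_motifs(n_motifs, lengths = motif_length, ic = ic,
                            alphabet = alphabet, seed = seed + 1L)
  planted <- plant_sites_and_variants(genome, motifs,
                                      sites_per_motif = sites_per_motif,
                                      n_background = n_background,
                                      seed = seed + 2L)
  if (mode_prep) motifs <- motif_pwm(motifs, granularity = granularity)
  list(genome = planted$genome, motifs = motifs,
       variants = planted$variants, truth = planted$truth)
}

#' Simulate effect labels from a Diff matrix
#'
#' Builds a synthetic variant-effect label table as a linear model over the
#' Diff features plus Gaussian noise: `effect = Diff %*% weights +
#' N(0, noise_sd)`.  Missing Diff entries contribute 0.
#'
#' @param diff A `motif_diff` tibble.
#' @param weights Numeric vector, one weight per motif column.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return A tibble with `id` and `effect`, joinable by
#'   [fit_effect_model()].
#' @export
simulate_labels <- function(diff, weights, noise_sd = 1, seed = 1L) {
  x <- diff_feature_matrix(diff)
  if (length(weights) != ncol(x)) {
    abort(sprintf("weights has length %d but the Diff matrix has %d motif columns",
                  length(weights), ncol(x)))
  }
  x[is.na(x)] <- 0
  eff <- withr::with_seed(seed, {
    as.numeric(x %*% weights) + rnorm(nrow(x), sd = noise_sd)
  })
  tibble(id = diff$variant_id, effect = eff)
}
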