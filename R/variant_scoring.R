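load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    gs <- genome
  } else if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    gs <- Biostrings::readDNAStringSet(genome)
  } else {
    abort("genome must be a DNAStringSet or a path to a FASTA file")
  }
  # FASTA headers may carry descriptions; contig names are the first token
  names(gs) <- sub("\\s.*$", "", names(gs))
  gs
}

#' Read variants from a VCF file
#'
#' Reads the fixed columns of a (plain or bgzipped) VCF into a tibble,
#' splitting multi-allelic records into one bi-allelic variant per ALT
#' allele.  Missing IDs (`.`) are replaced by the `chrom_pos_ref_alt`
#' convention used throughout the package.
#'
#' @param path Path to a VCF file.
#' @return A tibble with columns `chrom`, `pos` (1-based), `id`, `ref`,
#'   `alt`.
#' @export
read_vcf_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  out <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    id = fix$ID,
    ref = toupper(fix$REF),
    alt = toupper(fix$ALT)
  )
  out <- tidyr::separate_rows(out, "alt", sep = ",")
  out$id <- variant_ids(out)
  out
}

variant_ids <- function(variants) {
  id <- if ("id" %in% names(variants)) variants$id else rep(NA_character_, nrow(variants))
  fallback <- paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = "_")
  ifelse(is.na(id) | id == "." | id == "", fallback, id)
}

#' Extract REF and ALT sequence windows around a variant
#'
#' Builds the pair of sequences scanned for one variant: the window spans
#' `pos - (span - 1) - extra_flank` to `pos + nchar(ref) - 1 + (span - 1) +
#' extra_flank` (1-based inclusive), so every motif placement that overlaps
#' the variant is represented; the ALT window substitutes the ALT allele for
#' the REF allele and is otherwise identical.  For SNVs both windows have
#' length `2 * span - 1 + 2 * extra_flank`.  Windows running off the contig
#' are truncated with a warning.  The REF allele is validated against the
#' genome.
#'
#' @param chrom,pos,ref,alt One variant (VCF conventions, `pos` 1-based).
#' @param genome A `DNAStringSet` or FASTA path.
#' @param motif_span Motif span in nucleotides (matrix rows for mono,
#'   rows + 1 for di).
#' @param extra_flank Additional symmetric flank in nucleotides (default 0:
#'   windows are motif-length based, so positions not overlapping the
#'   variant contribute nothing).
#' @return A list with `ref_window` and `alt_window` character strings.
#' @export
extract_windows <- function(chrom, pos, ref, alt, genome, motif_span,
                            extra_flank = 0L) {
  stopifnot(extra_flank >= 0L, motif_span >= 1L)
  gs <- load_genome(genome)
  if (!chrom %in% names(gs)) abort(sprintf("contig '%s' not in genome", chrom))
  contig <- gs[[chrom]]
  clen <- length(contig)
  ref <- toupper(ref); alt <- toupper(alt)
  if (pos < 1L || pos + nchar(ref) - 1L > clen) {
    abort(sprintf("variant %s:%d ref '%s' outside contig bounds", chrom, pos, ref))
  }
  obs <- toupper(as.character(Biostrings::subseq(contig, pos, pos + nchar(ref) - 1L)))
  if (obs != ref) {
    abort(sprintf("REF mismatch for variant %s:%d: VCF says '%s', genome has '%s'",
                  chrom, pos, ref, obs))
  }
  flank <- motif_span - 1L + extra_flank
  start <- pos - flank
  end <- pos + nchar(ref) - 1L + flank
  if (start < 1L || end > clen) {
    warn(sprintf("window for %s:%d truncated at contig boundary", chrom, pos))
    start <- max(1L, start)
    end <- min(clen, end)
  }
  win <- toupper(as.character(Biostrings::subseq(contig, start, end)))
  off <- pos - start  # 0-based offset of the allele within the window
  list(
    ref_window = win,
    alt_window = paste0(substr(win, 1L, off), alt,
                        substr(win, off + nchar(ref) + 1L, nchar(win)))
  )
}

#' Score variants against a motif set: the Diff matrix
#'
#' For every variant and motif, extracts the REF and ALT windows, runs the
#' scan-normalize-pool pipeline on each, and reports
#' `Diff = pooled(ALT) - pooled(REF)`.  Positive values are constructive
#' (the variant increases the best match / average occupancy), negative
#' values destructive.  SNVs of equal window geometry are scored in a
#' vectorized batch; indels and boundary-truncated variants fall back to a
#' per-variant path with the identical pipeline.
#'
#' @param variants A tibble with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `id`, or a path to a VCF file (read with
#'   [read_vcf_variants()]).
#' @param genome A `DNAStringSet` or FASTA path; REF alleles are validated
#'   against it.
#' @param motifs A prepared motif tibble from [motif_pwm()] (with score
#'   distributions when `mode = "probnorm"`).
#' @param mode Normalization mode, see [normalize_scores()].
#' @param pooling `"max"` or `"avg"`; average pooling of unnormalized
#'   scores is rejected.
#' @param extra_flank Extra window flank in nucleotides (default 0).
#' @param both_strands Scan both strands (default `TRUE`).
#' @return A `motif_diff` tibble: `variant_id` plus one numeric column per
#'   motif; run metadata is attached as attributes and echoed by
#'   [write_diff_matrix()].  Unscoreable variants (e.g. all-ambiguous
#'   windows) get `NA` entries.
#' @examples
#' sim <- simulate_variant_set(seed = 1, n_motifs = 2, n_background = 5,
#'                             sites_per_motif = 2)
#' score_variants(sim$variants, sim$genome, sim$motifs)
#' @export
score_variants <- function(variants, genome, motifs,
                           mode = c("probnorm", "fabian", "none"),
                           pooling = c("max", "avg"),
                           extra_flank = 0L, both_strands = TRUE) {
  mode <- match.arg(mode)
  pooling <- match.arg(pooling)
  check_mode_pooling(mode, pooling)
  if (mode == "probnorm" && is.null(motifs$dist)) {
    abort("motifs were prepared without score distributions; rerun motif_pwm()")
  }
  if (is.character(variants)) variants <- read_vcf_variants(variants)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  variants$ref <- toupper(variants$ref)
  variants$alt <- toupper(variants$alt)
  ids <- variant_ids(variants)
  gs <- load_genome(genome)

  nv <- nrow(variants)
  nm <- nrow(motifs)
  res <- matrix(NA_real_, nrow = nv, ncol = nm, dimnames = list(NULL, motifs$name))

  validate_refs(variants, gs)

  span_max <- max(motifs$span) + extra_flank
  halfw <- span_max - 1L
  clen <- setNames(Biostrings::width(gs), names(gs))[variants$chrom]
  is_snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
  in_bounds <- variants$pos - halfw >= 1L & variants$pos + halfw <= clen
  fast <- which(is_snv & in_bounds)
  slow <- setdiff(seq_len(nv), fast)

  if (length(fast) > 0L) {
    for (ch in unique(variants$chrom[fast])) {
      sel <- fast[variants$chrom[fast] == ch]
      res[sel, ] <- score_snv_batch(variants[sel, , drop = FALSE], gs[[ch]],
                                    motifs, mode, pooling, halfw, both_strands)
    }
  }
  for (i in slow) {
    for (m in seq_len(nm)) {
      wins <- extract_windows(variants$chrom[i], variants$pos[i],
                              variants$ref[i], variants$alt[i], gs,
                              motif_span = motifs$span[[m]],
                              extra_flank = extra_flank)
      d <- if (!is.null(motifs$dist)) motifs$dist[[m]] else NULL
      pr <- pooled_score_one(wins$ref_window, motifs$pwm[[m]], d, mode, pooling, both_strands)
      pa <- pooled_score_one(wins$alt_window, motifs$pwm[[m]], d, mode, pooling, both_strands)
      res[i, m] <- pa - pr
    }
  }

  out <- dplyr::bind_cols(tibble(variant_id = ids), as_tibble(res))
  attr(out, "mode") <- mode
  attr(out, "pooling") <- pooling
  attr(out, "extra_flank") <- extra_flank
  attr(out, "both_strands") <- both_strands
  attr(out, "background") <- attr(motifs, "background") %||% "uniform"
  attr(out, "granularity") <- attr(motifs, "granularity") %||% NA_real_
  class(out) <- c("motif_diff", class(out))
  out
}

validate_refs <- function(variants, gs) {
  bad <- character(0L)
  for (ch in unique(variants$chrom)) {
    if (!ch %in% names(gs)) {
      abort(sprintf("contig '%s' not present in genome", ch))
    }
    sel <- variants$chrom == ch
    ends <- variants$pos[sel] + nchar(variants$ref[sel]) - 1L
    if (any(variants$pos[sel] < 1L | ends > length(gs[[ch]]))) {
      abort(sprintf("variant positions outside contig '%s'", ch))
    }
    obs <- toupper(as.character(Biostrings::extractAt(
      gs[[ch]], IRanges::IRanges(variants$pos[sel], ends))))
    mism <- obs != variants$ref[sel]
    if (any(mism)) {
      w <- which(sel)[mism]
      bad <- c(bad, sprintf("%s:%d expected '%s' found '%s'",
                            variants$chrom[w], variants$pos[w],
                            variants$ref[w], obs[mism]))
    }
  }
  if (length(bad) > 0L) {
    abort(paste0("REF allele mismatches against the genome:\n  ",
                 paste(head(bad, 10L), collapse = "\n  "),
                 if (length(bad) > 10L) sprintf("\n  ... and %d more", length(bad) - 10L) else ""))
  }
  invisible(TRUE)
}

# Vectorized SNV path: all variants on one contig share the same maximal
# window geometry; each motif scans the central sub-window it needs.
score_snv_batch <- function(variants, contig, motifs, mode, pooling, halfw,
                            both_strands) {
  n <- nrow(variants)
  starts <- variants$pos - halfw
  wins <- as.character(Biostrings::extractAt(
    contig, IRanges::IRanges(starts, variants$pos + halfw)))
  wlen <- 2L * halfw + 1L
  codes <- matrix(match(strsplit(paste(toupper(wins), collapse = ""), "", fixed = TRUE)[[1L]],
                        MONO_ALPHABET, nomatch = 5L),
                  nrow = n, ncol = wlen, byrow = TRUE)
  center <- halfw + 1L
  alt_code <- match(variants$alt, MONO_ALPHABET, nomatch = 5L)

  out <- matrix(NA_real_, nrow = n, ncol = nrow(motifs))
  for (m in seq_len(nrow(motifs))) {
    pwm <- motifs$pwm[[m]]
    dist <- if (!is.null(motifs$dist)) motifs$dist[[m]] else NULL
    w <- if (mode == "probnorm") dist$qweights else pwm
    span <- motifs$span[[m]]
    # motif-specific window: center +/- (span - 1 + extra_flank); halfw was
    # built from the maximal span, so trim to this motif's need.
    need <- span - 1L + (halfw - (max(motifs$span) - 1L))
    cols <- (center - need):(center + need)
    ref_sub <- codes[, cols, drop = FALSE]
    alt_sub <- ref_sub
    alt_sub[, need + 1L] <- alt_code
    if (ncol(w) == 16L) {
      ref_sub <- to_di_codes(ref_sub)
      alt_sub <- to_di_codes(alt_sub)
    }
    out[, m] <- pooled_diff_batch(ref_sub, alt_sub, w, pwm, dist, mode, pooling,
                                  both_strands)
  }
  out
}

to_di_codes <- function(codes) {
  n <- ncol(codes)
  x <- codes[, -n, drop = FALSE]
  y <- codes[, -1L, drop = FALSE]
  d <- di_index(x, y)
  d[x == 5L | y == 5L] <- 17L
  d
}

pooled_diff_batch <- function(ref_sub, alt_sub, w, pwm, dist, mode, pooling,
                              both_strands) {
  scan_both <- function(sub) {
    s <- scan_int_matrix(sub, w)
    if (both_strands) s <- cbind(s, scan_int_matrix(sub, reverse_complement_motif(w)))
    s
  }
  pool_rows <- function(raw) {
    nm <- normalize_scores(raw, mode, dist = dist, pwm = pwm)
    nm[!is.finite(nm)] <- NA_real_
    if (pooling == "max") {
      p <- do.call(pmax, c(lapply(seq_len(ncol(nm)), function(k) nm[, k]),
                           list(na.rm = TRUE)))
      p[is.infinite(p)] <- NA_real_
      p
    } else {
      p <- rowMeans(nm, na.rm = TRUE)
      p[is.nan(p)] <- NA_real_
      p
    }
  }
  pool_rows(scan_both(alt_sub)) - pool_rows(scan_both(ref_sub))
}

#' Write a Diff matrix to TSV
#'
#' Serializes a [score_variants()] result as tab-separated text: `#`-prefixed
#' comment lines echo the package version and run metadata (normalization
#' mode, pooling, flank, background, granularity), then a header row of
#' motif names and one row per variant at full float precision.  Missing
#' values are written as `NA`.
#'
#' @param diff A `motif_diff` tibble.
#' @param path Output path.
#' @param extra_meta Optional named character vector of additional metadata
#'   lines.
#' @return `path`, invisibly.
#' @export
write_diff_matrix <- function(diff, path, extra_meta = NULL) {
  meta <- c(
    tool = paste0("motifdelta ", as.character(packageVersion("motifdelta"))),
    mode = attr(diff, "mode") %||% NA,
    pooling = attr(diff, "pooling") %||% NA,
    extra_flank = attr(diff, "extra_flank") %||% NA,
    both_strands = attr(diff, "both_strands") %||% NA,
    background = attr(diff, "background") %||% NA,
    granularity = attr(diff, "granularity") %||% NA,
    extra_meta
  )
  con <- file(path, "w")
  writeLines(sprintf("#%s=%s", names(meta), vapply(meta, as.character, character(1L))), con)
  close(con)
  readr::write_tsv(as_tibble(as.data.frame(diff)), path, append = TRUE,
                   col_names = TRUE, na = "NA")
  invisible(path)
}

#' Read a Diff matrix written by [write_diff_matrix()]
#'
#' @param path Path to the TSV file.
#' @return A `motif_diff` tibble with the run metadata restored as
#'   attributes.
#' @export
read_diff_matrix <- function(path) {
  lines <- readLines(path, n = 50L)
  meta_lines <- lines[startsWith(lines, "#")]
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         na = "NA", progress = FALSE)
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#", "", ml), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L && !kv[1L] %in% c("tool")) {
      val <- suppressWarnings(as.numeric(kv[2L]))
      attr(out, kv[1L]) <- if (!is.na(val)) {
        val
      } else if (kv[2L] %in% c("TRUE", "FALSE")) {
        as.logical(kv[2L])
      } else {
        kv[2L]
      }
    }
  }
  class(out) <- c("motif_diff", class(out))
  out
}
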