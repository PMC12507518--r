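#' Read motif matrices from a plain-text file
#'
#' Parses a HOCOMOCO-style motif file: each record is a header line starting
#' with `>` (the motif name is the first whitespace-delimited token after the
#' `>`), followed by one numeric row per motif position with 4 columns
#' (mononucleotide, A/C/G/T) or 16 columns (dinucleotide, AA..TT row-major).
#' Rows may hold counts or probabilities; records whose rows all sum to 1
#' (within 0.01) are taken as probabilities, anything else as counts.  Every
#' row is normalized to sum to exactly 1, so the result is a
#' position-specific probability matrix (PSPM) per motif.
#'
#' @param path Path to the motif file.
#' @param alphabet `"mono"` (4 columns per row) or `"di"` (16 columns).
#' @return A tibble with one row per motif, in file order: `name`,
#'   `alphabet`, `positions` (matrix rows), `span` (nucleotides covered),
#'   and list-column `pspm` holding the probability matrix (positions x
#'   symbols, symbol column names).
#' @seealso [motif_pwm()], [write_motifs()], [simulate_motifs()]
#' @examples
#' path <- tempfile(fileext = ".motif")
#' writeLines(c(">toy", "10 0 0 0", "0 10 0 0", "0 0 10 0"), path)
#' read_motifs(path)
#' @export
read_motifs <- function(path, alphabet = c("mono", "di")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(sprintf("motif file not found: %s", path))
  syms <- alphabet_symbols(alphabet)
  width <- length(syms)

  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warn(sprintf("motif file is empty: %s", path))
    return(empty_motif_tbl())
  }
  is_header <- startsWith(trimws(lines), ">")
  if (!is_header[1L]) {
    abort(sprintf("line %d: expected a '>' header before matrix rows", line_no[1L]))
  }
  rec <- cumsum(is_header)
  out <- vector("list", max(rec))
  for (r in seq_len(max(rec))) {
    idx <- which(rec == r)
    header <- trimws(lines[idx[1L]])
    name <- strsplit(sub("^>", "", header), "\\s+")[[1L]][1L]
    if (is.na(name) || !nzchar(name)) name <- sprintf("motif_%d", r)
    body <- idx[-1L]
    if (length(body) == 0L) {
      abort(sprintf("motif '%s' (line %d): no matrix rows", name, line_no[idx[1L]]))
    }
    rows <- lapply(body, function(i) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "[\\s,]+", perl = TRUE)[[1L]]))
      if (anyNA(vals)) {
        abort(sprintf("motif '%s' (line %d): non-numeric matrix entry", name, line_no[i]))
      }
      if (length(vals) != width) {
        abort(sprintf("motif '%s' (line %d): expected %d columns, found %d",
                      name, line_no[i], width, length(vals)))
      }
      if (any(vals < 0)) {
        abort(sprintf("motif '%s' (line %d): negative entry", name, line_no[i]))
      }
      vals
    })
    mat <- do.call(rbind, rows)
    sums <- rowSums(mat)
    if (any(sums == 0)) {
      abort(sprintf("motif '%s': all-zero matrix row", name))
    }
    # counts vs probabilities: auto-detect by row sums.
    mat <- mat / sums
    colnames(mat) <- syms
    out[[r]] <- list(name = name, pspm = mat)
  }
  tibble(
    name = vapply(out, `[[`, character(1L), "name"),
    alphabet = alphabet,
    positions = vapply(out, function(x) nrow(x$pspm), integer(1L)),
    span = vapply(out, function(x) motif_span(x$pspm), integer(1L)),
    pspm = lapply(out, `[[`, "pspm")
  )
}

empty_motif_tbl <- function() {
  tibble(name = character(), alphabet = character(), positions = integer(),
         span = integer(), pspm = list())
}

#' Write motif probability matrices to a plain-text file
#'
#' Serializes the `pspm` column of a motif tibble in the same `>`-header
#' format read by [read_motifs()]; a read/write round trip reproduces the
#' probabilities to full printed precision.
#'
#' @param motifs A motif tibble from [read_motifs()] or [simulate_motifs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(motifs))) {
    writeLines(paste0(">", motifs$name[[i]]), con)
    m <- motifs$pspm[[i]]
    writeLines(apply(m, 1L, function(r) paste(format(r, digits = 17L, trim = TRUE),
                                              collapse = "\t")), con)
  }
  invisible(path)
}

#' Background nucleotide distribution
#'
#' The zero-order background model combined with a PSPM to form log-odds
#' weights and to define the motif score distribution.  `"uniform"` gives
#' 0.25 per base; `"motif"` uses the marginal nucleotide frequencies of the
#' PSPM itself (for dinucleotide matrices, the first-base marginal averaged
#' over positions).
#'
#' @param pspm A probability matrix (positions x 4 or positions x 16).
#' @param background `"uniform"`, `"motif"`, or a numeric length-4
#'   probability vector over A,C,G,T.
#' @return A named numeric length-4 probability vector.
#' @export
motif_background <- function(pspm, background = "uniform") {
  if (is.numeric(background)) {
    if (length(background) != 4L) abort("numeric background must have length 4 (A,C,G,T)")
    if (any(background <= 0)) abort("background probabilities must be > 0")
    bg <- background / sum(background)
  } else if (identical(background, "uniform")) {
    bg <- rep(0.25, 4L)
  } else if (identical(background, "motif")) {
    if (ncol(pspm) == 4L) {
      bg <- colMeans(pspm)
    } else {
      # first-base marginal of each dinucleotide position
      first <- sapply(seq_len(4L), function(x) sum(pspm[, di_index(x, seq_len(4L)), drop = FALSE]))
      bg <- first / sum(first)
    }
    if (any(bg == 0)) {
      # keep the background strictly positive even for degenerate matrices
      bg <- (bg + 1e-6) / sum(bg + 1e-6)
    }
  } else {
    abort("background must be 'uniform', 'motif', or a length-4 numeric vector")
  }
  names(bg) <- MONO_ALPHABET
  bg
}

#' Convert a probability matrix to log-odds weights
#'
#' Each probability is mixed with a small uniform pseudocount mass and
#' divided by its background counterpart, then log-transformed (natural
#' log): `w[j,i] = log((p[j,i] * (1 - pc*A) + pc) / b[i])` where `A` is the
#' alphabet width.  For dinucleotide matrices the background counterpart of
#' symbol XY is `b[X] * b[Y]` under the zero-order background chain.  A
#' uniform PSPM with uniform background and zero pseudocount maps to the
#' all-zero matrix.
#'
#' @param pspm Probability matrix (rows sum to 1).
#' @param background As in [motif_background()].
#' @param pseudocount Uniform probability mass mixed into each row; must be
#'   positive when the PSPM contains zero probabilities (otherwise the
#'   log-odds would be -Inf).
#' @return A weight matrix of the same shape with attribute `"background"`.
#' @examples
#' p <- matrix(c(0.5, 0.25, 0.125, 0.125), nrow = 1)
#' to_pwm(p, pseudocount = 0)  # log(2), 0, log(1/2), log(1/2)
#' @export
to_pwm <- function(pspm, background = "uniform", pseudocount = 0.001) {
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  if (pseudocount == 0 && any(pspm == 0)) {
    abort("PSPM contains zero probabilities; a positive pseudocount is required")
  }
  a <- ncol(pspm)
  bg <- motif_background(pspm, background)
  bg_col <- if (a == 4L) {
    bg
  } else {
    x <- rep(seq_len(4L), each = 4L)
    y <- rep(seq_len(4L), 4L)
    bg[x] * bg[y]
  }
  p <- pspm * (1 - pseudocount * a) + pseudocount
  w <- log(sweep(p, 2L, bg_col, `/`))
  colnames(w) <- colnames(pspm)
  attr(w, "background") <- bg
  w
}

#' Reverse-complement a motif matrix
#'
#' Reverses the position order and permutes the symbol axis by the
#' complement map (A<->T, C<->G; dinucleotide XY -> comp(Y)comp(X)), so that
#' scanning the forward strand with the reverse-complemented motif equals
#' scanning the reverse strand with the original.  Applying it twice is the
#' identity.
#'
#' @param weights A motif matrix (PSPM or PWM), 4 or 16 columns.
#' @return The reverse-complemented matrix, attributes preserved.
#' @export
reverse_complement_motif <- function(weights) {
  perm <- if (ncol(weights) == 4L) COMP_PERM else if (ncol(weights) == 16L) DI_RC_PERM else
    abort("motif matrix must have 4 or 16 columns")
  out <- weights[rev(seq_len(nrow(weights))), perm, drop = FALSE]
  colnames(out) <- colnames(weights)
  for (at in setdiff(names(attributes(weights)), c("dim", "dimnames"))) {
    attr(out, at) <- attr(weights, at)
  }
  out
}

#' Consensus sequence of a motif matrix
#'
#' The per-position argmax symbol; for dinucleotide matrices the consensus
#' is built greedily by chaining best-scoring transitions from the best
#' first dinucleotide (exact for position-independent mono matrices).
#'
#' @param weights A motif matrix, 4 or 16 columns.
#' @return A character string of length equal to the motif span.
#' @export
motif_consensus <- function(weights) {
  if (ncol(weights) == 4L) {
    paste(MONO_ALPHABET[apply(weights, 1L, which.max)], collapse = "")
  } else {
    d <- nrow(weights)
    first <- which.max(weights[1L, ])
    x <- (first - 1L) %/% 4L + 1L
    y <- (first - 1L) %% 4L + 1L
    bases <- c(x, y)
    if (d > 1L) {
      for (j in 2L:d) {
        prev <- bases[length(bases)]
        nxt <- which.max(weights[j, di_index(prev, seq_len(4L))])
        bases <- c(bases, nxt)
      }
    }
    paste(MONO_ALPHABET[bases], collapse = "")
  }
}

#' Prepare motifs for scanning
#'
#' Adds to a motif tibble everything variant scoring needs: the log-odds
#' weight matrix (`pwm`), the FABIAN-style per-motif constants, and (unless
#' `distributions = FALSE`) the exact score distribution under the
#' background model used by probability normalization.  Distributions are
#' computed once per motif here and reused across all variants.
#'
#' @param motifs A motif tibble from [read_motifs()] or [simulate_motifs()].
#' @param background As in [motif_background()]; `"motif"` uses each PSPM's
#'   own marginal frequencies.
#' @param pseudocount Passed to [to_pwm()].
#' @param granularity Score discretization bin width for the distribution
#'   dynamic program.
#' @param distributions Set `FALSE` to skip the score-distribution pass
#'   (sufficient for modes `"none"` and `"fabian"`).
#' @return The input tibble with list-columns `pwm` and (optionally) `dist`,
#'   plus attribute `"background"` recording the background choice.
#' @export
motif_pwm <- function(motifs, background = "uniform", pseudocount = 0.001,
                      granularity = 0.001, distributions = TRUE) {
  stopifnot(nrow(motifs) >= 1L)
  motifs$pwm <- lapply(motifs$pspm, to_pwm, background = background,
                       pseudocount = pseudocount)
  if (distributions) {
    motifs$dist <- lapply(motifs$pwm, function(w) {
      score_distribution(w, background = attr(w, "background"),
                         granularity = granularity)
    })
  }
  attr(motifs, "background") <- if (is.numeric(background))
    paste(signif(background, 4L), collapse = ",") else background
  attr(motifs, "granularity") <- granularity
  motifs
}
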