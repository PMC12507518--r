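# Core convolution: integer-encoded sequences (rows) x weight matrix.
# `seqmat` is N x n with codes 1..4 (mono) or 1..16 (di); the sentinel code
# (5 / 17, for placements touching an ambiguous base) scores -Inf so the
# whole placement is masked.  Returns an N x (n - L + 1) score matrix.
scan_int_matrix <- function(seqmat, weights) {
  l <- nrow(weights)
  n <- ncol(seqmat)
  p <- n - l + 1L
  if (p < 1L) return(matrix(numeric(0L), nrow = nrow(seqmat), ncol = 0L))
  wx <- cbind(weights, rep(-Inf, l))
  wrows <- lapply(seq_len(l), function(j) wx[j, ])
  scores <- matrix(0, nrow = nrow(seqmat), ncol = p)
  for (k in seq_len(p)) {
    acc <- wrows[[1L]][seqmat[, k]]
    if (l > 1L) for (j in 2L:l) {
      acc <- acc + wrows[[j]][seqmat[, k + j - 1L]]
    }
    scores[, k] <- acc
  }
  scores
}

encode_for_weights <- function(seq, weights) {
  code <- encode_dna_int(seq)
  if (ncol(weights) == 16L) code <- encode_di_int(code)
  matrix(code, nrow = 1L)
}

#' Raw convolution match scores of a motif along a sequence
#'
#' Computes the log-odds match score of every motif placement on the
#' forward strand and (by scanning with the reverse-complemented motif) on
#' the reverse strand.  A placement overlapping an ambiguous base scores
#' `-Inf` and is excluded from any downstream pooling.  With a sequence
#' shorter than the motif span, empty score vectors are returned with a
#' warning.
#'
#' @param seq A single DNA sequence (character string).
#' @param pwm Log-odds weight matrix (4 or 16 columns).
#' @param both_strands Scan the reverse strand as well (default `TRUE`).
#' @return A list with numeric vectors `forward` and `reverse` (length
#'   `n - span + 1` each; `reverse` is empty when `both_strands = FALSE`).
#' @examples
#' w <- to_pwm(matrix(c(1, 0, 0, 0, 0, 1, 0, 0), 2, 4, byrow = TRUE),
#'             pseudocount = 0.01)
#' scan_raw("TTACTT", w)
#' @export
scan_raw <- function(seq, pwm, both_strands = TRUE) {
  span <- motif_span(pwm)
  if (nchar(seq) < span) {
    warn(sprintf("sequence (%d nt) shorter than motif span (%d nt); no placements",
                 nchar(seq), span))
    return(list(forward = numeric(0L), reverse = numeric(0L)))
  }
  mat <- encode_for_weights(seq, pwm)
  fwd <- scan_int_matrix(mat, pwm)[1L, ]
  rev <- if (both_strands) {
    scan_int_matrix(mat, reverse_complement_motif(pwm))[1L, ]
  } else {
    numeric(0L)
  }
  list(forward = fwd, reverse = rev)
}

check_mode_pooling <- function(mode, pooling) {
  if (mode == "none" && pooling == "avg") {
    abort(paste("average pooling of raw (unnormalized) log-odds scores has no",
                "natural interpretation; use pooling = 'max' or a normalization",
                "mode ('probnorm' or 'fabian')"))
  }
  invisible(TRUE)
}

# FABIAN-style per-motif constants: column-max shift and normalization
# factor F = sum over positions of (column min - column max) <= 0.
fabian_constants <- function(pwm) {
  cmax <- apply(pwm, 1L, max)
  cmin <- apply(pwm, 1L, min)
  list(smax = sum(cmax), f = sum(cmin - cmax))
}

#' Normalize raw motif match scores
#'
#' Maps raw log-odds match scores onto `[0, 1]`:
#' \describe{
#'   \item{`"none"`}{identity (raw log-odds are passed through).}
#'   \item{`"probnorm"`}{probability normalization: each score is replaced
#'     by the CDF of the motif's exact score distribution at that score, so
#'     the value is the probability that a background sequence matches no
#'     better.}
#'   \item{`"fabian"`}{per-motif min-max scheme: scores are shifted to the
#'     scale on which every column maximum is zero, divided by the
#'     normalization factor `F` (the summed column minima on that scale),
#'     and oriented so a perfect match maps to 1 and the worst match to 0.}
#' }
#' `-Inf` sentinels (placements overlapping ambiguous bases) are preserved
#' so pooling can exclude them.
#'
#' @param scores Numeric vector or matrix of raw match scores.
#' @param mode `"none"`, `"fabian"` or `"probnorm"`.
#' @param dist The motif's [score_distribution()] (required for
#'   `"probnorm"`).
#' @param pwm The motif's log-odds matrix (required for `"fabian"`).
#' @return Normalized scores, same shape as the input.
#' @export
normalize_scores <- function(scores, mode = c("probnorm", "fabian", "none"),
                             dist = NULL, pwm = NULL) {
  mode <- match.arg(mode)
  if (mode == "none") return(scores)
  mask <- !is.finite(scores) & !is.na(scores)
  out <- scores
  if (mode == "probnorm") {
    if (is.null(dist)) abort("mode 'probnorm' requires the motif's score distribution")
    out[] <- cdf_lookup(dist, as.numeric(scores))
  } else {
    if (is.null(pwm)) abort("mode 'fabian' requires the motif's weight matrix")
    k <- fabian_constants(pwm)
    if (k$f == 0) {
      out[] <- 1
    } else {
      out[] <- 1 - (as.numeric(scores) - k$smax) / k$f
      out[] <- pmin(pmax(as.numeric(out), 0), 1)
    }
  }
  out[mask] <- -Inf
  out
}

#' Pool per-placement scores into one value per sequence
#'
#' Reduces the (normalized) scores of all motif placements over both strands
#' to a single value: the best match (`"max"`) or the average occupancy
#' (`"avg"`).  Non-finite sentinels (masked placements) are dropped first;
#' if no finite placement remains the result is `NA`.
#'
#' @param scores Numeric vector (or list of numeric vectors, e.g. the two
#'   strands) of per-placement scores.
#' @param method `"max"` or `"avg"`.
#' @return A single numeric value.
#' @examples
#' pool_scores(c(0.2, 0.9, 0.1), "max")  # 0.9
#' pool_scores(c(0.2, 0.9, 0.1), "avg")  # 0.4
#' @export
pool_scores <- function(scores, method = c("max", "avg")) {
  method <- match.arg(method)
  x <- unlist(scores, use.names = FALSE)
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  if (method == "max") max(x) else mean(x)
}

# One pooled score for one sequence x one prepared motif row.
pooled_score_one <- function(seq, pwm, dist, mode, pooling, both_strands = TRUE) {
  w <- if (mode == "probnorm") {
    q <- dist$qweights
    colnames(q) <- colnames(pwm)
    q
  } else {
    pwm
  }
  span <- motif_span(w)
  if (nchar(seq) < span) return(NA_real_)
  mat <- encode_for_weights(seq, w)
  raw <- scan_int_matrix(mat, w)[1L, ]
  if (both_strands) {
    raw <- c(raw, scan_int_matrix(mat, reverse_complement_motif(w))[1L, ])
  }
  norm <- normalize_scores(raw, mode, dist = dist, pwm = pwm)
  pool_scores(norm, pooling)
}

#' Scan sequences with a set of motifs and pool
#'
#' Runs the full scan-normalize-pool pipeline for every (sequence, motif)
#' pair: all placements on both strands are scored by convolution,
#' normalized per `mode`, and pooled per `pooling`.
#'
#' @param seqs Character vector of DNA sequences; names (or positions) become
#'   `seq_id`.
#' @param motifs A prepared motif tibble from [motif_pwm()].
#' @param mode Normalization: `"probnorm"` (default), `"fabian"` or
#'   `"none"`.  See [normalize_scores()].
#' @param pooling `"max"` (best match) or `"avg"` (average occupancy).
#'   Average pooling of unnormalized scores is rejected.
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @return A tibble with columns `seq_id`, `motif`, `score`.
#' @export
scan_sequences <- function(seqs, motifs, mode = c("probnorm", "fabian", "none"),
                           pooling = c("max", "avg"), both_strands = TRUE) {
  mode <- match.arg(mode)
  pooling <- match.arg(pooling)
  check_mode_pooling(mode, pooling)
  if (mode == "probnorm" && is.null(motifs$dist)) {
    abort("motifs were prepared without score distributions; rerun motif_pwm()")
  }
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  grid <- tidyr::expand_grid(s = seq_along(seqs), m = seq_len(nrow(motifs)))
  grid$score <- purrr::map2_dbl(grid$s, grid$m, function(s, m) {
    pooled_score_one(seqs[[s]], motifs$pwm[[m]],
                     if (!is.null(motifs$dist)) motifs$dist[[m]] else NULL,
                     mode, pooling, both_strands)
  })
  tibble(seq_id = ids[grid$s], motif = motifs$name[grid$m], score = grid$score)
}
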