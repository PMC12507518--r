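#' Exact motif score distribution under the background model
#'
#' Computes the exact (discretized) distribution of motif match scores for a
#' random sequence drawn from the zero-order background model, by dynamic
#' programming over positions.  Weights are first discretized to integer
#' multiples of `granularity` (round-half-to-even); the per-position score
#' contributions are then convolved exactly, so the resulting probability
#' mass function equals exhaustive enumeration over all sequences of the
#' motif span under identical rounding.  The cumulative distribution of this
#' object is the probability-normalization map: a raw match score is
#' replaced by the probability that a background sequence scores at most as
#' high.
#'
#' For mononucleotide matrices the dynamic program convolves one 4-point
#' distribution per position.  For dinucleotide matrices the program state
#' is (last nucleotide, discretized score): the first nucleotide is drawn
#' from the background with score 0, each dinucleotide position then
#' transitions from state `(x, s)` to `(y, s + w[j, xy])` with probability
#' `b[y]`, and the nucleotide state is marginalized at the end.
#'
#' @param pwm Log-odds weight matrix (positions x 4 mono, or x 16 di).
#' @param background Length-4 probability vector over A,C,G,T, or
#'   `"uniform"`.
#' @param granularity Score bin width (epsilon).  Total discretization error
#'   of a match score is at most `granularity * positions / 2`.
#' @param max_bins Safety cap on the support size; a `granularity` fine
#'   enough to exceed it raises an error suggesting a coarser value.
#' @return An object of class `score_distribution`: list with `support`
#'   (ascending scores with nonzero mass), `pmf`, `cdf`, `granularity`,
#'   `qweights` (the granularity-quantized weight matrix, on whose grid the
#'   support lives), and `background`.
#' @seealso [cdf_lookup()], [normalize_scores()]
#' @examples
#' w <- matrix(c(1, 0, -1, -2), nrow = 1)
#' d <- score_distribution(w, granularity = 0.01)
#' d$pmf  # 0.25 at each of -2, -1, 0, 1
#' @export
score_distribution <- function(pwm, background = "uniform", granularity = 0.001,
                               max_bins = 5e6) {
  if (granularity <= 0) abort("granularity must be > 0")
  bg <- if (is.numeric(background)) {
    if (length(background) != 4L) abort("background must have length 4")
    background / sum(background)
  } else if (identical(background, "uniform")) {
    rep(0.25, 4L)
  } else {
    abort("background must be numeric (length 4) or 'uniform'")
  }
  a <- ncol(pwm)
  if (!a %in% c(4L, 16L)) abort("pwm must have 4 or 16 columns")
  qw <- round(pwm / granularity)  # integer-valued, round-half-to-even

  res <- if (a == 4L) dp_mono(qw, bg, max_bins) else dp_di(qw, bg, max_bins)

  keep <- res$pmf > 0
  pmf <- res$pmf[keep]
  support <- (res$lo + which(keep) - 1L) * granularity
  cdf <- cumsum(pmf)
  cdf <- cdf / cdf[length(cdf)]  # guard accumulated float error; last == 1

  structure(
    list(
      support = support, pmf = pmf, cdf = cdf,
      granularity = granularity,
      qweights = qw * granularity,
      background = bg,
      alphabet = alphabet_of_width(a),
      positions = nrow(pwm)
    ),
    class = "score_distribution"
  )
}

dp_mono <- function(qw, bg, max_bins) {
  lo <- 0
  hi <- 0
  v <- 1
  for (j in seq_len(nrow(qw))) {
    w <- qw[j, ]
    new_lo <- lo + min(w)
    new_hi <- hi + max(w)
    nl <- new_hi - new_lo + 1
    if (nl > max_bins) {
      abort(sprintf("score support would need %.0f bins; increase granularity", nl))
    }
    nv <- numeric(nl)
    for (i in seq_len(4L)) {
      idx <- (lo + w[i] - new_lo + 1):(hi + w[i] - new_lo + 1)
      nv[idx] <- nv[idx] + bg[i] * v
    }
    lo <- new_lo; hi <- new_hi; v <- nv
  }
  list(pmf = v, lo = lo)
}

dp_di <- function(qw, bg, max_bins) {
  lo <- 0
  hi <- 0
  v <- matrix(bg, nrow = 4L, ncol = 1L)  # state: last nucleotide x score
  for (j in seq_len(nrow(qw))) {
    w <- qw[j, ]
    new_lo <- lo + min(w)
    new_hi <- hi + max(w)
    nl <- new_hi - new_lo + 1
    if (4 * nl > max_bins) {
      abort(sprintf("score support would need %.0f bins; increase granularity", 4 * nl))
    }
    nv <- matrix(0, nrow = 4L, ncol = nl)
    for (x in seq_len(4L)) {
      for (y in seq_len(4L)) {
        wxy <- w[di_index(x, y)]
        idx <- (lo + wxy - new_lo + 1):(hi + wxy - new_lo + 1)
        nv[y, idx] <- nv[y, idx] + bg[y] * v[x, ]
      }
    }
    lo <- new_lo; hi <- new_hi; v <- nv
  }
  list(pmf = colSums(v), lo = lo)
}

#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf(
    "<score_distribution> %s motif, %d positions, granularity %g\n  support [%.4g, %.4g], %d bins with mass\n",
    x$alphabet, x$positions, x$granularity,
    x$support[1L], x$support[length(x$support)], length(x$support)
  ))
  invisible(x)
}

#' Cumulative probability of a motif match score
#'
#' Returns `P(S <= score)` under the motif's exact score distribution.
#' Scores falling between support points take the CDF of the largest support
#' value at or below them (a half-bin numerical tolerance absorbs float
#' round-off for scores computed on the distribution's own grid); scores
#' below the minimum support give 0 and scores at or above the maximum give
#' 1.  Vectorized over `score`.
#'
#' @param dist A [score_distribution()].
#' @param score Numeric vector of raw match scores.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
cdf_lookup <- function(dist, score) {
  stopifnot(inherits(dist, "score_distribution"))
  idx <- findInterval(score + dist$granularity * 1e-6, dist$support)
  out <- numeric(length(score))
  pos <- idx > 0L
  out[pos] <- dist$cdf[idx[pos]]
  out[is.na(score)] <- NA_real_
  out
}

#' Plot a motif score distribution
#'
#' Draws the cumulative distribution function used by probability
#' normalization, i.e. the map from raw log-odds match scores to
#' probabilities.
#'
#' @param object A [score_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.score_distribution <- function(object, ...) {
  df <- tibble(score = object$support, cdf = object$cdf)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$cdf)) +
    ggplot2::geom_step(linewidth = 0.4) +
    ggplot2::labs(
      x = "raw match score (log-odds)",
      y = "P(S ≤ s) under background",
      title = sprintf("Exact score distribution (%s, %d positions)",
                      object$alphabet, object$positions)
    ) +
    ggplot2::theme_minimal()
}
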