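#' Empirical probability of positive shift (EPPS)
#'
#' The proportion of variants whose Diff score for a motif is strictly
#' positive, among variants with a nonzero Diff: exact zeros represent
#' neither gain nor loss and are excluded from numerator and denominator.
#' Under the null hypothesis of no systematic binding change the
#' expectation is 0.5.
#'
#' @param diffs Numeric vector of Diff scores for one motif (NAs dropped).
#' @return A proportion in `[0, 1]`, or `NA` when no nonzero finite value
#'   remains.
#' @examples
#' compute_epps(c(1, -1, 2, -2))  # 0.5
#' @export
compute_epps <- function(diffs) {
  x <- diffs[!is.na(diffs)]
  x <- x[x != 0]
  if (length(x) == 0L) return(NA_real_)
  mean(x > 0)
}

#' Distribution-shift test for Diff scores
#'
#' Tests whether a motif's Diff scores are shifted away from zero.  The
#' default is a two-sided one-sample Wilcoxon signed-rank test against
#' location 0, using the normal approximation with continuity correction so
#' the same procedure applies at every sample size.  As an alternative
#' reference, `reference = "normal-sample"` runs a two-sample Wilcoxon
#' rank-sum test against a deterministic normal quantile sample with the
#' observed scale (mean 0), probing the shift relative to a matched normal
#' rather than relative to exact symmetry about 0.
#'
#' @param diffs Numeric vector of Diff scores (NAs dropped).
#' @param min_n Minimum number of observations; below it the p-value is
#'   `NA`.
#' @param reference `"zero"` (signed-rank against location 0, default) or
#'   `"normal-sample"` (rank-sum against a matched-scale normal sample).
#' @return A two-sided p-value (`1` when every value is exactly zero).
#' @export
shift_test <- function(diffs, min_n = 10L, reference = c("zero", "normal-sample")) {
  reference <- match.arg(reference)
  x <- diffs[!is.na(diffs)]
  if (length(x) < min_n) return(NA_real_)
  if (all(x == 0)) return(1)
  if (reference == "zero") {
    suppressWarnings(wilcox.test(x, mu = 0, exact = FALSE)$p.value)
  } else {
    n <- length(x)
    ref <- stats::qnorm((seq_len(n) - 0.5) / n, mean = 0, sd = stats::sd(x))
    suppressWarnings(wilcox.test(x, ref, exact = FALSE)$p.value)
  }
}

#' Benjamini-Hochberg adjustment of per-motif p-values
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`, kept as the
#' single FDR entry point for gain/loss summaries; `NA` p-values are
#' preserved.
#'
#' @param pvalues Numeric vector of raw p-values.
#' @return Adjusted p-values, never below the raw values.
#' @export
fdr_correct <- function(pvalues) {
  p.adjust(pvalues, method = "BH")
}

#' Per-motif gain/loss summary of a Diff matrix
#'
#' For every motif column: the EPPS (and its centered version, EPPS - 0.5,
#' so gains are positive), the number of non-missing variants, the
#' distribution-shift p-value and its Benjamini-Hochberg adjustment.  The
#' result is sorted by centered EPPS (strongest gains first) and is
#' plot-ready for a volcano of EPPS against `-log10(FDR p)` via
#' [autoplot.epps_result()].
#'
#' @param diff A `motif_diff` tibble from [score_variants()] or
#'   [read_diff_matrix()].
#' @param min_n Minimum variants for the shift test (p is `NA` below it).
#' @param reference Passed to [shift_test()].
#' @return A tibble of class `epps_result`: `motif`, `n`, `epps`,
#'   `epps_centered`, `p_value`, `p_adjusted`.
#' @export
summarize_gain_loss <- function(diff, min_n = 10L,
                                reference = c("zero", "normal-sample")) {
  reference <- match.arg(reference)
  motifs <- setdiff(names(diff), "variant_id")
  if (length(motifs) == 0L) abort("Diff matrix has no motif columns")
  out <- purrr::map_dfr(motifs, function(m) {
    x <- diff[[m]]
    tibble(
      motif = m,
      n = sum(!is.na(x)),
      epps = compute_epps(x),
      p_value = shift_test(x, min_n = min_n, reference = reference)
    )
  })
  out$epps_centered <- out$epps - 0.5
  out$p_adjusted <- fdr_correct(out$p_value)
  out <- out[, c("motif", "n", "epps", "epps_centered", "p_value", "p_adjusted")]
  out <- dplyr::arrange(out, dplyr::desc(.data$epps_centered))
  class(out) <- c("epps_result", class(out))
  out
}

#' Volcano plot of motif binding gains and losses
#'
#' Centered EPPS on the x-axis (positive = gains) against
#' `-log10(FDR-adjusted p)` on the y-axis, one point per motif.
#'
#' @param object An `epps_result` tibble from [summarize_gain_loss()].
#' @param alpha_line Draw a horizontal reference line at this FDR level
#'   (`NULL` to omit).
#' @param label_top Label this many motifs with the largest `|epps_centered|`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.epps_result <- function(object, alpha_line = 0.05, label_top = 10L, ...) {
  df <- as_tibble(object)
  df$neglog_fdr <- -log10(df$p_adjusted)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$epps_centered, y = .data$neglog_fdr)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "EPPS - 0.5 (positive = binding gain)",
                  y = expression(-log[10] ~ "FDR p-value"),
                  title = "Per-motif gain/loss shift") +
    ggplot2::theme_minimal()
  if (!is.null(alpha_line)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(alpha_line),
                                 linetype = "dotted", colour = "grey50")
  }
  if (label_top > 0L) {
    lab <- df[order(-abs(df$epps_centered)), ][seq_len(min(label_top, nrow(df))), ]
    p <- p + ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$motif),
                                size = 2.5, vjust = -0.6)
  }
  p
}
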