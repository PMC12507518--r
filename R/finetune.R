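diff_feature_matrix <- function(diff) {
  cols <- setdiff(names(diff), "variant_id")
  x <- as.matrix(as.data.frame(diff)[, cols, drop = FALSE])
  rownames(x) <- diff$variant_id
  x
}

#' Fit an elastic-net fine-tuning model on Diff features
#'
#' Trains an L1/L2-penalized linear regression from the variant-by-motif
#' Diff matrix to a measured variant-effect value (e.g. a signed
#' significance score such as `-log10(P) * sign(effect)`).  Variants are
#' split into training and holdout sets; the mixing parameter and penalty
#' strength are chosen by cross-validation on the training split only.
#' Features are standardized internally by glmnet; missing Diff entries are
#' imputed as 0 (no scoreable binding change) and all-missing columns are
#' dropped with a warning.  Fully deterministic given `seed`.
#'
#' @param diff A `motif_diff` tibble from [score_variants()] (or
#'   [read_diff_matrix()]).
#' @param labels A tibble with columns `id` and `effect`; joined 1:1 to the
#'   Diff matrix on `variant_id`, with unmatched ids reported.
#' @param folds Cross-validation folds within the training split.
#' @param seed Integer seed controlling the split and fold assignment.
#' @param alphas Candidate elastic-net mixing values.
#' @param holdout_frac Fraction of variants held out for evaluation.
#' @return An object of class `effect_model`; see [evaluate_model()],
#'   [tidy.effect_model()], [glance.effect_model()].
#' @export
fit_effect_model <- function(diff, labels, folds = 5L, seed = 1L,
                             alphas = c(0.1, 0.5, 0.9), holdout_frac = 0.2) {
  stopifnot(all(c("id", "effect") %in% names(labels)))
  x_all <- diff_feature_matrix(diff)
  common <- intersect(diff$variant_id, labels$id)
  n_unmatched <- nrow(labels) - length(common) + nrow(diff) - length(common)
  if (length(common) == 0L) abort("no label ids match the Diff matrix variant ids")
  if (n_unmatched > 0L) {
    message(sprintf("%d unmatched ids dropped at the Diff/label join", n_unmatched))
  }
  x <- x_all[match(common, rownames(x_all)), , drop = FALSE]
  y <- labels$effect[match(common, labels$id)]
  if (stats::sd(y) == 0) abort("effect labels are constant; nothing to fit")

  all_na <- colSums(!is.na(x)) == 0L
  if (any(all_na)) {
    warn(sprintf("%d all-missing Diff columns dropped: %s", sum(all_na),
                 paste(head(colnames(x)[all_na], 5L), collapse = ", ")))
    x <- x[, !all_na, drop = FALSE]
  }
  x[is.na(x)] <- 0

  n <- nrow(x)
  if (n < 2L * folds) abort(sprintf("need at least %d variants for %d-fold CV", 2L * folds, folds))

  withr::with_seed(seed, {
    holdout <- sample.int(n, size = max(1L, round(holdout_frac * n)))
    train <- setdiff(seq_len(n), holdout)
    foldid <- sample(rep(seq_len(folds), length.out = length(train)))
    cvs <- lapply(alphas, function(a) {
      glmnet::cv.glmnet(x[train, , drop = FALSE], y[train], alpha = a,
                        foldid = foldid, standardize = TRUE)
    })
  })
  best_cvm <- vapply(cvs, function(cv) min(cv$cvm), numeric(1L))
  k <- which.min(best_cvm)
  cv <- cvs[[k]]

  structure(
    list(
      cv = cv,
      alpha = alphas[k],
      lambda = cv$lambda.min,
      motifs = colnames(x),
      seed = seed, folds = folds,
      train_ids = common[train], holdout_ids = common[holdout],
      x_holdout = x[holdout, , drop = FALSE], y_holdout = y[holdout],
      n_train = length(train)
    ),
    class = "effect_model"
  )
}

#' @export
print.effect_model <- function(x, ...) {
  cat(sprintf(
    "<effect_model> elastic net on %d motif features\n  alpha %.2f, lambda %.4g, %d training / %d holdout variants, %d nonzero weights\n",
    length(x$motifs), x$alpha, x$lambda, x$n_train, length(x$holdout_ids),
    nrow(tidy(x))
  ))
  invisible(x)
}

#' @export
predict.effect_model <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else diff_feature_matrix(newdata)
  x <- x[, object$motifs, drop = FALSE]
  x[is.na(x)] <- 0
  as.numeric(predict(object$cv, newx = x, s = object$lambda))
}

#' Evaluate a fitted effect model on held-out variants
#'
#' Computes the Pearson correlation between predicted and measured effects
#' and the AUROC of the predictions against the sign of the measured effect
#' (binary gain/loss direction).  By default the holdout split stored in the
#' model is used; pass `diff` and `labels` to evaluate on other variants
#' (they must be disjoint from training for an honest estimate).
#'
#' @param model An [fit_effect_model()] result.
#' @param diff,labels Optional evaluation data (same contracts as in
#'   [fit_effect_model()]).
#' @return A one-row tibble: `correlation`, `auroc`, `n`, `alpha`, `lambda`,
#'   `n_nonzero`.  `auroc` is `NA` when only one sign class is present.
#' @export
evaluate_model <- function(model, diff = NULL, labels = NULL) {
  if (is.null(diff) != is.null(labels)) {
    abort("provide both 'diff' and 'labels', or neither")
  }
  if (is.null(diff)) {
    x <- model$x_holdout
    y <- model$y_holdout
  } else {
    common <- intersect(diff$variant_id, labels$id)
    if (length(common) == 0L) abort("no label ids match the Diff matrix variant ids")
    x <- diff_feature_matrix(diff)[match(common, diff$variant_id), , drop = FALSE]
    y <- labels$effect[match(common, labels$id)]
  }
  pred <- predict(model, x)
  tibble(
    correlation = if (stats::sd(pred) == 0 || stats::sd(y) == 0) NA_real_ else cor(pred, y),
    auroc = sign_auroc(pred, y),
    n = length(y),
    alpha = model$alpha,
    lambda = model$lambda,
    n_nonzero = nrow(tidy(model))
  )
}

# AUROC of a continuous prediction against the binary direction of effect.
sign_auroc <- function(pred, y) {
  lab <- y > 0
  if (length(unique(lab)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(
    response = factor(lab, levels = c(FALSE, TRUE)),
    predictor = pred, levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
  )))
}

#' @describeIn fit_effect_model Nonzero model weights as a tibble (`term`,
#'   `estimate`), sorted by absolute weight; the intercept is excluded.
#' @param x,object An `effect_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.effect_model <- function(x, ...) {
  b <- as.matrix(stats::coef(x$cv, s = x$lambda))
  out <- tibble(term = rownames(b), estimate = b[, 1L])
  out <- out[out$term != "(Intercept)" & out$estimate != 0, , drop = FALSE]
  dplyr::arrange(out, dplyr::desc(abs(.data$estimate)))
}

#' @describeIn fit_effect_model One-row model summary with holdout metrics.
#' @exportS3Method generics::glance
#' @export
glance.effect_model <- function(x, ...) {
  evaluate_model(x)
}

#' Correlation between a single motif's Diff column and measured effects
#'
#' The direct single-motif evaluation: no fitting, just the Pearson
#' correlation between one motif's Diff scores and the effect labels over
#' the joined variants.
#'
#' @param diff A `motif_diff` tibble.
#' @param labels A tibble with `id` and `effect`.
#' @param motif Motif column name.
#' @return A single correlation value.
#' @export
single_motif_correlation <- function(diff, labels, motif) {
  if (!motif %in% names(diff)) {
    abort(sprintf("motif '%s' not in the Diff matrix; available: %s",
                  motif, paste(head(setdiff(names(diff), "variant_id"), 20L),
                               collapse = ", ")))
  }
  common <- intersect(diff$variant_id, labels$id)
  if (length(common) == 0L) abort("no label ids match the Diff matrix variant ids")
  d <- diff[[motif]][match(common, diff$variant_id)]
  y <- labels$effect[match(common, labels$id)]
  ok <- !is.na(d) & !is.na(y)
  cor(d[ok], y[ok])
}

#' Plot the selected elastic-net weights
#'
#' Bar chart of the nonzero motif weights of a fitted effect model, the
#' standard view of which motifs the fine-tuned predictor relies on.
#'
#' @param object An `effect_model`.
#' @param top_n Show at most this many motifs (by absolute weight).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.effect_model <- function(object, top_n = 25L, ...) {
  df <- head(tidy(object), top_n)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "elastic-net weight", y = NULL,
                  title = "Motif features selected by fine-tuning") +
    ggplot2::theme_minimal()
}
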