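#' Root-mean-square error
#'
#' `sqrt(mean((actual - predicted)^2))`, the validation indicator used to
#' rank biomarkers (lower = the biomarker predicts the class signal better).
#'
#' @param actual,predicted Equal-length non-empty numeric vectors.
#' @return A non-negative scalar.
#' @export
rmse <- function(actual, predicted) {
  if (length(actual) == 0L || length(actual) != length(predicted)) {
    abort("`actual` and `predicted` must have equal non-zero length.")
  }
  sqrt(mean((actual - predicted)^2))
}

#' Least-squares boosting of a single biomarker
#'
#' Stage-wise gradient boosting with depth-1 regression stumps on one
#' predictor: each stage fits a stump to the current residuals and adds it,
#' shrunk by the learning rate, so the training RMSE is non-increasing in
#' the number of learners. The fit is fully deterministic given its inputs.
#'
#' @param x Numeric predictor (one biomarker's intensities).
#' @param y Numeric target (e.g. the class code).
#' @param n_learners Number of boosting stages (>= 1).
#' @param learning_rate Shrinkage in `(0, 1]`.
#' @return An object of class `lsboost` with elements `base_prediction`,
#'   `stumps` (split/left/right matrix), `learning_rate`, `train_rmse`
#'   (per-stage path).
#' @export
fit_lsboost <- function(x, y, n_learners = 100, learning_rate = 0.1) {
  if (length(x) != length(y) || length(x) < 4L) {
    abort("`x` and `y` must have equal length >= 4.")
  }
  if (anyNA(x) || anyNA(y)) abort("Boosting input must be complete (impute first).")
  if (n_learners < 1) abort("n_learners must be >= 1.")
  if (learning_rate <= 0 || learning_rate > 1) abort("learning_rate must be in (0, 1].")
  fit <- lsboost_fit_cpp(as.numeric(x), as.numeric(y),
                         as.integer(n_learners), learning_rate)
  structure(
    list(base_prediction = fit$base,
         stumps = `colnames<-`(fit$stumps, c("split", "left", "right")),
         learning_rate = learning_rate, n_learners = as.integer(n_learners),
         train_rmse = as.numeric(fit$train_rmse)),
    class = "lsboost"
  )
}

#' @export
predict.lsboost <- function(object, newdata, ...) {
  as.numeric(lsboost_predict_cpp(object$base_prediction, object$stumps,
                                 object$learning_rate, as.numeric(newdata)))
}

#' @export
print.lsboost <- function(x, ...) {
  cat(sprintf("# LSBoost stump ensemble: %d learners, rate %.2f, final training RMSE %.4g\n",
              x$n_learners, x$learning_rate, utils::tail(x$train_rmse, 1L)))
  invisible(x)
}

#' @rdname fit_lsboost
#' @param object,x An `lsboost` fit.
#' @param ... Unused.
#' @export
#' @method tidy lsboost
tidy.lsboost <- function(x, ...) {
  tibble(stage = seq_len(x$n_learners),
         split = x$stumps[, "split"], left = x$stumps[, "left"],
         right = x$stumps[, "right"], train_rmse = x$train_rmse)
}

# numeric class code used as the regression target (documented ordering)
class_code <- function(classes) {
  codes <- c(Normal = 0, OtherSubtype = 1, TNBC_no_recur = 2, TNBC_recur = 3)
  unname(codes[as.character(classes)])
}

#' Rank biomarkers by held-out LSBoost RMSE
#'
#' For each of `n_iterations` stratified 70/30 splits, every biomarker is
#' individually regressed onto the numeric class code with [fit_lsboost()]
#' on the training part and scored by [rmse()] on the held-out part.
#' Per-biomarker RMSE is averaged over iterations, min-max normalised across
#' biomarkers, and ranked ascending (low normalised RMSE = informative); the
#' full iteration-by-biomarker RMSE matrix is retained for distribution and
#' correlation displays.
#'
#' @param x A complete (imputed) [ev_intensity] table on log2 scale.
#' @param classes Factor/character of four-class labels, one per sample, in
#'   matrix column order.
#' @param k Size of the reported top set (default 10).
#' @param n_iterations Number of resampled splits (default 50).
#' @param n_learners,learning_rate Boosting hyperparameters per biomarker.
#' @param target `"ordinal"` (default; class code Normal=0, OtherSubtype=1,
#'   TNBC_no_recur=2, TNBC_recur=3) or `"one_vs_rest"` (mean RMSE over the
#'   four binary indicator targets, avoiding the arbitrary ordering).
#' @param seed Integer seed controlling all splits.
#' @return An object of class `ev_ranking`: `per_biomarker` tibble (protein,
#'   rmse, normalized_rmse, rank), `iteration_rmse` matrix
#'   (iterations x biomarkers), `n_iterations`, `k`, `target`.
#' @export
rank_biomarkers <- function(x, classes, k = 10, n_iterations = 50,
                            n_learners = 100, learning_rate = 0.1,
                            target = c("ordinal", "one_vs_rest"), seed = 1L) {
  target <- match.arg(target)
  assert_log2(x, "Biomarker ranking")
  m <- as_matrix(x)
  if (anyNA(m)) abort("Ranking needs a complete matrix; run impute_median() first.")
  if (k > nrow(m)) abort("k exceeds the number of proteins.")
  classes <- factor(as.character(classes), levels = EV_CLASSES)
  if (length(classes) != ncol(m)) abort("One class label per sample required.")
  if (nlevels(droplevels(classes)) < 2) abort("Need >= 2 classes.")

  xm <- t(m) # samples x proteins for the C++ kernel
  targets <- if (target == "ordinal") {
    list(class_code(classes))
  } else {
    lapply(levels(droplevels(classes)), function(cl) as.numeric(classes == cl))
  }

  withr::local_seed(as.integer(seed))
  iter_seeds <- sample.int(.Machine$integer.max, n_iterations)
  iter_rmse <- matrix(NA_real_, nrow = n_iterations, ncol = nrow(m),
                      dimnames = list(NULL, rownames(m)))
  for (it in seq_len(n_iterations)) {
    split <- stratified_split(classes, fraction_train = 0.7,
                              seed = iter_seeds[it], ids = rownames(xm))
    tr <- match(split$train_ids, rownames(xm))
    te <- match(split$test_ids, rownames(xm))
    per_target <- vapply(targets, function(y) {
      as.numeric(lsboost_split_rmse_cpp(xm, y, tr, te,
                                        as.integer(n_learners), learning_rate))
    }, numeric(nrow(m)))
    iter_rmse[it, ] <- rowMeans(per_target)
  }

  agg <- colMeans(iter_rmse)
  rng <- range(agg)
  norm <- if (rng[2] > rng[1]) (agg - rng[1]) / (rng[2] - rng[1]) else rep(0, length(agg))
  ord <- order(norm, names(agg)) # ties broken lexicographically by protein id
  per <- tibble(
    protein = names(agg)[ord],
    rmse = unname(agg[ord]),
    normalized_rmse = unname(norm[ord]),
    rank = seq_along(agg)
  )
  structure(
    list(per_biomarker = per, iteration_rmse = iter_rmse,
         n_iterations = n_iterations, k = k, target = target),
    class = "ev_ranking"
  )
}

#' @export
print.ev_ranking <- function(x, ...) {
  cat(sprintf("# LSBoost RMSE ranking: %d biomarkers, %d iterations (top %d shown)\n",
              nrow(x$per_biomarker), x$n_iterations, x$k))
  print(utils::head(x$per_biomarker, x$k))
  invisible(x)
}

#' @rdname rank_biomarkers
#' @export
#' @method tidy ev_ranking
tidy.ev_ranking <- function(x, ...) x$per_biomarker

#' @rdname rank_biomarkers
#' @export
#' @method glance ev_ranking
glance.ev_ranking <- function(x, ...) {
  tibble(n_biomarkers = nrow(x$per_biomarker), n_iterations = x$n_iterations,
         target = x$target, min_rmse = min(x$per_biomarker$rmse),
         max_rmse = max(x$per_biomarker$rmse))
}

#' Top markers of a ranking
#' @param ranking An `ev_ranking`.
#' @param k Number of markers (defaults to the ranking's `k`).
#' @return Character vector of protein ids, best first.
#' @export
top_markers <- function(ranking, k = ranking$k) {
  utils::head(ranking$per_biomarker$protein, k)
}

#' Correlation of per-iteration RMSE among the top biomarkers
#'
#' Pearson correlation between the top-k biomarkers' iteration-RMSE vectors:
#' markers that track the same class signal rise and fall together across
#' resampled splits.
#'
#' @param ranking An `ev_ranking` with >= 3 iterations.
#' @param top_k Number of top biomarkers to correlate.
#' @return A symmetric correlation matrix with unit diagonal; biomarkers
#'   whose iteration RMSE has zero variance get `NA` rows/columns and a
#'   warning naming them.
#' @export
rmse_correlation <- function(ranking, top_k = 10) {
  if (ranking$n_iterations < 3) abort("Need >= 3 iterations for correlations.")
  top <- top_markers(ranking, top_k)
  v <- ranking$iteration_rmse[, top, drop = FALSE]
  flat <- names(which(apply(v, 2L, sd) == 0))
  if (length(flat)) {
    warn(paste0("Zero-variance iteration RMSE (correlation undefined): ",
                paste(flat, collapse = ", ")))
  }
  suppressWarnings(stats::cor(v))
}

#' @rdname rank_biomarkers
#' @export
#' @method autoplot ev_ranking
autoplot.ev_ranking <- function(object, ...) {
  top <- top_markers(object)
  df <- tidyr::pivot_longer(
    as_tibble(object$iteration_rmse[, top, drop = FALSE]),
    dplyr::everything(), names_to = "protein", values_to = "rmse"
  )
  df$protein <- factor(df$protein, levels = top)
  ggplot2::ggplot(df, ggplot2::aes(.data$protein, .data$rmse)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "held-out RMSE across iterations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
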