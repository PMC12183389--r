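#' Stratified train/test split of labelled samples
#'
#' Draws a random split preserving per-class proportions (each class's train
#' count is `round(fraction_train * n_class)`, clamped so both parts stay
#' non-empty). Deterministic given the seed.
#'
#' @param labels Factor/character class labels, one per sample.
#' @param fraction_train Training fraction in `(0, 1)` (default 0.7).
#' @param seed Integer seed.
#' @param ids Optional sample ids (defaults to `names(labels)` or indices).
#' @param stratified Set `FALSE` to split ignoring classes (needed when some
#'   class has a single sample).
#' @return A list of class `ev_split`: `train_ids`, `test_ids`,
#'   `fraction_train`, `stratified`, `seed`.
#' @export
stratified_split <- function(labels, fraction_train = 0.7, seed = 1L,
                             ids = NULL, stratified = TRUE) {
  if (fraction_train <= 0 || fraction_train >= 1) {
    abort("fraction_train must be strictly between 0 and 1.")
  }
  labels <- as.character(labels)
  ids <- ids %||% names(labels) %||% as.character(seq_along(labels))
  withr::local_seed(as.integer(seed))
  if (stratified) {
    singleton <- names(which(table(labels) < 2))
    if (length(singleton)) {
      abort(paste0("Class(es) with a single sample: ",
                   paste(singleton, collapse = ", "),
                   ". Use stratified = FALSE."))
    }
    train <- unlist(lapply(split(ids, labels), function(g) {
      n_tr <- min(max(round(fraction_train * length(g)), 1L), length(g) - 1L)
      sample(g, n_tr)
    }), use.names = FALSE)
  } else {
    n_tr <- min(max(round(fraction_train * length(ids)), 1L), length(ids) - 1L)
    train <- sample(ids, n_tr)
  }
  structure(
    list(train_ids = ids[ids %in% train], test_ids = ids[!ids %in% train],
         fraction_train = fraction_train, stratified = stratified,
         seed = as.integer(seed)),
    class = "ev_split"
  )
}

#' Classification metrics for multi-class predictions
#'
#' Confusion matrix (rows = true class), per-class true-positive and
#' false-negative rates, overall accuracy (trace over total), macro-averaged
#' per-class accuracy, and one-vs-rest AUC per class computed from decision
#' scores by the Mann-Whitney statistic.
#'
#' @param truth,predicted Aligned label vectors over the same class set.
#' @param scores Optional numeric matrix (samples x classes) of per-class
#'   decision scores for the AUC column.
#' @param classes Class-level ordering (default: levels found in `truth`).
#' @return A list of class `ev_class_report`: `confusion`, `metrics` tibble
#'   (class, n, tpr, fnr, auc), `accuracy`, `macro_accuracy`.
#' @export
classification_report <- function(truth, predicted, scores = NULL,
                                  classes = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted) || !length(truth)) {
    abort("`truth` and `predicted` must be aligned and non-empty.")
  }
  classes <- classes %||% (if (is.factor(truth)) levels(truth) else sort(unique(truth)))
  bad <- setdiff(c(truth, predicted), classes)
  if (length(bad)) abort(paste0("Labels outside the class set: ", paste(bad, collapse = ", ")))
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  confusion <- table(truth = tf, predicted = pf)
  tpr <- diag(confusion) / rowSums(confusion)
  aucs <- rep(NA_real_, length(classes))
  if (!is.null(scores)) {
    stopifnot(nrow(scores) == length(truth))
    for (i in seq_along(classes)) {
      pos <- truth == classes[i]
      if (any(pos) && any(!pos)) {
        aucs[i] <- mann_whitney_auc(scores[, i], pos)
      }
    }
  }
  structure(
    list(
      confusion = confusion,
      metrics = tibble(class = classes, n = as.numeric(rowSums(confusion)),
                       tpr = as.numeric(tpr), fnr = 1 - as.numeric(tpr),
                       auc = aucs),
      accuracy = sum(diag(confusion)) / length(truth),
      macro_accuracy = mean(tpr, na.rm = TRUE)
    ),
    class = "ev_class_report"
  )
}

#' @export
print.ev_class_report <- function(x, ...) {
  cat(sprintf("# Classification report: accuracy %.3f (macro %.3f)\n",
              x$accuracy, x$macro_accuracy))
  print(x$confusion)
  print(x$metrics)
  invisible(x)
}

#' @rdname classification_report
#' @param x,object An `ev_class_report`.
#' @param ... Unused.
#' @export
#' @method tidy ev_class_report
tidy.ev_class_report <- function(x, ...) x$metrics

#' @rdname classification_report
#' @export
#' @method glance ev_class_report
glance.ev_class_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, macro_accuracy = x$macro_accuracy,
         min_class_auc = suppressWarnings(min(x$metrics$auc, na.rm = TRUE)))
}

#' @export
#' @method autoplot ev_class_report
autoplot.ev_class_report <- function(object, ...) {
  df <- as_tibble(as.data.frame(object$confusion))
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth, fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "predicted", y = "true", fill = "n") +
    ggplot2::theme_minimal()
}

#' Train the hybrid CNN-to-SVM four-class classifier
#'
#' Standardises features with training-split statistics, trains a small 1-D
#' convolutional network (two conv/ReLU/max-pool blocks, dense activation
#' map, softmax head) on the training samples, extracts the penultimate-layer
#' activation map for every sample, and fits an RBF-kernel SVM
#' (one-vs-one multiclass) on the training activations. Marker panels
#' shorter than the convolutional minimum use a dense feature extractor
#' instead (a notice is emitted). Test-split metrics are primary; training
#' metrics are retained for comparison.
#'
#' @param x A complete [ev_intensity] table on log2 scale.
#' @param classes Four-class labels aligned with the matrix columns.
#' @param split An [stratified_split()] result (default: a fresh 70/30
#'   stratified split from `seed`).
#' @param marker_subset Optional protein ids to restrict the input panel
#'   (e.g. the top markers of [rank_biomarkers()]).
#' @param cnn Hyperparameter list from `cnn_config()` entries: `channels`,
#'   `kernels`, `dense_units`, `epochs`, `learning_rate`, `weight_decay`.
#' @param svm_cost RBF SVM cost parameter.
#' @param seed Integer seed for network initialisation and the SVM's
#'   probability calibration.
#' @return An object of class `ev_hybrid` with the fitted network and SVM,
#'   the split, and `report_test` / `report_train`
#'   ([classification_report()] objects).
#' @export
train_hybrid <- function(x, classes, split = NULL, marker_subset = NULL,
                         cnn = list(), svm_cost = 1, seed = 1L) {
  assert_log2(x, "Classification")
  m <- as_matrix(x)
  if (anyNA(m)) abort("Classifier needs a complete matrix; run impute_median() first.")
  if (!is.null(marker_subset)) {
    unknown <- setdiff(marker_subset, rownames(m))
    if (length(unknown)) abort(paste0("Unknown marker(s): ", paste(unknown, collapse = ", ")))
    m <- m[marker_subset, , drop = FALSE]
  }
  classes <- factor(as.character(classes),
                    levels = intersect(EV_CLASSES, unique(as.character(classes))))
  names(classes) <- colnames(m)
  if (nlevels(classes) < 2) {
    abort(paste0("Training data contains the single class '",
                 levels(classes)[1L], "'; cannot fit a classifier."))
  }
  split <- split %||% stratified_split(classes, 0.7, seed = seed, ids = colnames(m))
  X <- t(m) # samples x proteins
  Xtr <- X[split$train_ids, , drop = FALSE]
  Xte <- X[split$test_ids, , drop = FALSE]
  ytr <- classes[split$train_ids]
  yte <- classes[split$test_ids]
  if (any(table(ytr) == 0)) {
    abort("A class is absent from the training split; use a stratified split.")
  }
  mu <- colMeans(Xtr)
  sg <- pmax(apply(Xtr, 2L, sd), 1e-8)
  std <- function(A) sweep(sweep(A, 2L, mu), 2L, sg, `/`)
  cfg <- do.call(cnn_config, cnn)
  net <- cnn_train(std(Xtr), ytr, cfg, seed = seed)
  Htr <- cnn_forward(net, std(Xtr))$H
  Hte <- cnn_forward(net, std(Xte))$H
  withr::local_seed(as.integer(seed) + 101L)
  svm_fit <- e1071::svm(x = Htr, y = ytr, kernel = "radial", cost = svm_cost,
                        probability = TRUE, scale = FALSE)
  prob_of <- function(H) {
    pr <- predict(svm_fit, H, probability = TRUE)
    p <- attr(pr, "probabilities")[, levels(ytr), drop = FALSE]
    list(pred = as.character(pr), prob = p)
  }
  tr <- prob_of(Htr)
  te <- prob_of(Hte)
  structure(
    list(
      net = net, svm = svm_fit, center = mu, scale = sg,
      markers = rownames(m), classes = levels(ytr), split = split,
      extractor = net$kind,
      report_train = classification_report(as.character(ytr), tr$pred, tr$prob,
                                           classes = levels(ytr)),
      report_test = classification_report(as.character(yte), te$pred, te$prob,
                                          classes = levels(ytr))
    ),
    class = "ev_hybrid"
  )
}

#' @export
print.ev_hybrid <- function(x, ...) {
  cat(sprintf(
    "# Hybrid CNN-SVM (%s extractor, %d features): test accuracy %.3f, train accuracy %.3f\n",
    x$extractor, length(x$markers), x$report_test$accuracy, x$report_train$accuracy
  ))
  invisible(x)
}

#' @export
predict.ev_hybrid <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  m <- if (inherits(newdata, "ev_intensity")) as_matrix(newdata) else newdata
  m <- m[object$markers, , drop = FALSE]
  A <- sweep(sweep(t(m), 2L, object$center), 2L, object$scale, `/`)
  H <- cnn_forward(object$net, A)$H
  pr <- predict(object$svm, H, probability = TRUE)
  if (type == "class") as.character(pr) else
    attr(pr, "probabilities")[, object$classes, drop = FALSE]
}

#' @rdname train_hybrid
#' @param x,object An `ev_hybrid` fit.
#' @param ... Unused.
#' @export
#' @method tidy ev_hybrid
tidy.ev_hybrid <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$report_test$metrics, partition = "test"),
    dplyr::mutate(x$report_train$metrics, partition = "train")
  )
}

#' @rdname train_hybrid
#' @export
#' @method glance ev_hybrid
glance.ev_hybrid <- function(x, ...) {
  tibble(
    extractor = x$extractor, n_features = length(x$markers),
    test_accuracy = x$report_test$accuracy,
    test_macro_accuracy = x$report_test$macro_accuracy,
    train_accuracy = x$report_train$accuracy,
    min_test_auc = suppressWarnings(min(x$report_test$metrics$auc, na.rm = TRUE))
  )
}
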