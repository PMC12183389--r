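#' Fit the logistic multi-marker score model
#'
#' Maximum-likelihood logistic regression of a binary outcome on a marker
#' panel. Markers whose Wald p exceeds `exclusion_p` are dropped in a single
#' backward pass and the model is refit once on the survivors (set
#' `iterate = TRUE` for repeated passes). Perfect separation is detected and
#' flagged; coefficients then come from a lightly ridge-penalised fit rather
#' than a divergent one. The fitted probability is the marker score in
#' `(0, 1)`.
#'
#' @param values Data frame or matrix (samples x markers), complete; row
#'   names or a `sample_id` column identify samples.
#' @param labels Binary outcome aligned with rows (logical, 0/1, or
#'   two-level factor with the second level as positive).
#' @param exclusion_p Wald-p threshold above which a marker is excluded
#'   (default 0.1).
#' @param alpha Significance level recorded for reporting (default 0.05).
#' @param iterate Repeat the exclusion pass until stable (default FALSE:
#'   one pass).
#' @return An object of class `ev_score_model`: `markers`, `intercept`,
#'   `coefficients`, `excluded` tibble (marker, p_value), `model_p`
#'   (likelihood-ratio test of the refit model), `separation`, `scale`
#'   metadata.
#' @export
fit_marker_score <- function(values, labels, exclusion_p = 0.1, alpha = 0.05,
                             iterate = FALSE) {
  vals <- score_values_matrix(values)
  y <- to_binary(labels)
  if (nrow(vals) != length(y)) abort("values and labels must align.")
  if (anyNA(vals)) abort("Marker values must be complete.")
  if (min(table(y)) < 2) abort("Need >= 2 samples in each outcome class.")
  markers <- colnames(vals)
  excluded <- tibble(marker = character(), p_value = numeric())
  repeat {
    fit <- fit_logistic(vals[, markers, drop = FALSE], y)
    if (length(markers) <= 1L) break
    pvals <- fit$wald_p[markers]
    drop <- names(pvals)[pvals > exclusion_p]
    if (length(drop) == length(markers)) {
      # never empty the panel: retain the single most significant marker
      drop <- setdiff(drop, names(which.min(pvals)))
    }
    if (!length(drop)) break
    excluded <- dplyr::bind_rows(excluded,
                                 tibble(marker = drop, p_value = unname(pvals[drop])))
    markers <- setdiff(markers, drop)
    if (!iterate) {
      fit <- fit_logistic(vals[, markers, drop = FALSE], y)
      break
    }
  }
  structure(
    list(markers = markers, intercept = unname(fit$coef["(Intercept)"]),
         coefficients = fit$coef[markers], wald_p = fit$wald_p[markers],
         excluded = excluded, model_p = fit$lrt_p, alpha = alpha,
         separation = fit$separation, scale = "log2_intensity"),
    class = "ev_score_model"
  )
}

score_values_matrix <- function(values) {
  if (is.matrix(values)) return(values)
  values <- as_tibble(values)
  ids <- NULL
  if ("sample_id" %in% names(values)) {
    ids <- values$sample_id
    values <- dplyr::select(values, -"sample_id")
  }
  m <- as.matrix(values)
  if (!is.null(ids)) rownames(m) <- ids
  m
}

fit_logistic <- function(X, y) {
  df <- data.frame(X, check.names = FALSE)
  df$.y <- as.numeric(y)
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  separation <- !fit$converged || anyNA(coef(fit)) ||
    any(abs(coef(fit)[-1L]) > 15, na.rm = TRUE) || fit$deviance < 1e-6
  if (separation) {
    # (near-)separation: fall back to a weak ridge penalty for finite estimates
    co <- ridge_logistic(X, y)
    wald <- rep(0, ncol(X)) # effectively certain markers; never excluded
    names(wald) <- colnames(X)
    return(list(coef = co, wald_p = wald, lrt_p = NA_real_, separation = TRUE))
  }
  sm <- summary(fit)$coefficients
  wald <- sm[-1L, "Pr(>|z|)"]
  names(wald) <- colnames(X)
  lrt_p <- pchisq(fit$null.deviance - fit$deviance,
                  df = fit$df.null - fit$df.residual, lower.tail = FALSE)
  list(coef = coef(fit), wald_p = wald, lrt_p = lrt_p, separation = FALSE)
}

ridge_logistic <- function(X, y, lambda = 1e-3) {
  if (ncol(X) == 1L) {
    # glmnet needs >= 2 columns; augment with a null column and discard it
    Xa <- cbind(X, .null = 0)
    fit <- glmnet::glmnet(Xa, as.numeric(y), family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
    co <- as.numeric(coef(fit))[1:2]
    names(co) <- c("(Intercept)", colnames(X))
    return(co)
  }
  fit <- glmnet::glmnet(X, as.numeric(y), family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  co <- as.numeric(coef(fit))
  names(co) <- c("(Intercept)", colnames(X))
  co
}

#' @export
print.ev_score_model <- function(x, ...) {
  cat(sprintf("# Marker score model: %s%s\n",
              paste(x$markers, collapse = " + "),
              if (x$separation) " [separation: ridge fallback]" else ""))
  eq <- paste(sprintf("%+.3f*%s", x$coefficients, x$markers), collapse = " ")
  cat(sprintf("  logit(p) = %.3f %s\n", x$intercept, eq))
  if (nrow(x$excluded)) {
    cat("  excluded:", paste(sprintf("%s (p=%.3g)", x$excluded$marker,
                                     x$excluded$p_value), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname fit_marker_score
#' @param x,object An `ev_score_model`.
#' @param ... Unused.
#' @export
#' @method tidy ev_score_model
tidy.ev_score_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = "(Intercept)", estimate = x$intercept, p_value = NA_real_),
    tibble(term = x$markers, estimate = unname(x$coefficients),
           p_value = unname(x$wald_p))
  )
}

#' @rdname fit_marker_score
#' @export
#' @method glance ev_score_model
glance.ev_score_model <- function(x, ...) {
  tibble(n_markers = length(x$markers), n_excluded = nrow(x$excluded),
         model_p = x$model_p, separation = x$separation)
}

#' Score samples with a fitted marker model
#'
#' Deterministic sigmoid of the linear predictor over the model's markers.
#'
#' @param model An [fit_marker_score()] model.
#' @param values Samples x markers data (must contain every model marker).
#' @return Named numeric vector of scores in `(0, 1)`.
#' @export
score_samples <- function(model, values) {
  vals <- score_values_matrix(values)
  missing_mk <- setdiff(model$markers, colnames(vals))
  if (length(missing_mk)) {
    abort(paste0("Missing marker column(s): ", paste(missing_mk, collapse = ", ")))
  }
  eta <- model$intercept +
    as.numeric(vals[, model$markers, drop = FALSE] %*% model$coefficients)
  out <- 1 / (1 + exp(-eta))
  names(out) <- rownames(vals)
  out
}

#' Exhaustive marker-combination search
#'
#' Fits [fit_marker_score()] for every non-empty subset of the candidate
#' markers (2^k - 1 models), scores the fitting samples (or a held-out test
#' part when a split is supplied), and evaluates each panel by ROC AUC with
#' its DeLong SE. The best panel maximises AUC with ties broken by minimal
#' SE, then by smaller panel, then lexicographically, so exactly one subset
#' is flagged.
#'
#' @param values Samples x markers data (rows named by sample id).
#' @param labels Binary outcome aligned with rows.
#' @param candidates Candidate marker names (<= 15; exhaustive enumeration).
#' @param split Optional [stratified_split()] over the sample ids: models are
#'   fit on the training part and AUCs measured on the test part.
#' @param exclusion_p Passed to [fit_marker_score()]. Default 1: every subset
#'   is evaluated exactly as listed, so nested panels stay distinguishable;
#'   the backward-exclusion rule is applied when the final score model is
#'   built, not during the search.
#' @return A tibble of class `ev_combos`: `markers` (list column), `panel`
#'   (label), `n_markers`, `auc`, `auc_se`, `ci_lo`, `ci_hi`, `is_best`;
#'   sorted best first.
#' @export
evaluate_combinations <- function(values, labels, candidates = NULL,
                                  split = NULL, exclusion_p = 1) {
  vals <- score_values_matrix(values)
  y <- to_binary(labels)
  names(y) <- rownames(vals)
  candidates <- candidates %||% colnames(vals)
  if (length(candidates) > 15) abort("> 15 candidates; shortlist first (2^k blow-up).")
  unknown <- setdiff(candidates, colnames(vals))
  if (length(unknown)) abort(paste0("Unknown candidates: ", paste(unknown, collapse = ", ")))
  subsets <- unlist(lapply(seq_along(candidates), function(k) {
    utils::combn(candidates, k, simplify = FALSE)
  }), recursive = FALSE)
  fit_rows <- if (is.null(split)) rownames(vals) else split$train_ids
  eval_rows <- if (is.null(split)) rownames(vals) else split$test_ids
  rows <- purrr::map_dfr(subsets, function(mk) {
    model <- fit_marker_score(vals[fit_rows, mk, drop = FALSE], y[fit_rows],
                              exclusion_p = exclusion_p)
    sc <- score_samples(model, vals[eval_rows, , drop = FALSE])
    roc <- roc_auc(sc, y[eval_rows])
    tibble(markers = list(mk), panel = paste(mk, collapse = "+"),
           n_markers = length(mk), auc = roc$auc, auc_se = roc$auc_se,
           ci_lo = roc$ci95[1], ci_hi = roc$ci95[2])
  })
  ord <- order(-rows$auc, rows$auc_se, rows$n_markers, rows$panel)
  rows <- rows[ord, ]
  rows$is_best <- seq_len(nrow(rows)) == 1L
  structure(rows, class = c("ev_combos", class(tibble())))
}

#' Best panel of a combination search
#' @param combos An [evaluate_combinations()] result.
#' @return Character vector of the winning panel's markers.
#' @export
best_combination <- function(combos) {
  combos$markers[[which(combos$is_best)]]
}

#' Normalise marker concentrations to the control-group median
#'
#' Divides each marker's concentrations by that marker's median among
#' control samples, putting heterogeneous assay scales on a common
#' fold-of-control axis (control medians map to 1).
#'
#' @param concentrations Tibble with `sample_id` plus one numeric column per
#'   marker (linear scale, e.g. pg/mL).
#' @param control_ids Sample ids of the control group.
#' @return The table with every marker column divided by its control median.
#' @export
normalize_to_control_median <- function(concentrations, control_ids) {
  tb <- as_tibble(concentrations)
  if (!"sample_id" %in% names(tb)) abort("Need a sample_id column.")
  ctrl <- tb$sample_id %in% control_ids
  if (!any(ctrl)) abort("No control samples found.")
  num_cols <- names(tb)[vapply(tb, is.numeric, logical(1))]
  for (col in num_cols) {
    med <- median(tb[[col]][ctrl], na.rm = TRUE)
    if (!is.finite(med) || med == 0) {
      abort(paste0("Zero or undefined control median for marker ", col))
    }
    tb[[col]] <- tb[[col]] / med
  }
  tb
}

#' Dichotomise a marker score into recurrence-risk groups
#'
#' High risk iff the score strictly exceeds the threshold (default 0.5).
#'
#' @param score Numeric scores in `[0, 1]`.
#' @param threshold Risk cutoff (strict `>`).
#' @return Factor with levels `low_risk`, `high_risk`.
#' @export
risk_classify <- function(score, threshold = 0.5) {
  if (any(score < 0 | score > 1, na.rm = TRUE)) abort("Scores must lie in [0, 1].")
  factor(ifelse(score > threshold, "high_risk", "low_risk"),
         levels = c("low_risk", "high_risk"))
}
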