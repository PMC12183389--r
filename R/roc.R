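# Mann-Whitney AUC with midrank tie handling: P(score_pos > score_neg) +
# 0.5 P(tie), computed from the rank sum.
mann_whitney_auc <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present.")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Hanley-McNeil standard error of the AUC (distribution-free moments)
hanley_mcneil_se <- function(auc, n1, n0) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n0 - 1) * (q2 - auc^2)) /
         (n1 * n0))
}

# DeLong variance of the AUC via placement values
delong_se <- function(scores, positive) {
  xs <- scores[positive]
  ys <- scores[!positive]
  n1 <- length(xs)
  n0 <- length(ys)
  v10 <- vapply(xs, function(x) mean((x > ys) + 0.5 * (x == ys)), numeric(1))
  v01 <- vapply(ys, function(y) mean((xs > y) + 0.5 * (xs == y)), numeric(1))
  sqrt(var(v10) / n1 + var(v01) / n0)
}

#' ROC curve, AUC, standard error and confidence interval
#'
#' Builds the empirical ROC curve over all score thresholds. The AUC is the
#' Mann-Whitney concordance statistic (equal, by construction, to the
#' trapezoidal area under the curve); its standard error is reported both by
#' the Hanley-McNeil formula and by the DeLong placement-value variance, and
#' the 95% CI is DeLong-based on the probit-free linear scale, clipped to
#' `[0, 1]`.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Logical/0-1 vector (or factor with two levels, second =
#'   positive) aligned with `scores`.
#' @return An object of class `ev_roc`: `curve` tibble (threshold,
#'   sensitivity, specificity, descending thresholds), `auc`, `auc_se`
#'   (DeLong), `auc_se_hanley`, `ci95`, class counts.
#' @export
roc_auc <- function(scores, labels) {
  positive <- to_binary(labels)
  if (length(scores) != length(positive)) abort("scores and labels must align.")
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present.")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(scores >= t & positive) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & !positive) / n0, numeric(1))
  auc <- mann_whitney_auc(scores, positive)
  se_d <- delong_se(scores, positive)
  ci <- pmin(pmax(auc + qnorm(c(0.025, 0.975)) * se_d, 0), 1)
  structure(
    list(
      curve = tibble(threshold = thr, sensitivity = sens, specificity = spec),
      auc = auc, auc_se = se_d,
      auc_se_hanley = hanley_mcneil_se(auc, n1, n0),
      ci95 = ci, n_positive = n1, n_negative = n0,
      scores = scores, positive = positive
    ),
    class = "ev_roc"
  )
}

to_binary <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) abort("Numeric labels must be 0/1.")
    return(labels == 1)
  }
  f <- factor(labels)
  if (nlevels(f) != 2) abort("Labels must have exactly two levels.")
  f == levels(f)[2L]
}

#' @export
print.ev_roc <- function(x, ...) {
  cat(sprintf("# ROC: AUC %.3f (DeLong SE %.3f, 95%% CI %.3f-%.3f; %d pos / %d neg)\n",
              x$auc, x$auc_se, x$ci95[1], x$ci95[2], x$n_positive, x$n_negative))
  invisible(x)
}

#' @rdname roc_auc
#' @param x,object An `ev_roc`.
#' @param ... Unused.
#' @export
#' @method tidy ev_roc
tidy.ev_roc <- function(x, ...) x$curve

#' @rdname roc_auc
#' @export
#' @method glance ev_roc
glance.ev_roc <- function(x, ...) {
  tibble(auc = x$auc, auc_se = x$auc_se, auc_se_hanley = x$auc_se_hanley,
         ci_lo = x$ci95[1], ci_hi = x$ci95[2],
         n_positive = x$n_positive, n_negative = x$n_negative)
}

#' @rdname roc_auc
#' @export
#' @method autoplot ev_roc
autoplot.ev_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  subtitle = sprintf("AUC %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Sensitivity at a fixed specificity
#'
#' Reads the empirical ROC at the most permissive threshold whose specificity
#' still meets the target (conservative: specificity >= target, no
#' interpolation beyond observed operating points) and attaches a stratified
#' bootstrap percentile CI.
#'
#' @param roc An [roc_auc()] result.
#' @param target_specificity Specificity to fix (default 0.95).
#' @param n_boot Bootstrap resamples for the CI (stratified within class).
#' @param seed Integer seed for the bootstrap.
#' @return A one-row tibble: `target_specificity`, `sensitivity`, `ci_lo`,
#'   `ci_hi`. When no threshold attains the target, sensitivity 0 is
#'   returned with a notice.
#' @export
sensitivity_at_specificity <- function(roc, target_specificity = 0.95,
                                       n_boot = 2000, seed = 1L) {
  # O(n log n) sweep: operating points at the last occurrence of each
  # distinct score in descending order
  sens_at <- function(scores, positive) {
    n1 <- sum(positive)
    n0 <- sum(!positive)
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]
    cp <- cumsum(positive[o])
    cn <- cumsum(!positive[o])
    idx <- which(!duplicated(s, fromLast = TRUE))
    sens <- c(0, cp[idx] / n1)
    spec <- c(1, (n0 - cn[idx]) / n0)
    ok <- spec >= target_specificity
    if (!any(ok)) return(NA_real_)
    max(sens[ok])
  }
  est <- sens_at(roc$scores, roc$positive)
  if (is.na(est)) {
    inform("No threshold attains the target specificity; reporting sensitivity 0.")
    est <- 0
  }
  withr::local_seed(as.integer(seed))
  ip <- which(roc$positive)
  ineg <- which(!roc$positive)
  bs <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
    v <- sens_at(roc$scores[idx], roc$positive[idx])
    if (is.na(v)) 0 else v
  }, numeric(1))
  ci <- unname(quantile(bs, c(0.025, 0.975), type = 7))
  tibble(target_specificity = target_specificity, sensitivity = est,
         ci_lo = ci[1], ci_hi = ci[2])
}
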