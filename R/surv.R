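#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group plus the two-sample log-rank
#' chi-square (1 df) and its p value, via the survival package.
#'
#' @param times Follow-up times (months, >= 0).
#' @param events Event indicators (1 = event, 0 = censored).
#' @param groups Two-level group indicator (e.g. high/low risk).
#' @return An object of class `ev_survfit`: `curves` tibble (group, time,
#'   survival, n_risk, n_event), `logrank_chi2`, `logrank_p`, `fit`
#'   (the `survfit` object).
#' @export
km_logrank <- function(times, events, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) abort("Exactly two groups required.")
  if (any(table(groups) == 0)) abort("Both groups must be non-empty.")
  if (sum(events) < 1) abort("Need at least one event.")
  df <- data.frame(time = times, event = events, group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sm <- summary(fit, censored = TRUE)
  strata <- sub("^group=", "", as.character(sm$strata))
  curves <- tibble(group = strata, time = sm$time, survival = sm$surv,
                   n_risk = sm$n.risk, n_event = sm$n.event)
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  structure(
    list(curves = curves, logrank_chi2 = lr$chisq,
         logrank_p = pchisq(lr$chisq, df = 1, lower.tail = FALSE),
         fit = fit),
    class = "ev_survfit"
  )
}

#' @export
print.ev_survfit <- function(x, ...) {
  cat(sprintf("# Kaplan-Meier / log-rank: chi2 %.3f, p %.3g\n",
              x$logrank_chi2, x$logrank_p))
  invisible(x)
}

#' @rdname km_logrank
#' @param x,object An `ev_survfit`.
#' @param ... Unused.
#' @export
#' @method tidy ev_survfit
tidy.ev_survfit <- function(x, ...) x$curves

#' @rdname km_logrank
#' @export
#' @method glance ev_survfit
glance.ev_survfit <- function(x, ...) {
  tibble(logrank_chi2 = x$logrank_chi2, logrank_p = x$logrank_p)
}

#' @rdname km_logrank
#' @export
#' @method autoplot ev_survfit
autoplot.ev_survfit <- function(object, ...) {
  start <- dplyr::distinct(object$curves, .data$group)
  start <- dplyr::mutate(start, time = 0, survival = 1)
  df <- dplyr::bind_rows(start,
                         dplyr::select(object$curves, "group", "time", "survival"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability",
                  colour = NULL,
                  subtitle = sprintf("log-rank p = %.3g", object$logrank_p)) +
    ggplot2::theme_minimal()
}

#' Cox proportional-hazards ratio between two groups
#'
#' Partial-likelihood estimate with Efron tie handling and a Wald 95% CI on
#' the log scale. If one group carries no events the model cannot converge;
#' the result is flagged rather than erroring.
#'
#' @inheritParams km_logrank
#' @return A one-row tibble: `hazard_ratio`, `ci_lo`, `ci_hi`, `p_value`,
#'   `log_hr`, `log_hr_se`, `converged`.
#' @export
cox_hazard_ratio <- function(times, events, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) abort("Exactly two groups required.")
  ev_by_group <- tapply(events, groups, sum)
  df <- data.frame(time = times, event = events, group = groups)
  if (any(ev_by_group == 0)) {
    warn("One group has no events; hazard ratio not estimable.")
    return(tibble(hazard_ratio = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                  p_value = NA_real_, log_hr = NA_real_, log_hr_se = NA_real_,
                  converged = FALSE))
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ group, data = df,
                         ties = "efron")
  s <- summary(fit)
  beta <- unname(coef(fit))
  se <- unname(sqrt(fit$var[1, 1]))
  tibble(
    hazard_ratio = exp(beta),
    ci_lo = exp(beta - qnorm(0.975) * se),
    ci_hi = exp(beta + qnorm(0.975) * se),
    p_value = unname(s$coefficients[1, "Pr(>|z|)"]),
    log_hr = beta, log_hr_se = se, converged = TRUE
  )
}

#' Survival analysis of score-defined risk groups
#'
#' Dichotomises a marker score (default: high risk when score > 0.5, the
#' recurrence-risk rule; alternatively a median split), then runs
#' [km_logrank()] and [cox_hazard_ratio()] on the chosen endpoint.
#'
#' @param ann Annotation tibble with survival columns (`rfs_time`,
#'   `rfs_event`, `os_time`, `os_event`).
#' @param scores Named numeric vector of marker scores (names = sample ids).
#' @param endpoint `"rfs"` or `"os"`.
#' @param cutoff Score cutoff for the high-risk group (strict `>`), or
#'   `"median"` for a median split.
#' @param fallback_median When the fixed cutoff leaves one risk group empty
#'   (e.g. every case scores near 1), fall back to a median split instead of
#'   returning a degenerate result (default TRUE; the applied rule is
#'   recorded in `cutoff_rule`).
#' @return A list of class `ev_surv_eval`: `km` ([km_logrank()] result),
#'   `cox` ([cox_hazard_ratio()] row), `groups` tibble, `cutoff`,
#'   `cutoff_rule`. With a single risk group and no fallback, `km` is `NULL`
#'   and `cox` is a flagged non-converged row.
#' @export
survival_by_score <- function(ann, scores, endpoint = c("rfs", "os"),
                              cutoff = 0.5, fallback_median = TRUE) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_time")
  ecol <- paste0(endpoint, "_event")
  keep <- !is.na(ann[[tcol]]) & !is.na(ann[[ecol]]) & ann$sample_id %in% names(scores)
  d <- ann[keep, ]
  s <- scores[d$sample_id]
  rule <- if (identical(cutoff, "median")) "median" else "fixed"
  cut_val <- if (rule == "median") median(s) else cutoff
  split_groups <- function(cv) {
    factor(ifelse(s > cv, "high_risk", "low_risk"),
           levels = c("low_risk", "high_risk"))
  }
  grp <- split_groups(cut_val)
  if (any(table(grp) == 0) && rule == "fixed" && fallback_median) {
    warn(sprintf("Cutoff %.3g leaves one risk group empty; using a median split.",
                 cut_val))
    cut_val <- median(s)
    rule <- "median (fixed cutoff degenerate)"
    grp <- split_groups(cut_val)
  }
  if (any(table(grp) == 0)) {
    warn("Single risk group; survival comparison not estimable.")
    km <- NULL
    cox <- tibble(hazard_ratio = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                  p_value = NA_real_, log_hr = NA_real_, log_hr_se = NA_real_,
                  converged = FALSE)
  } else {
    km <- km_logrank(d[[tcol]], d[[ecol]], grp)
    cox <- cox_hazard_ratio(d[[tcol]], d[[ecol]], grp)
  }
  structure(
    list(km = km, cox = cox,
         groups = tibble(sample_id = d$sample_id, score = unname(s), group = grp),
         endpoint = endpoint, cutoff = cut_val, cutoff_rule = rule),
    class = "ev_surv_eval"
  )
}

#' @export
print.ev_surv_eval <- function(x, ...) {
  lr_p <- if (is.null(x$km)) NA_real_ else x$km$logrank_p
  cat(sprintf("# %s by score > %.3g [%s]: HR %.3f (95%% CI %.3f-%.3f), log-rank p %.3g\n",
              toupper(x$endpoint), x$cutoff, x$cutoff_rule, x$cox$hazard_ratio,
              x$cox$ci_lo, x$cox$ci_hi, lr_p))
  invisible(x)
}
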