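#' Welch two-group test on log2 intensities
#'
#' Two-sided two-sample t-test with unequal-variance (Welch) degrees of
#' freedom; the effect is the difference of group means on the log2 scale.
#'
#' @param a,b Numeric vectors of observed log2 intensities (>= 2 values each;
#'   `NA`s are dropped).
#' @return A one-row tibble with `p_value` and `log2_difference`
#'   (mean of `a` minus mean of `b`).
#' @export
two_group_test <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("Each group needs >= 2 observed values.")
  }
  diff <- mean(a) - mean(b)
  if (sd(a) == 0 && sd(b) == 0) {
    # degenerate: no within-group variance; identical means give p = 1
    p <- if (abs(diff) < 1e-12) 1 else 0
  } else {
    p <- t.test(a, b, var.equal = FALSE)$p.value
  }
  tibble(p_value = p, log2_difference = diff)
}

# resolve a group selector (character groups, classes, or sample ids) to ids
resolve_selector <- function(selector, ann) {
  if (is.null(selector) || !length(selector)) abort("Empty group selector.")
  if (all(selector %in% ann$sample_id)) return(selector)
  hit <- ann$group %in% selector
  if ("class" %in% names(ann)) hit <- hit | as.character(ann$class) %in% selector
  if ("cancer" %in% selector) hit <- hit | ann$group != "HC"
  ids <- ann$sample_id[hit]
  if (!length(ids)) abort(paste0("Selector matches no samples: ",
                                 paste(selector, collapse = ", ")))
  ids
}

#' Volcano differential-expression selection
#'
#' Tests every protein between two sample groups with [two_group_test()] and
#' flags differentially expressed proteins by the standard volcano rule:
#' `p < p_thresh` and `|log2 difference| > fc_log2_thresh` (defaults p < 0.05
#' and fold change > 2). Fold change is reported on the linear scale as
#' `2^|log2_difference|` with direction carried by the up/down flags. Raw p
#' values drive the selection; a Benjamini-Hochberg column is appended for
#' information only.
#'
#' @param x An [ev_intensity] table on log2 scale.
#' @param ann Annotation tibble.
#' @param group_a,group_b Selectors: group names (`"HC"`, `"TNBC"`, ...),
#'   class labels, the shorthand `"cancer"` (all non-HC), or explicit sample
#'   ids. Effects are `group_a` minus `group_b`.
#' @param p_thresh Raw p-value threshold (strict).
#' @param fc_log2_thresh Absolute log2-difference threshold (strict).
#' @return A tibble of class `ev_volcano`, one row per testable protein
#'   (>= 2 observations per group), sorted by ascending p: columns `protein`,
#'   `log2_difference`, `fold_change`, `p_value`, `p_adj_bh`,
#'   `significant_up`, `significant_down`. Untestable proteins are skipped
#'   with a warning.
#' @export
volcano_select <- function(x, ann, group_a, group_b,
                           p_thresh = 0.05, fc_log2_thresh = 1) {
  assert_log2(x, "Differential expression")
  m <- as_matrix(x)
  ids_a <- resolve_selector(group_a, ann)
  ids_b <- resolve_selector(group_b, ann)
  ma <- m[, ids_a, drop = FALSE]
  mb <- m[, ids_b, drop = FALSE]
  ok <- rowSums(!is.na(ma)) >= 2 & rowSums(!is.na(mb)) >= 2
  if (any(!ok)) {
    warn(sprintf("%d protein(s) skipped (< 2 observations in a group).", sum(!ok)))
  }
  rows <- purrr::map_dfr(which(ok), function(j) {
    res <- two_group_test(ma[j, ], mb[j, ])
    dplyr::mutate(res, protein = rownames(m)[j], .before = 1L)
  })
  rows <- dplyr::mutate(rows,
    fold_change = 2^abs(.data$log2_difference),
    p_adj_bh = p.adjust(.data$p_value, method = "BH"),
    significant_up = .data$p_value < p_thresh & .data$log2_difference > fc_log2_thresh,
    significant_down = .data$p_value < p_thresh & .data$log2_difference < -fc_log2_thresh
  )
  rows <- dplyr::select(rows, "protein", "log2_difference", "fold_change",
                        "p_value", "p_adj_bh", "significant_up", "significant_down")
  rows <- dplyr::arrange(rows, .data$p_value)
  structure(rows, class = c("ev_volcano", class(tibble())),
            p_thresh = p_thresh, fc_log2_thresh = fc_log2_thresh,
            test = "Welch two-sample t (two-sided)")
}

#' Apply the volcano selection rule to a table of printed statistics
#'
#' Convenience for externally reported (p, fold change) pairs: flags rows with
#' `p < p_thresh` and linear `fold_change > fc_thresh`.
#'
#' @param stats A data frame with columns `p_value` and `fold_change`
#'   (linear-scale, direction-free).
#' @param p_thresh,fc_thresh Strict thresholds (defaults 0.05 and 2).
#' @return The input with a logical `selected` column.
#' @export
dep_rule <- function(stats, p_thresh = 0.05, fc_thresh = 2) {
  dplyr::mutate(as_tibble(stats),
    selected = .data$p_value < p_thresh & .data$fold_change > fc_thresh
  )
}

#' Effect/p grid over multiple group comparisons
#'
#' Computes, for each named comparison and each protein (optionally
#' restricted to a marker subset), the log2 difference and Welch p value:
#' the statistics behind subtype bubble-plot panels.
#'
#' @param x An [ev_intensity] table on log2 scale.
#' @param ann Annotation tibble.
#' @param comparisons Named list; each element is `list(a = selector,
#'   b = selector)`.
#' @param marker_subset Optional character vector of proteins to restrict to.
#' @return A tibble with `comparison`, `protein`, `log2_difference`,
#'   `fold_change`, `p_value`, `significant_up`, `significant_down`.
#' @export
comparison_grid <- function(x, ann, comparisons, marker_subset = NULL) {
  if (!length(comparisons)) abort("Need at least one comparison.")
  if (!is.null(marker_subset)) {
    unknown <- setdiff(marker_subset, x$protein)
    if (length(unknown)) {
      abort(paste0("Unknown proteins in marker_subset: ", paste(unknown, collapse = ", ")))
    }
    x <- x[match(marker_subset, x$protein), , drop = FALSE]
  }
  purrr::imap_dfr(comparisons, function(cmp, nm) {
    v <- volcano_select(x, ann, cmp$a, cmp$b)
    dplyr::mutate(
      dplyr::select(as_tibble(v), "protein", "log2_difference", "fold_change",
                    "p_value", "significant_up", "significant_down"),
      comparison = nm, .before = 1L
    )
  })
}

#' Volcano plot of differential-expression results
#'
#' @param object An `ev_volcano` table from [volcano_select()].
#' @param ... Unused.
#' @return A ggplot: -log10 p against log2 difference, selected proteins
#'   coloured by direction.
#' @export
#' @method autoplot ev_volcano
autoplot.ev_volcano <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object), status = dplyr::case_when(
    .data$significant_up ~ "up",
    .data$significant_down ~ "down",
    TRUE ~ "ns"
  ))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2_difference, -log10(.data$p_value),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "p_thresh")), linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * attr(object, "fc_log2_thresh"),
                        linetype = 2) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 difference", y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}
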