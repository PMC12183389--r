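#' Log2-transform a linear-scale intensity table
#'
#' Replaces every observed entry by its log2; missingness is untouched.
#' Refuses non-positive observed values, naming the offending protein and
#' sample.
#'
#' @param x An [ev_intensity] table on linear scale.
#' @return The table on log2 scale.
#' @export
normalize_log2 <- function(x) {
  if (intensity_scale(x) != "linear") {
    abort("normalize_log2() expects a linear-scale table.")
  }
  m <- as_matrix(x)
  bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "Non-positive intensity for protein '%s', sample '%s'.",
      rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]
    ))
  }
  matrix_to_intensity(log2(m), scale = "log2")
}

# observed (non-missing) count and fraction of each protein within each group
presence_by_group <- function(x, ann, by) {
  m <- !is.na(as_matrix(x))
  grp <- ann[[by]][match(colnames(m), ann$sample_id)]
  groups <- unique(grp)
  counts <- vapply(groups, function(g) rowSums(m[, grp == g, drop = FALSE]),
                   numeric(nrow(m)))
  sizes <- vapply(groups, function(g) sum(grp == g), numeric(1))
  list(counts = counts, sizes = sizes, groups = groups)
}

make_filter_report <- function(x_in, x_out, rule, pres) {
  frac <- sweep(pres$counts, 2L, pres$sizes, `/`)
  report <- tibble(
    protein = rep(rownames(frac), times = ncol(frac)),
    group = rep(colnames(frac), each = nrow(frac)),
    n_observed = as.vector(pres$counts),
    fraction_observed = as.vector(frac)
  )
  structure(
    list(n_input = nrow(x_in), n_output = nrow(x_out), rule = rule,
         per_group = report),
    class = "ev_filter_report"
  )
}

#' @export
print.ev_filter_report <- function(x, ...) {
  cat(sprintf("# Presence filter [%s]: %d -> %d proteins\n",
              x$rule, x$n_input, x$n_output))
  invisible(x)
}

#' Retrieve the presence-filter report attached to a filtered table
#' @param x A table returned by [filter_min_individuals()] or
#'   [filter_group_presence()].
#' @return An `ev_filter_report` (counts, rule, per-group presence tibble).
#' @export
filter_report <- function(x) attr(x, "filter_report")

#' Presence filter: observed in at least `min_n` individuals of some group
#'
#' First reduction step of the analysis: a protein is retained iff at least
#' one annotation group contains `min_n` or more samples with an observed
#' (non-missing) value for it.
#'
#' @param x An [ev_intensity] table.
#' @param ann Annotation tibble with `sample_id` and `group`.
#' @param min_n Minimum observed individuals (default 10, non-strict).
#' @param by Annotation column defining the groups (default `"group"`).
#' @return The filtered table with a `filter_report` attribute
#'   (see [filter_report()]).
#' @export
filter_min_individuals <- function(x, ann, min_n = 10, by = "group") {
  if (min_n < 1) abort("min_n must be >= 1.")
  pres <- presence_by_group(x, ann, by)
  keep <- apply(pres$counts >= min_n, 1L, any)
  out <- x[keep, , drop = FALSE]
  attr(out, "filter_report") <- make_filter_report(
    x, out, sprintf(">= %d observed individuals in some %s", min_n, by), pres
  )
  out
}

#' Presence filter: observed in more than a fraction of every group
#'
#' Second reduction step: a protein is retained iff its observed fraction
#' strictly exceeds `min_fraction` within every group (default reading of
#' presence "in more than 70% of all groups"). Setting
#' `mode = "fraction_of_groups"` instead requires the per-group criterion to
#' hold in more than `min_fraction` of the groups.
#'
#' @param x An [ev_intensity] table.
#' @param ann Annotation tibble with `sample_id` and `group`.
#' @param min_fraction Presence threshold in `[0, 1)`; comparison is strict.
#' @param mode `"per_group"` (default) or `"fraction_of_groups"`.
#' @param by Annotation column defining the groups.
#' @return The filtered table with a `filter_report` attribute.
#' @export
filter_group_presence <- function(x, ann, min_fraction = 0.7,
                                  mode = c("per_group", "fraction_of_groups"),
                                  by = "group") {
  mode <- match.arg(mode)
  if (min_fraction < 0 || min_fraction >= 1) abort("min_fraction must be in [0, 1).")
  pres <- presence_by_group(x, ann, by)
  if (any(pres$sizes == 0)) abort("Every group must be non-empty.")
  frac <- sweep(pres$counts, 2L, pres$sizes, `/`)
  keep <- if (mode == "per_group") {
    apply(frac > min_fraction, 1L, all)
  } else {
    rowMeans(frac > min_fraction) > min_fraction
  }
  out <- x[keep, , drop = FALSE]
  attr(out, "filter_report") <- make_filter_report(
    x, out, sprintf("> %.0f%% observed in %s [%s]", 100 * min_fraction, by, mode), pres
  )
  out
}

#' Median-impute missing intensities for the machine-learning stages
#'
#' Replaces each missing entry by the per-protein median of its observed
#' values, computed across all samples (not per group, so class labels never
#' leak into classifier input). Differential-expression testing keeps using
#' observed values only; imputation exists solely to feed complete arrays to
#' the boosting and classification stages.
#'
#' @param x An [ev_intensity] table (typically after presence filtering).
#' @return A complete table (no missing entries).
#' @export
impute_median <- function(x) {
  m <- as_matrix(x)
  if (!anyNA(m)) return(x)
  med <- apply(m, 1L, median, na.rm = TRUE)
  none <- which(is.na(med))
  if (length(none)) {
    abort(paste0("Proteins with no observed values: ",
                 paste(rownames(m)[none], collapse = ", ")))
  }
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- med[idx[, 1L]]
  matrix_to_intensity(m, scale = intensity_scale(x))
}
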