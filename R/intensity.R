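#' Construct an EV protein intensity table
#'
#' The central container of the package: a wide tibble with one row per
#' protein and one column per sample, carrying TMT reporter intensities.
#' Missing observations are `NA` (never zero). A scale attribute records
#' whether values are raw (`"linear"`) or log2-transformed (`"log2"`);
#' differential-expression and machine-learning stages require `"log2"`.
#'
#' @param data A data frame whose first column (named `protein`) holds unique
#'   protein identifiers and whose remaining columns are numeric per-sample
#'   intensities with unique names.
#' @param scale `"log2"` or `"linear"`.
#' @return A tibble of class `ev_intensity`.
#' @export
ev_intensity <- function(data, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  data <- as_tibble(data)
  if (ncol(data) < 2L || names(data)[1L] != "protein") {
    abort("`data` must have a first column named `protein` plus >= 1 sample column.")
  }
  prot <- as.character(data$protein)
  if (anyDuplicated(prot)) {
    dup <- unique(prot[duplicated(prot)])
    abort(paste0("Duplicate protein ids: ", paste(dup, collapse = ", ")))
  }
  smp <- names(data)[-1L]
  if (anyDuplicated(smp)) {
    abort("Duplicate sample ids in column names.")
  }
  not_num <- smp[!vapply(data[smp], is.numeric, logical(1))]
  if (length(not_num)) {
    abort(paste0("Non-numeric sample columns: ", paste(not_num, collapse = ", ")))
  }
  data$protein <- prot
  structure(data,
    class = c("ev_intensity", class(tibble())),
    scale = scale
  )
}

#' @export
print.ev_intensity <- function(x, ...) {
  cat(sprintf(
    "# EV intensity table: %d proteins x %d samples [%s scale, %.1f%% missing]\n",
    nrow(x), ncol(x) - 1L, intensity_scale(x),
    100 * mean(is.na(as_matrix(x)))
  ))
  NextMethod()
}

#' Scale tag of an intensity table
#' @param x An `ev_intensity` table.
#' @return `"log2"` or `"linear"`.
#' @export
intensity_scale <- function(x) attr(x, "scale") %||% "log2"

#' Extract the numeric matrix (proteins x samples) from an intensity table
#' @param x An `ev_intensity` table.
#' @return A numeric matrix with protein rownames and sample colnames;
#'   missing entries are `NA`.
#' @export
as_matrix <- function(x) {
  m <- as.matrix(x[, -1L, drop = FALSE])
  rownames(m) <- x$protein
  m
}

sample_ids <- function(x) names(x)[-1L]

# rebuild an ev_intensity from a matrix, preserving the scale tag
matrix_to_intensity <- function(m, scale) {
  ev_intensity(
    tibble::as_tibble(cbind(
      tibble(protein = rownames(m)),
      as_tibble(m, .name_repair = "minimal")
    )),
    scale = scale
  )
}

assert_log2 <- function(x, what) {
  if (intensity_scale(x) != "log2") {
    abort(paste0(what, " requires log2-scale intensities; call normalize_log2() first."))
  }
}

#' Read an intensity matrix from delimited text
#'
#' Expects a header row of sample ids, a first column of protein ids, and
#' proteins in rows. Empty cells and the literal `NA` are parsed as missing.
#' A table with more columns than rows that fails annotation matching usually
#' indicates a transposed export; the loader refuses to guess.
#'
#' @param path Path to a TSV or CSV file (dialect inferred from extension).
#' @param scale Scale tag to attach, `"log2"` (default) or `"linear"`.
#' @return An [ev_intensity] table.
#' @export
read_intensity <- function(path, scale = "log2") {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path,
    delim = delim, na = c("", "NA"), show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  names(raw)[1L] <- "protein"
  vals <- raw[-1L]
  num <- lapply(names(vals), function(s) {
    v <- suppressWarnings(as.numeric(vals[[s]]))
    bad <- which(is.na(v) & !is.na(vals[[s]]))
    if (length(bad)) {
      abort(sprintf(
        "Non-numeric cell in sample '%s' at protein '%s': '%s'",
        s, raw$protein[bad[1L]], vals[[s]][bad[1L]]
      ))
    }
    v
  })
  names(num) <- names(vals)
  ev_intensity(tibble(protein = raw$protein, !!!num), scale = scale)
}

#' Write an intensity table to delimited text
#'
#' Missing values are written as empty cells; the round trip
#' write/[read_intensity] is lossless for values, missingness and ids.
#'
#' @param x An [ev_intensity] table.
#' @param path Output path (`.csv` writes comma-separated, otherwise tabs).
#' @return `path`, invisibly.
#' @export
write_intensity <- function(x, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(as_tibble(x), path, delim = delim, na = "")
  invisible(path)
}

#' Read a sample annotation table
#'
#' Columns: `sample_id`, `group` (HC/Luminal/HER2/TNBC), `recurrence`
#' (none/early/late/not_applicable; early = before 2 years, late = within
#' 2-5 years), optional `rfs_time`, `rfs_event`, `os_time`, `os_event`
#' (months / 0-1 event flags) and any further clinical covariates.
#'
#' @param path Path to a TSV or CSV file.
#' @return A validated annotation tibble.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  ann <- readr::read_delim(path, delim = delim, na = c("", "NA"), show_col_types = FALSE)
  validate_annotations(ann)
}

#' Validate a sample annotation tibble
#'
#' Checks id uniqueness, group/recurrence levels, the healthy-control
#' consistency rules (controls carry no recurrence or survival information)
#' and that relapse-free survival never exceeds overall survival.
#'
#' @param ann A data frame of sample annotations.
#' @return The annotations as a tibble, invisibly validated.
#' @export
validate_annotations <- function(ann) {
  ann <- as_tibble(ann)
  need <- c("sample_id", "group", "recurrence")
  miss <- setdiff(need, names(ann))
  if (length(miss)) abort(paste0("Annotation table lacks columns: ", paste(miss, collapse = ", ")))
  ann$sample_id <- as.character(ann$sample_id)
  if (anyDuplicated(ann$sample_id)) abort("Duplicate sample_id in annotations.")
  bad <- setdiff(unique(ann$group), EV_GROUPS)
  if (length(bad)) abort(paste0("Unknown group levels: ", paste(bad, collapse = ", ")))
  rec_levels <- c("none", "early", "late", "not_applicable")
  bad <- setdiff(unique(ann$recurrence), rec_levels)
  if (length(bad)) abort(paste0("Unknown recurrence levels: ", paste(bad, collapse = ", ")))
  hc <- ann$group == "HC"
  if (any(hc & ann$recurrence != "not_applicable")) {
    abort("Healthy controls must have recurrence == 'not_applicable'.")
  }
  for (col in c("rfs_time", "rfs_event", "os_time", "os_event")) {
    if (col %in% names(ann) && any(hc & !is.na(ann[[col]]))) {
      abort(paste0("Healthy controls must not carry survival field '", col, "'."))
    }
  }
  if (all(c("rfs_time", "os_time") %in% names(ann))) {
    both <- !is.na(ann$rfs_time) & !is.na(ann$os_time)
    if (any(both & ann$rfs_time > ann$os_time + 1e-9)) {
      abort("rfs_time must not exceed os_time.")
    }
  }
  ann
}

#' Load a matched intensity matrix and annotation table
#'
#' Reads both files, validates them jointly, and reorders the annotations to
#' match the matrix column order. Every matrix sample must have exactly one
#' annotation row; offenders on either side are named in the error.
#'
#' @param matrix_path Path to the intensity matrix file.
#' @param annotation_path Path to the annotation file.
#' @param scale Scale tag for the matrix (`"log2"` default).
#' @return A list with elements `intensity` ([ev_intensity]) and
#'   `annotations` (tibble, ordered as the matrix columns).
#' @export
load_dataset <- function(matrix_path, annotation_path, scale = "log2") {
  x <- read_intensity(matrix_path, scale = scale)
  ann <- read_annotations(annotation_path)
  ids <- sample_ids(x)
  missing_ann <- setdiff(ids, ann$sample_id)
  if (length(missing_ann)) {
    abort(paste0("Samples without annotation: ", paste(missing_ann, collapse = ", ")))
  }
  extra <- setdiff(ann$sample_id, ids)
  if (length(extra)) {
    abort(paste0("Annotated samples absent from matrix: ", paste(extra, collapse = ", ")))
  }
  list(intensity = x, annotations = ann[match(ids, ann$sample_id), ])
}

#' Derive the four-class clinical label for each sample
#'
#' Healthy controls map to `Normal`; TNBC patients split by recurrence into
#' `TNBC_recur` (early or late recurrence) and `TNBC_no_recur`; luminal and
#' HER2 patients map to `OtherSubtype` regardless of recurrence. Recurrence
#' timing stays available in the annotations for survival analysis.
#'
#' @param ann An annotation tibble (see [read_annotations]).
#' @return The annotations with a `class` factor column appended
#'   (levels Normal, OtherSubtype, TNBC_no_recur, TNBC_recur).
#' @export
derive_four_class <- function(ann) {
  ann <- validate_annotations(ann)
  cls <- dplyr::case_when(
    ann$group == "HC" ~ "Normal",
    ann$group %in% c("Luminal", "HER2") ~ "OtherSubtype",
    ann$group == "TNBC" & ann$recurrence %in% c("early", "late") ~ "TNBC_recur",
    ann$group == "TNBC" & ann$recurrence == "none" ~ "TNBC_no_recur"
  )
  if (anyNA(cls)) {
    bad <- ann$sample_id[is.na(cls)]
    abort(paste0("Cannot derive class for samples: ", paste(bad, collapse = ", ")))
  }
  dplyr::mutate(ann, class = factor(cls, levels = EV_CLASSES))
}
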