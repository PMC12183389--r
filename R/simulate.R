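#' Default planted marker effects
#'
#' The four signature proteins (ECM1, MBL2, BTD, RAB5C) with cancer-class
#' log2 shifts anchored to their reported linear fold changes versus healthy
#' controls (2.238, 6.665, 2.337, 5.913). The TNBC-without-recurrence class
#' carries the anchor shift; the other cancer classes are scaled to reflect
#' the qualitative subtype pattern (luminal/HER2 weaker overall; MBL2 lower
#' and BTD/RAB5C higher in recurrent TNBC). Normal is 0 by convention.
#'
#' @return A tibble with columns `protein` and one log2-shift column per
#'   cancer class.
#' @export
planted_effects_default <- function() {
  anchor <- c(ECM1 = log2(2.238), MBL2 = log2(6.665), BTD = log2(2.337), RAB5C = log2(5.913))
  mult <- rbind( # OtherSubtype, TNBC_no_recur, TNBC_recur
    ECM1  = c(0.5, 1.0, 1.5),
    MBL2  = c(0.5, 1.0, 0.4),
    BTD   = c(0.4, 1.0, 1.6),
    RAB5C = c(1.0, 0.6, 1.3)
  )
  tibble(
    protein = names(anchor),
    OtherSubtype = anchor * mult[, 1L],
    TNBC_no_recur = anchor * mult[, 2L],
    TNBC_recur = anchor * mult[, 3L]
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the processed study matrix: 985 proteins x 130 samples
#' with classes 30 Normal / 57 other subtype / 26 TNBC without recurrence /
#' 17 TNBC with recurrence (the 26/17 split of the 43 TNBC patients follows
#' the validation set's recurrence proportion), log2-Gaussian intensities
#' around a baseline of 20 log2 units, 10% missing-completely-at-random
#' cells, and the four planted signature markers of
#' [planted_effects_default()].
#'
#' @param n_per_class Named integer vector of samples per class
#'   (names Normal, OtherSubtype, TNBC_no_recur, TNBC_recur).
#' @param n_proteins Total proteins simulated (planted markers included).
#' @param planted Tibble as returned by [planted_effects_default()]: column
#'   `protein` plus one additive log2-shift column per non-Normal class.
#' @param baseline_mean,baseline_sd Mean and SD (log2 units) of unplanted
#'   protein intensities; `baseline_sd` must be positive.
#' @param marker_sd SD (log2 units) of planted marker intensities.
#' @param missing_rate Per-cell missingness probability in `[0, 1)`.
#' @param missing_mode `"mcar"` (default) or `"intensity"`: in intensity mode
#'   missingness concentrates on cells below the per-protein mean, emulating
#'   abundance-dependent dropout at the same overall rate.
#' @param survival_true_hr True hazard ratio applied to high-score samples by
#'   [simulate_survival()].
#' @param censor_rate Target censoring fraction in `[0, 1)`.
#' @param seed Integer seed; every generator draw derives from it.
#' @return A list of class `ev_sim_config`.
#' @export
sim_config <- function(n_per_class = c(Normal = 30, OtherSubtype = 57,
                                       TNBC_no_recur = 26, TNBC_recur = 17),
                       n_proteins = 985,
                       planted = planted_effects_default(),
                       baseline_mean = 20, baseline_sd = 1,
                       marker_sd = 0.8,
                       missing_rate = 0.1,
                       missing_mode = c("mcar", "intensity"),
                       survival_true_hr = 4.8,
                       censor_rate = 0.2,
                       seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  if (!all(EV_CLASSES %in% names(n_per_class))) {
    abort(paste0("n_per_class must name all classes: ", paste(EV_CLASSES, collapse = ", ")))
  }
  if (any(n_per_class < 1)) abort("Each class needs >= 1 sample.")
  if (baseline_sd <= 0 || marker_sd <= 0) abort("Standard deviations must be > 0.")
  if (missing_rate < 0 || missing_rate >= 1) abort("missing_rate must be in [0, 1).")
  if (censor_rate < 0 || censor_rate >= 1) abort("censor_rate must be in [0, 1).")
  if (survival_true_hr <= 0) abort("survival_true_hr must be > 0.")
  if (!is.null(planted) && nrow(planted) > n_proteins) {
    abort("More planted markers than proteins.")
  }
  structure(
    list(
      n_per_class = n_per_class[EV_CLASSES], n_proteins = as.integer(n_proteins),
      planted = planted, baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      marker_sd = marker_sd, missing_rate = missing_rate, missing_mode = missing_mode,
      survival_true_hr = survival_true_hr, censor_rate = censor_rate,
      seed = as.integer(seed)
    ),
    class = "ev_sim_config"
  )
}

# Protein id universe: planted marker names plus zero-padded fillers.
sim_protein_ids <- function(config) {
  planted_ids <- if (is.null(config$planted)) character() else config$planted$protein
  n_fill <- config$n_proteins - length(planted_ids)
  if (n_fill < 0) abort("More planted markers than proteins.")
  fill <- sprintf("PROT%04d", seq_len(max(n_fill, 0L)))
  c(planted_ids, fill)
}

#' Generate a synthetic EV proteome cohort
#'
#' Draws log2 intensities entry-wise from
#' `Normal(baseline_mean + shift(protein, class), sd(protein))`, where the
#' shift is zero except for planted markers in cancer classes and the SD is
#' `marker_sd` for planted markers and `baseline_sd` otherwise. Cells are
#' then masked missing at `missing_rate`. Identical configs (including seed)
#' give bit-identical output.
#'
#' @param config An [sim_config()] object.
#' @return A list with `intensity` ([ev_intensity], log2 scale),
#'   `annotations` (tibble with `class` column) and `truth` (planted effect
#'   table).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "ev_sim_config"))
  withr::local_seed(config$seed)
  prot <- sim_protein_ids(config)
  n <- config$n_per_class
  classes <- factor(rep(EV_CLASSES, times = n[EV_CLASSES]), levels = EV_CLASSES)
  n_smp <- length(classes)
  smp <- sprintf("S%03d", seq_len(n_smp))

  shift <- matrix(0, nrow = length(prot), ncol = length(EV_CLASSES),
                  dimnames = list(prot, EV_CLASSES))
  sds <- rep(config$baseline_sd, length(prot))
  names(sds) <- prot
  if (!is.null(config$planted) && nrow(config$planted)) {
    pl <- config$planted
    if (anyDuplicated(pl$protein)) abort("Duplicate planted protein ids.")
    missing_ids <- setdiff(pl$protein, prot)
    if (length(missing_ids)) {
      abort(paste0("Planted ids not among generated proteins: ",
                   paste(missing_ids, collapse = ", ")))
    }
    for (cls in setdiff(names(pl), "protein")) {
      shift[pl$protein, cls] <- pl[[cls]]
    }
    sds[pl$protein] <- config$marker_sd
  }

  mu <- config$baseline_mean + shift[, as.integer(classes), drop = FALSE]
  vals <- mu + matrix(rnorm(length(prot) * n_smp, sd = rep(sds, n_smp)),
                      nrow = length(prot))
  dimnames(vals) <- list(prot, smp)

  if (config$missing_rate > 0) {
    if (config$missing_mode == "mcar") {
      mask <- matrix(runif(length(vals)) < config$missing_rate, nrow = nrow(vals))
    } else {
      # abundance-dependent: cells below the protein mean are 3x as likely to
      # drop out, scaled so the expected overall rate stays missing_rate
      below <- sweep(vals, 1L, rowMeans(vals), `<`)
      p_lo <- 1.5 * config$missing_rate
      p_hi <- 0.5 * config$missing_rate
      pm <- ifelse(below, p_lo, p_hi)
      mask <- matrix(runif(length(vals)) < pm, nrow = nrow(vals))
    }
    vals[mask] <- NA_real_
  }

  ann <- tibble(
    sample_id = smp,
    group = dplyr::case_when(
      classes == "Normal" ~ "HC",
      classes == "OtherSubtype" ~ rep_len(c("Luminal", "HER2"), n_smp),
      TRUE ~ "TNBC"
    ),
    recurrence = dplyr::case_when(
      classes == "Normal" ~ "not_applicable",
      classes == "TNBC_recur" ~ rep_len(c("early", "late"), n_smp),
      TRUE ~ "none"
    ),
    class = classes
  )
  list(
    intensity = matrix_to_intensity(vals, scale = "log2"),
    annotations = ann,
    truth = config$planted
  )
}

#' Attach score-linked survival outcomes to annotated samples
#'
#' Event times follow an exponential model whose hazard is multiplied by
#' `config$survival_true_hr` for samples with risk score above 0.5 (the
#' recurrence-risk rule used downstream). Overall survival is relapse-free
#' survival plus an independent exponential post-recurrence time, so
#' `rfs_time <= os_time` holds by construction; one shared exponential
#' censoring time per subject is calibrated to `config$censor_rate`.
#' Healthy controls receive no survival fields.
#'
#' @param ann Annotation tibble.
#' @param risk_score Named numeric vector in `[0, 1]`, one entry per non-HC
#'   sample (names = sample ids).
#' @param config An [sim_config()] object (uses `survival_true_hr`,
#'   `censor_rate`, `seed`).
#' @param base_hazard Baseline RFS hazard per month for low-risk samples
#'   (default `log(2)/60`: five-year median relapse-free survival).
#' @return `ann` with `rfs_time`, `rfs_event`, `os_time`, `os_event` columns.
#' @export
simulate_survival <- function(ann, risk_score, config = sim_config(),
                              base_hazard = log(2) / 60) {
  ann <- as_tibble(ann)
  case <- ann$group != "HC"
  ids <- ann$sample_id[case]
  missing_scores <- setdiff(ids, names(risk_score))
  if (length(missing_scores)) {
    abort(paste0("No risk score for samples: ", paste(missing_scores, collapse = ", ")))
  }
  s <- risk_score[ids]
  if (any(s < 0 | s > 1)) abort("Risk scores must lie in [0, 1].")
  withr::local_seed(config$seed + 211L)
  n <- length(ids)
  high <- s > 0.5
  hz <- base_hazard * ifelse(high, config$survival_true_hr, 1)
  t_rfs <- rexp(n, rate = hz)
  t_os <- t_rfs + rexp(n, rate = base_hazard * 2) # post-recurrence survival
  # censoring rate c for exponential event/censor pair: hc = h * c / (1 - c)
  cr <- config$censor_rate
  if (cr > 0) {
    hc <- mean(hz) * cr / (1 - cr)
    cens <- rexp(n, rate = hc)
  } else {
    cens <- rep(Inf, n)
  }
  out <- ann
  for (col in c("rfs_time", "rfs_event", "os_time", "os_event")) out[[col]] <- NA_real_
  out$rfs_time[case] <- pmin(t_rfs, cens)
  out$rfs_event[case] <- as.numeric(t_rfs <= cens)
  out$os_time[case] <- pmin(t_os, cens)
  out$os_event[case] <- as.numeric(t_os <= cens)
  out
}

#' Generate an ELISA-style marker concentration panel
#'
#' Log-normal plasma concentrations (pg/mL, linear scale) for a small marker
#' panel measured in a control and a case group; case medians are the control
#' median times the requested fold change. Defaults mirror a 10-control /
#' 30-case validation cohort.
#'
#' @param n_control,n_case Group sizes (positive integers).
#' @param fold_changes Named positive numeric vector: case/control median
#'   fold change per marker.
#' @param median_control Control-group median concentration in pg/mL.
#' @param cv_log Log-scale SD of concentrations (default 0.5, a typical
#'   immunoassay between-subject spread).
#' @param seed Integer seed.
#' @return A tibble with `sample_id`, `group` (`control`/`case`) and one
#'   concentration column per marker.
#' @export
simulate_elisa <- function(n_control = 10, n_case = 30,
                           fold_changes = c(ECM1 = 2.238, MBL2 = 6.665,
                                            BTD = 2.337, RAB5C = 5.913),
                           median_control = 1000, cv_log = 0.5, seed = 1L) {
  if (n_control < 1 || n_case < 1) abort("Group sizes must be positive.")
  if (any(fold_changes <= 0)) abort("Fold changes must be > 0.")
  withr::local_seed(as.integer(seed) + 977L)
  n <- n_control + n_case
  grp <- rep(c("control", "case"), c(n_control, n_case))
  cols <- lapply(names(fold_changes), function(mk) {
    mu <- log(median_control) + ifelse(grp == "case", log(fold_changes[[mk]]), 0)
    exp(rnorm(n, mean = mu, sd = cv_log))
  })
  names(cols) <- names(fold_changes)
  tibble(sample_id = sprintf("E%03d", seq_len(n)), group = grp, !!!cols)
}
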