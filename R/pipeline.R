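pipeline_defaults <- function() {
  list(
    seed = 1L,
    simulate = list(),             # sim_config() overrides, or NULL when input given
    input = NULL,                  # list(matrix = path, annotations = path)
    preprocess = list(min_individuals = 10, min_group_presence = 0.7,
                      impute = "median"),
    dep = list(group_a = "cancer", group_b = "HC", p = 0.05, log2fc = 1),
    rank = list(k = 10, iterations = 50, learners = 100, learning_rate = 0.1),
    classify = list(markers = "top4", cnn = list(), svm_cost = 1),
    score = list(candidates = "top4", exclusion_p = 0.1),
    evaluate = list(fixed_specificity = 0.95, n_boot = 2000),
    survival = list(cutoff = 0.5, endpoints = c("rfs", "os"))
  )
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

write_stage_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the full biomarker-discovery pipeline
#'
#' Orchestrates all stages under one seeded configuration: cohort simulation
#' (or loading), presence filtering and imputation, volcano differential
#' expression, LSBoost RMSE ranking, hybrid CNN-SVM classification,
#' marker-combination logistic scoring, ROC evaluation at fixed specificity,
#' and score-stratified survival analysis. Every stage writes its artifact
#' into `out_dir`; a manifest records outputs, the configuration digest and
#' per-stage timings. Identical config + seed reproduce identical outputs.
#' Paper-default thresholds are the config defaults (p = 0.05, |log2 FC| > 1,
#' presence > 0.7, min 10 individuals, 70/30 split, 50 ranking iterations,
#' top 10 markers, exclusion p 0.1, fixed specificity 0.95, risk cutoff 0.5).
#'
#' @param config A YAML file path or nested list overriding the defaults
#'   (see `evsig:::pipeline_defaults()`); `NULL` runs the default synthetic
#'   cohort.
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides `config$seed` when given.
#' @return The run manifest (list): `seed`, `config_digest`, `stage_outputs`,
#'   `timings`, plus in-memory stage results in `results`. On stage failure
#'   the manifest (with the failing stage's error) is written before the
#'   error propagates.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("evsig_run_"),
                         seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(pipeline_defaults(), config %||% list())
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  digest <- rlang::hash(cfg)
  stage_seed <- function(i) (cfg$seed * 131L + i * 7919L) %% 2147483647L

  manifest <- list(config_digest = digest, seed = cfg$seed,
                   stage_outputs = list(), timings = list(),
                   versions = list(evsig = as.character(utils::packageVersion("evsig"))))
  results <- list()
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fn(), error = function(e) {
      manifest$error <<- list(stage = name, message = conditionMessage(e))
      write_stage_json(manifest[setdiff(names(manifest), "results")],
                       file.path(out_dir, "manifest.json"))
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    manifest$stage_outputs[[name]] <<- basename(out$path)
    results[[name]] <<- out$value
  }

  # -- data ------------------------------------------------------------
  run_stage("simulate", function() {
    if (!is.null(cfg$input)) {
      ds <- load_dataset(cfg$input$matrix, cfg$input$annotations)
      ds$annotations <- derive_four_class(ds$annotations)
      path <- file.path(out_dir, "dataset_source.json")
      write_stage_json(list(matrix = cfg$input$matrix,
                            annotations = cfg$input$annotations), path)
    } else {
      sim_args <- cfg$simulate %||% list()
      sim_args$seed <- sim_args$seed %||% stage_seed(1L)
      ds <- simulate_cohort(do.call(sim_config, sim_args))
      path <- file.path(out_dir, "matrix.tsv")
      write_intensity(ds$intensity, path)
      readr::write_tsv(ds$annotations, file.path(out_dir, "annotations.tsv"))
      if (!is.null(ds$truth)) readr::write_tsv(ds$truth, file.path(out_dir, "truth.tsv"))
    }
    list(path = path, value = ds)
  })
  ds <- results$simulate

  run_stage("preprocess", function() {
    pp <- cfg$preprocess
    x <- ds$intensity
    if (intensity_scale(x) == "linear") x <- normalize_log2(x)
    x <- filter_min_individuals(x, ds$annotations, min_n = pp$min_individuals)
    x <- filter_group_presence(x, ds$annotations, min_fraction = pp$min_group_presence)
    report <- filter_report(x)
    imputed <- if (identical(pp$impute, "median")) impute_median(x) else x
    path <- file.path(out_dir, "filtered_matrix.tsv")
    write_intensity(x, path)
    readr::write_tsv(report$per_group, file.path(out_dir, "presence_report.tsv"))
    list(path = path, value = list(filtered = x, imputed = imputed, report = report))
  })
  filt <- results$preprocess

  run_stage("dep", function() {
    v <- volcano_select(filt$filtered, ds$annotations,
                        group_a = cfg$dep$group_a, group_b = cfg$dep$group_b,
                        p_thresh = cfg$dep$p, fc_log2_thresh = cfg$dep$log2fc)
    path <- file.path(out_dir, "volcano.tsv")
    readr::write_tsv(as_tibble(v), path)
    list(path = path, value = v)
  })

  cls <- ds$annotations$class %||% derive_four_class(ds$annotations)$class

  run_stage("rank", function() {
    rk <- rank_biomarkers(filt$imputed, cls, k = cfg$rank$k,
                          n_iterations = cfg$rank$iterations,
                          n_learners = cfg$rank$learners,
                          learning_rate = cfg$rank$learning_rate,
                          seed = stage_seed(2L))
    path <- file.path(out_dir, "ranking.tsv")
    readr::write_tsv(rk$per_biomarker, path)
    list(path = path, value = rk)
  })
  rk <- results$rank

  run_stage("classify", function() {
    subset <- switch(as.character(cfg$classify$markers[1L]),
      full = NULL,
      top4 = top_markers(rk, 4L),
      topk = top_markers(rk, cfg$rank$k),
      cfg$classify$markers
    )
    hy <- train_hybrid(filt$imputed, cls, marker_subset = subset,
                       cnn = cfg$classify$cnn, svm_cost = cfg$classify$svm_cost,
                       seed = stage_seed(3L))
    path <- file.path(out_dir, "classification.json")
    write_stage_json(list(
      extractor = hy$extractor,
      test = list(accuracy = hy$report_test$accuracy,
                  macro_accuracy = hy$report_test$macro_accuracy,
                  confusion = as.data.frame(hy$report_test$confusion),
                  metrics = hy$report_test$metrics),
      train = list(accuracy = hy$report_train$accuracy)
    ), path)
    list(path = path, value = hy)
  })

  m_imp <- as_matrix(filt$imputed)
  cancer <- cls != "Normal"

  run_stage("score", function() {
    cand <- if (identical(cfg$score$candidates, "top4")) {
      top_markers(rk, 4L)
    } else if (identical(cfg$score$candidates, "topk")) {
      top_markers(rk, min(cfg$rank$k, 10L))
    } else cfg$score$candidates
    combos <- evaluate_combinations(t(m_imp), cancer, candidates = cand,
                                    exclusion_p = cfg$score$exclusion_p)
    model <- fit_marker_score(t(m_imp)[, best_combination(combos), drop = FALSE],
                              cancer, exclusion_p = cfg$score$exclusion_p)
    scores <- score_samples(model, t(m_imp))
    path <- file.path(out_dir, "combinations.tsv")
    readr::write_tsv(dplyr::select(as_tibble(combos), -"markers"), path)
    write_stage_json(list(markers = model$markers,
                          intercept = model$intercept,
                          coefficients = as.list(model$coefficients),
                          scale = model$scale), file.path(out_dir, "score_model.json"))
    readr::write_tsv(tibble(sample_id = names(scores), score = unname(scores)),
                     file.path(out_dir, "scores.tsv"))
    list(path = path, value = list(combos = combos, model = model, scores = scores))
  })
  sc <- results$score

  run_stage("evaluate", function() {
    roc <- roc_auc(sc$scores, cancer)
    sens <- sensitivity_at_specificity(roc, cfg$evaluate$fixed_specificity,
                                       n_boot = cfg$evaluate$n_boot,
                                       seed = stage_seed(4L))
    path <- file.path(out_dir, "evaluation.json")
    write_stage_json(list(
      best_panel = paste(best_combination(sc$combos), collapse = "+"),
      auc = roc$auc, auc_se = roc$auc_se, auc_ci95 = roc$ci95,
      sensitivity_at_fixed_specificity = as.list(sens)
    ), path)
    list(path = path, value = list(roc = roc, sensitivity = sens))
  })

  run_stage("survival", function() {
    ann <- ds$annotations
    if (!("rfs_time" %in% names(ann)) || all(is.na(ann$rfs_time))) {
      sim_args <- cfg$simulate %||% list()
      sim_args$seed <- sim_args$seed %||% stage_seed(1L)
      ann <- simulate_survival(ann, sc$scores[ann$sample_id[ann$group != "HC"]],
                               do.call(sim_config, sim_args))
    }
    res <- lapply(cfg$survival$endpoints, function(ep) {
      sv <- survival_by_score(ann, sc$scores, endpoint = ep,
                              cutoff = cfg$survival$cutoff)
      list(endpoint = ep, cutoff = sv$cutoff, cutoff_rule = sv$cutoff_rule,
           hazard_ratio = sv$cox$hazard_ratio,
           hr_ci95 = c(sv$cox$ci_lo, sv$cox$ci_hi), cox_p = sv$cox$p_value,
           logrank_chi2 = if (is.null(sv$km)) NA_real_ else sv$km$logrank_chi2,
           logrank_p = if (is.null(sv$km)) NA_real_ else sv$km$logrank_p)
    })
    names(res) <- cfg$survival$endpoints
    path <- file.path(out_dir, "survival.json")
    write_stage_json(res, path)
    list(path = path, value = res)
  })

  manifest$results <- results
  write_stage_json(manifest[setdiff(names(manifest), c("results", "timings"))],
                   file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
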