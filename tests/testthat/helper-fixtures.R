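# small constructors used across the unit tests

tiny_intensity <- function(values, proteins = NULL, samples = NULL,
                           scale = "log2") {
  proteins <- proteins %||% sprintf("P%02d", seq_len(nrow(values)))
  samples <- samples %||% sprintf("S%02d", seq_len(ncol(values)))
  colnames(values) <- samples
  ev_intensity(tibble::tibble(protein = proteins,
                              tibble::as_tibble(values, .name_repair = "minimal")),
               scale = scale)
}

tiny_annotations <- function(groups, recurrence = NULL) {
  n <- length(groups)
  recurrence <- recurrence %||% ifelse(groups == "HC", "not_applicable", "none")
  tibble::tibble(sample_id = sprintf("S%02d", seq_len(n)),
                 group = groups, recurrence = recurrence)
}

small_sim_config <- function(..., n_proteins = 40, seed = 1L) {
  sim_config(n_per_class = c(Normal = 12, OtherSubtype = 14,
                             TNBC_no_recur = 10, TNBC_recur = 8),
             n_proteins = n_proteins, seed = seed, ...)
}

`%||%` <- rlang::`%||%`
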