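#' Published 26-protein breast-cancer signature statistics
#'
#' The reported per-protein Welch p values and linear fold changes of the 26
#' plasma-EV proteins that distinguish breast-cancer patients from healthy
#' controls, as printed in the source study's marker table. Useful as a
#' worked example for [dep_rule()].
#'
#' @return A tibble with columns `protein`, `uniprot`, `p_value`,
#'   `fold_change`.
#' @export
bc_signature_table <- function() {
  path <- system.file("extdata", "bc_signature_26.tsv", package = "evsig",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
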