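#' Write or read ensemble predictions
#'
#' Predictions round-trip losslessly: values are written with full
#' precision and re-read within 1e-10.
#'
#' @param preds Tibble from [ensemble_predict()] (non-empty).
#' @param path Destination CSV path.
#' @return `write_predictions()` returns `path` invisibly;
#'   `read_predictions()` returns the tibble.
#' @export
write_predictions <- function(preds, path) {
  if (nrow(preds) == 0) rlang::abort("refusing to write an empty prediction set")
  cols <- c("id", "smiles", "mu_ens", "sigma2_ale", "sigma2_epi", "sigma2_total")
  missing_cols <- setdiff(cols, names(preds))
  if (length(missing_cols)) {
    rlang::abort(paste("missing prediction columns:", paste(missing_cols, collapse = ", ")))
  }
  readr::write_csv(preds[cols], path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write per-atom attributions to a long-format CSV
#'
#' One row per atom: `id`, `atom_index` (0-based, in featurization atom
#' order), `element`, `mu_atom`, `sigma2_ale_atom`, `sigma2_epi_atom`.
#' Molecule-mode predictions carry no atomic detail and are rejected.
#'
#' @param preds Tibble from [ensemble_predict()] in atom mode (with an
#'   `atoms` list-column).
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_atomic_attributions <- function(preds, path) {
  if (nrow(preds) == 0) rlang::abort("refusing to write an empty prediction set")
  if (!"atoms" %in% names(preds)) {
    rlang::abort("predictions carry no atomic decomposition (molecule-based mode is unsupported here)")
  }
  long <- preds |>
    dplyr::select("id", "atoms") |>
    tidyr::unnest("atoms")
  readr::write_csv(long, path)
  invisible(path)
}

#' @rdname write_atomic_attributions
#' @export
read_atomic_attributions <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
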