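#' Write a synthetic panel to plain-text files
#'
#' Writes the wave-level records CSV, the latent-truth sidecar CSV (annual
#' states, for oracle checks) and a YAML file with the scalar fields of the
#' generating specification.
#'
#' @param panel list with `records` and `truth` as from [simulate_panel()].
#' @param dir output directory (created if needed).
#' @param spec the "panel_spec" used (optional; written as YAML when given).
#' @return invisibly, the paths written.
#' @export
write_panel_csv <- function(panel, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_rec <- file.path(dir, "wave_records.csv")
  p_truth <- file.path(dir, "latent_truth.csv")
  utils::write.csv(panel$records, p_rec, row.names = FALSE, na = "")
  utils::write.csv(panel$truth$paths, p_truth, row.names = FALSE, na = "")
  paths <- c(records = p_rec, truth = p_truth)
  if (!is.null(spec)) {
    p_spec <- file.path(dir, "panel_spec.yaml")
    scal <- list(
      n_subjects = spec$n_subjects, sex_ratio = spec$sex_ratio,
      n_villages = spec$n_villages, n_regions = spec$n_regions,
      wave_years = as.list(spec$wave_years),
      too_ill_prob = spec$too_ill_prob, age_cap = spec$age_cap,
      seed = spec$seed,
      attrition = as.list(spec$attrition)
    )
    yaml::write_yaml(scal, p_spec)
    paths <- c(paths, spec = p_spec)
  }
  invisible(paths)
}

#' Read wave-level records written by [write_panel_csv()]
#'
#' @param path path to the wave_records.csv file.
#' @return wave-level records data frame (items as character labels).
#' @export
read_panel_csv <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  rec$too_ill <- as.logical(rec$too_ill)
  rec
}

#' Write a health-expectancy table to CSV
#'
#' @param he a "he_table".
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_he_csv <- function(he, path) {
  utils::write.csv(as.data.frame(he), path, row.names = FALSE, na = "")
  invisible(path)
}
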