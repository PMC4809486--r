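#' Write a simulated population to delimited text with JSON metadata
#'
#' Writes the dataset as CSV (columns `id`, `x`, optionally `z`, `y`; `y`
#' blank where missing) plus a JSON sidecar `<path>.json` recording the
#' design (scenario, kind, factor values) and, for complete data, the
#' unrestricted sample statistics.
#'
#' @param data A population or restricted sample tibble.
#' @param path Output CSV path.
#' @param seed Optional seed to record in the metadata.
#' @return `path`, invisibly.
#' @export
write_population <- function(data, path, seed = NULL) {
  cols <- intersect(c("x", "z", "y"), names(data))
  out <- dplyr::bind_cols(tibble(id = seq_len(nrow(data))), data[cols])
  readr::write_csv(out, path, na = "")
  meta <- list(
    scenario = attr(data, "scenario"),
    kind = attr(data, "kind"),
    factors = attr(data, "factors"),
    sr = attr(data, "sr"),
    seed = seed,
    n = nrow(data)
  )
  if (!anyNA(data$y)) {
    meta$true_params <- as.list(true_params(data, attr(data, "kind"),
                                            attr(data, "scenario")))
  }
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a population written by [write_population()]
#'
#' Restores the CSV and, when the JSON sidecar is present, the `scenario`,
#' `kind`, `factors` and `sr` attributes.
#'
#' @param path CSV path.
#' @return A tibble with columns `x`, optionally `z`, and `y` (integer with
#'   `NA` for missing).
#' @export
read_population <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  data$y <- as.integer(data$y)
  data$id <- NULL
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(data, "scenario") <- meta$scenario
    attr(data, "kind") <- meta$kind
    attr(data, "factors") <- meta$factors
    attr(data, "sr") <- meta$sr
  }
  data
}
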