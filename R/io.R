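#' Read a compound table from CSV
#'
#' Expects a comma-separated, UTF-8 file with a header row. Column names are
#' matched liberally (`half_life` / `half_life_days`, `mec` /
#' `mec_ng_per_l`, ...); unknown columns are ignored for validation but do
#' not fail the read. Numeric cells may use plain (`14800`), scientific
#' (`1.48e4`) or typeset (`1.48 × 10^4^`) notation, and concentrations may
#' carry explicit `ug/L` / `mg/L` unit suffixes. Invalid rows are reported
#' with their row number in the `"problems"` attribute and excluded from the
#' returned records.
#'
#' @param path Path to the CSV file.
#' @param medium_default Medium used for rows without a `medium` column.
#' @param warn_cas Warn on malformed CAS strings.
#' @return A tibble of validated compound records (see [validate_record()])
#'   with attribute `"problems"`.
#'
#' @section Errors: unreadable file, `io-error`; a header missing the
#'   required columns, `schema-error`.
#' @examples
#' path <- system.file("extdata", "ebro_pesticides.csv", package = "srftox")
#' read_compound_table(path)
#' @export
read_compound_table <- function(path, medium_default = "water",
                                warn_cas = TRUE) {
  if (!file.exists(path)) {
    abort_srftox("io-error", sprintf("cannot read '%s': no such file", path))
  }
  raw <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) abort_srftox("io-error",
                                     sprintf("cannot read '%s': %s", path,
                                             conditionMessage(e))))
  names(raw) <- normalise_field_names(names(raw))
  required <- c("name", "half_life_days", "mec_ng_per_l")
  missing_cols <- setdiff(required, names(raw))
  has_tox <- "pnec_ng_per_l" %in% names(raw) ||
    all(c("endpoint_kind", "endpoint_value_ng_per_l") %in% names(raw))
  if (length(missing_cols) > 0 || !has_tox) {
    abort_srftox("schema-error",
                 sprintf("'%s' is missing required columns: %s", path,
                         paste(c(missing_cols,
                                 if (!has_tox) "pnec_ng_per_l or endpoint_kind+endpoint_value_ng_per_l"),
                               collapse = ", ")))
  }
  validate_compounds(raw, medium_default = medium_default, warn_cas = warn_cas)
}

results_columns <- c("name", "cas", "c", "pnec_ng_per_l", "rq", "srf",
                     "rq_class", "srf_class", "reclassified", "direction")

#' Write assessment results to CSV or JSON
#'
#' Numeric columns (`c`, `pnec_ng_per_l`, `rq`, `srf`) are written in full
#' precision, each with a formatted twin (`*_fmt`) at 4 significant figures
#' for human readers. JSON output is an array of flat objects with the same
#' keys; full-precision numbers survive a JSON round-trip bit-identically.
#'
#' @param results An `srf_assessment` (or compatible data frame).
#' @param path Output file path.
#' @param format `"csv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @examples
#' res <- srf_assess(srf_fixture("ebro_pesticides"))
#' write_results(res, file.path(tempdir(), "ebro.csv"))
#' @export
write_results <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results), nrow(results) > 0)
  out <- tibble::as_tibble(results) |>
    dplyr::select(dplyr::all_of(results_columns)) |>
    dplyr::mutate(
      dplyr::across(dplyr::all_of(c("rq_class", "srf_class")), as.character),
      c_fmt = signif(.data$c, 4),
      pnec_fmt = signif(.data$pnec_ng_per_l, 4),
      rq_fmt = signif(.data$rq, 4),
      srf_fmt = signif(.data$srf, 4))
  ok <- tryCatch({
    if (format == "csv") {
      readr::write_csv(out, path, progress = FALSE)
    } else {
      jsonlite::write_json(out, path, dataframe = "rows", digits = I(17),
                           na = "null", auto_unbox = TRUE)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort_srftox("io-error",
                 sprintf("cannot write '%s': %s", path, conditionMessage(ok)))
  }
  invisible(path)
}

#' Read back a results file written by [write_results()]
#'
#' @param path Path to a results CSV or JSON.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return A tibble with the written columns; risk bands restored as ordered
#'   factors.
#' @export
read_results <- function(path, format = NULL) {
  if (!file.exists(path)) {
    abort_srftox("io-error", sprintf("cannot read '%s': no such file", path))
  }
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  out <- if (format == "json") {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  dplyr::mutate(out, dplyr::across(
    dplyr::any_of(c("rq_class", "srf_class")),
    ~ factor(.x, levels = risk_band_levels, ordered = TRUE)))
}
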