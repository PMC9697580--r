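#' Environmental persistence coefficient
#'
#' C = T_CV / T_1/2: the ratio of a medium's persistence boundary value to
#' the compound's half-life. C < 1 means the compound outlasts the boundary
#' value (more persistent, higher assessed risk under the SRF); C > 1 means
#' it degrades faster than the cut-off.
#'
#' @param half_life_days Positive half-life T_1/2 in days (vectorised).
#' @param t_cv_days Positive persistence boundary value T_CV in days
#'   (60 for water, 180 for soil/sediment under the defaults).
#' @return Dimensionless C at full floating precision.
#' @examples
#' persistence_coefficient(8, 60)    # 7.5
#' persistence_coefficient(151, 60)  # 0.397...
#' @export
persistence_coefficient <- function(half_life_days, t_cv_days) {
  half_life_days <- as.numeric(half_life_days)
  t_cv_days <- as.numeric(t_cv_days)
  if (any(!is.finite(half_life_days)) || any(half_life_days <= 0) ||
      any(!is.finite(t_cv_days)) || any(t_cv_days <= 0)) {
    abort_srftox("invalid-value",
                 "half-life and persistence boundary value must both be positive")
  }
  t_cv_days / half_life_days
}

#' Predicted no-effect concentration from a toxicity endpoint
#'
#' Divides an acute EC50/LC50 by 1000 or a chronic value (ChV) by 100 —
#' the standard assessment factors for screening-level aquatic risk.
#'
#' @param value_ng_per_l Positive endpoint concentration in ng/L (vectorised).
#' @param kind `"acute_ec50"`, `"acute_lc50"` or `"chronic_chv"`.
#' @param config An [srf_config()]; override to change assessment factors.
#' @return PNEC in ng/L.
#' @examples
#' pnec(1e6, "acute_ec50")   # 1000
#' pnec(100, "chronic_chv")  # 1
#' @export
pnec <- function(value_ng_per_l, kind, config = srf_config()) {
  value_ng_per_l <- as.numeric(value_ng_per_l)
  kind <- tolower(as.character(kind))
  if (any(!kind %in% endpoint_kinds)) {
    abort_srftox("invalid-value",
                 sprintf("endpoint kind must be one of %s",
                         paste(endpoint_kinds, collapse = ", ")))
  }
  if (any(!is.finite(value_ng_per_l)) || any(value_ng_per_l <= 0)) {
    abort_srftox("invalid-value", "endpoint value must be positive")
  }
  af <- ifelse(kind == "chronic_chv",
               config$assessment_factors[["chronic"]],
               config$assessment_factors[["acute"]])
  value_ng_per_l / af
}

#' Risk quotient
#'
#' RQ = MEC / PNEC: measured environmental concentration over predicted
#' no-effect concentration, the classical point-estimate risk screen.
#'
#' @param mec_ng_per_l Non-negative measured concentration in ng/L.
#' @param pnec_ng_per_l Positive PNEC in ng/L.
#' @return Dimensionless RQ.
#' @examples
#' risk_quotient(61.01, 92)  # 0.663...
#' @export
risk_quotient <- function(mec_ng_per_l, pnec_ng_per_l) {
  mec_ng_per_l <- as.numeric(mec_ng_per_l)
  pnec_ng_per_l <- as.numeric(pnec_ng_per_l)
  if (any(!is.finite(mec_ng_per_l)) || any(mec_ng_per_l < 0)) {
    abort_srftox("invalid-value", "MEC must be non-negative")
  }
  if (any(!is.finite(pnec_ng_per_l)) || any(pnec_ng_per_l <= 0)) {
    abort_srftox("invalid-value", "PNEC must be positive")
  }
  mec_ng_per_l / pnec_ng_per_l
}

#' Synthetic risk factor
#'
#' SRF (written F(R)) = MEC / (PNEC * C), identically RQ / C: the risk
#' quotient re-weighted by environmental persistence. Because
#' SRF / RQ = T_1/2 / T_CV, the SRF of a compound grows with its half-life
#' at fixed exposure and toxicity, and collapses to the RQ exactly when the
#' half-life equals the boundary value.
#'
#' @inheritParams risk_quotient
#' @param c Positive persistence coefficient from
#'   [persistence_coefficient()].
#' @return Dimensionless SRF.
#' @examples
#' synthetic_risk_factor(61.01, 92, 0.40)  # 1.657...
#' @export
synthetic_risk_factor <- function(mec_ng_per_l, pnec_ng_per_l, c) {
  c <- as.numeric(c)
  if (any(!is.finite(c)) || any(c <= 0)) {
    abort_srftox("invalid-value", "persistence coefficient must be positive")
  }
  risk_quotient(mec_ng_per_l, pnec_ng_per_l) / c
}

#' Classify an RQ or SRF value into a risk band
#'
#' Four ordered bands: value <= 0.01 is negligible (adverse effects
#' unlikely); up to 0.1, minimal; up to 1, medium; at or above 1, high.
#' Each interior boundary is assigned to the higher band (the protective
#' convention), except 0.01 which the band definition itself places in
#' negligible.
#'
#' @param value Non-negative RQ or SRF values (vectorised).
#' @return Ordered factor with levels
#'   `negligible < minimal < medium < high`.
#' @examples
#' classify_risk(c(0.005, 0.05, 0.1, 1.66))
#' @export
classify_risk <- function(value) {
  value <- as.numeric(value)
  if (any(!is.finite(value)) || any(value < 0)) {
    abort_srftox("invalid-value", "risk values must be non-negative")
  }
  band <- dplyr::case_when(
    value <= 0.01 ~ "negligible",
    value < 0.1   ~ "minimal",
    value < 1     ~ "medium",
    TRUE          ~ "high"
  )
  factor(band, levels = risk_band_levels, ordered = TRUE)
}

risk_band_levels <- c("negligible", "minimal", "medium", "high")

# Resolve the persistence coefficient used in the SRF. "full" recomputes
# T_CV/T_1/2 in full precision; "table" uses the printed/rounded C carried by
# a fixture (falling back to 2 significant figures), which reproduces the
# arithmetic of published tables at the cost of propagating rounding error.
resolve_c <- function(c_full, c_printed, rounding) {
  if (rounding == "full") {
    return(c_full)
  }
  dplyr::coalesce(c_printed, signif(c_full, 2))
}

#' Assess a compound table: RQ, SRF and risk bands
#'
#' The workhorse. For every row of a compound table it computes the
#' persistence coefficient C (from the half-life and the medium's boundary
#' value), the PNEC (passed through directly, or derived from a toxicity
#' endpoint with its assessment factor; a direct chronic value takes
#' precedence when both routes could apply), the risk quotient RQ, the
#' synthetic risk factor SRF = RQ/C, the risk band of each, and whether the
#' persistence weighting reclassified the compound (and in which direction).
#'
#' Rows failing validation are reported in the `"problems"` attribute, never
#' silently dropped; an input in which no row survives validation is an
#' error (`empty-after-validation`).
#'
#' @param data Data frame with one row per compound. Recognised columns
#'   (liberal matching): `name`, `cas`, `formula`, `half_life_days`,
#'   `medium`, `mec_ng_per_l`, and either `pnec_ng_per_l` or
#'   `endpoint_kind` + `endpoint_value_ng_per_l`; optional `c_printed`
#'   (rounded C as printed in a source table, used by `rounding = "table"`).
#' @param medium_default Medium assumed for rows without one (default
#'   `"water"`).
#' @param rounding `"full"` (default) computes the SRF with full-precision
#'   C; `"table"` uses the printed C (or C rounded to 2 significant
#'   figures), reproducing published-table arithmetic.
#' @param config An [srf_config()] with boundary values and assessment
#'   factors.
#' @param warn_cas Warn on malformed CAS strings.
#'
#' @return A tibble of class `srf_assessment`, one row per valid compound,
#'   with columns `name`, `cas`, `medium`, `half_life_days`, `t_cv_days`,
#'   `c`, `pnec_ng_per_l`, `mec_ng_per_l`, `rq`, `srf`, `rq_class`,
#'   `srf_class`, `reclassified`, `direction`. Attributes: `"problems"`
#'   (invalid rows), `"rounding"`.
#' @examples
#' srf_assess(srf_fixture("ebro_pesticides"))
#' @export
srf_assess <- function(data, medium_default = "water",
                       rounding = c("full", "table"),
                       config = srf_config(), warn_cas = TRUE) {
  rounding <- match.arg(rounding)
  records <- validate_compounds(data, medium_default = medium_default,
                                warn_cas = warn_cas)
  problems <- attr(records, "problems")
  if (nrow(records) == 0) {
    abort_srftox("empty-after-validation",
                 "no rows survived validation; see the problems report")
  }

  out <- records |>
    dplyr::mutate(
      t_cv_days = t_cv(.data$medium, config = config),
      c_full = persistence_coefficient(.data$half_life_days, .data$t_cv_days),
      c = resolve_c(.data$c_full, .data$c_printed, rounding),
      pnec_ng_per_l = dplyr::if_else(
        is.na(.data$pnec_ng_per_l),
        pnec(dplyr::coalesce(.data$endpoint_value_ng_per_l, 1),
             dplyr::coalesce(.data$endpoint_kind, "acute_ec50"),
             config = config),
        .data$pnec_ng_per_l),
      rq = risk_quotient(.data$mec_ng_per_l, .data$pnec_ng_per_l),
      srf = synthetic_risk_factor(.data$mec_ng_per_l, .data$pnec_ng_per_l,
                                  .data$c),
      rq_class = classify_risk(.data$rq),
      srf_class = classify_risk(.data$srf),
      reclassified = .data$rq_class != .data$srf_class,
      direction = dplyr::case_when(
        .data$srf_class > .data$rq_class ~ "up",
        .data$srf_class < .data$rq_class ~ "down",
        TRUE ~ "unchanged")
    ) |>
    dplyr::select(dplyr::all_of(c(
      "name", "cas", "formula", "medium", "half_life_days", "t_cv_days",
      "c", "pnec_ng_per_l", "mec_ng_per_l", "rq", "srf",
      "rq_class", "srf_class", "reclassified", "direction")))

  structure(out, problems = problems, rounding = rounding,
            class = c("srf_assessment", class(out)))
}

#' Summarise an assessment: band counts and reclassifications
#'
#' @param x An `srf_assessment` from [srf_assess()].
#' @return A list with `band_counts` (tibble: method, band, n),
#'   `n_reclassified`, `n_up`, `n_down`, and `reclassified` (the subset of
#'   rows whose band changed).
#' @examples
#' srf_summary(srf_assess(srf_fixture("ebro_pesticides")))
#' @export
srf_summary <- function(x) {
  stopifnot(inherits(x, "srf_assessment"))
  bands <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(x), dplyr::all_of(c("name", "rq_class", "srf_class"))),
    cols = dplyr::all_of(c("rq_class", "srf_class")),
    names_to = "method", values_to = "band") |>
    dplyr::mutate(method = dplyr::if_else(.data$method == "rq_class", "RQ", "SRF")) |>
    dplyr::count(.data$method, .data$band, .drop = FALSE)
  list(
    band_counts = bands,
    n_reclassified = sum(x$reclassified),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    reclassified = dplyr::filter(tibble::as_tibble(x), .data$reclassified)
  )
}

#' @export
print.srf_assessment <- function(x, ...) {
  cat(sprintf("<srf_assessment: %d compounds, rounding = %s>\n",
              nrow(x), attr(x, "rounding")))
  NextMethod()
  # column subsets lose the summary fields; skip the footer then
  needed <- c("name", "rq_class", "srf_class", "reclassified", "direction")
  if (!all(needed %in% names(x))) {
    return(invisible(x))
  }
  s <- srf_summary(x)
  cat(sprintf("reclassified: %d (%d up, %d down)\n",
              s$n_reclassified, s$n_up, s$n_down))
  pr <- attr(x, "problems")
  if (!is.null(pr) && nrow(pr) > 0) {
    cat(sprintf("invalid input rows: %d (see attr(., 'problems'))\n", nrow(pr)))
  }
  invisible(x)
}

#' Tidy an assessment into a long per-method table
#'
#' One row per compound and method (RQ / SRF), with the value and its band —
#' the shape plotting and downstream summaries want.
#'
#' @param x An `srf_assessment`.
#' @param ... Unused.
#' @return A tibble with columns `name`, `method`, `value`, `band`.
#' @method tidy srf_assessment
#' @export
tidy.srf_assessment <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select(dplyr::all_of(c("name", "rq", "srf", "rq_class", "srf_class"))) |>
    tidyr::pivot_longer(cols = dplyr::all_of(c("rq", "srf")),
                        names_to = "method", values_to = "value") |>
    dplyr::mutate(
      band = dplyr::if_else(.data$method == "rq", .data$rq_class, .data$srf_class),
      method = toupper(.data$method)) |>
    dplyr::select(dplyr::all_of(c("name", "method", "value", "band"))) |>
    dplyr::arrange(.data$name, .data$method)
}

#' One-row summary of an assessment
#'
#' @param x An `srf_assessment`.
#' @param ... Unused.
#' @return A one-row tibble: number of compounds, invalid rows,
#'   reclassification counts, and per-band compound counts for each method.
#' @method glance srf_assessment
#' @export
glance.srf_assessment <- function(x, ...) {
  s <- srf_summary(x)
  wide <- s$band_counts |>
    dplyr::mutate(key = paste0("n_", tolower(.data$method), "_", .data$band)) |>
    dplyr::select(dplyr::all_of(c("key", "n"))) |>
    tidyr::pivot_wider(names_from = "key", values_from = "n")
  dplyr::bind_cols(
    tibble::tibble(
      n_compounds = nrow(x),
      n_invalid = nrow(attr(x, "problems") %||% tibble::tibble()),
      n_reclassified = s$n_reclassified,
      n_up = s$n_up, n_down = s$n_down),
    wide)
}
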