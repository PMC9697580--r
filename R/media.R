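#' Assessment configuration: persistence boundary values and assessment factors
#'
#' The persistence boundary value T_CV is the Stockholm Convention Annex D
#' stability cut-off for an environmental compartment: 60 days in water and
#' 180 days in soil and sediment. Assessment factors divide a toxicity
#' endpoint down to a predicted no-effect concentration: 1000 for acute
#' EC50/LC50 endpoints, 100 for chronic values (ChV). Both sets are
#' regulatory defaults, not laws of nature, so they can be overridden here —
#' every assessment function accepts a `config` argument.
#'
#' @param t_cv_days Named numeric vector of persistence boundary values in
#'   days, one entry per medium. Names must cover `"water"`, `"soil"` and
#'   `"sediment"`; all values must be positive.
#' @param assessment_factors Named numeric vector with entries `"acute"` and
#'   `"chronic"`; positive dimensionless divisors applied to toxicity
#'   endpoints when deriving a PNEC.
#'
#' @return A list of class `srf_config` with elements `t_cv_days` and
#'   `assessment_factors`.
#' @examples
#' srf_config()
#' srf_config(t_cv_days = c(water = 40, soil = 120, sediment = 120))
#' @export
srf_config <- function(t_cv_days = c(water = 60, soil = 180, sediment = 180),
                       assessment_factors = c(acute = 1000, chronic = 100)) {
  t_cv_days <- unlist(t_cv_days)
  assessment_factors <- unlist(assessment_factors)
  missing_media <- setdiff(srf_media_levels, names(t_cv_days))
  if (length(missing_media) > 0) {
    abort_srftox("invalid-value",
                 sprintf("t_cv_days must name every medium; missing: %s",
                         paste(missing_media, collapse = ", ")))
  }
  if (any(!is.finite(t_cv_days)) || any(t_cv_days <= 0)) {
    abort_srftox("invalid-value", "persistence boundary values must be positive")
  }
  if (!all(c("acute", "chronic") %in% names(assessment_factors)) ||
      any(!is.finite(assessment_factors)) || any(assessment_factors <= 0)) {
    abort_srftox("invalid-value",
                 "assessment_factors must give positive 'acute' and 'chronic' values")
  }
  structure(list(t_cv_days = t_cv_days[srf_media_levels],
                 assessment_factors = assessment_factors[c("acute", "chronic")]),
            class = "srf_config")
}

srf_media_levels <- c("water", "soil", "sediment")

#' Persistence boundary value for a medium
#'
#' @param medium Character vector of media (`"water"`, `"soil"`, `"sediment"`).
#' @param config An [srf_config()] object.
#' @return Numeric vector of boundary values T_CV in days.
#' @examples
#' t_cv(c("water", "sediment"))
#' @export
t_cv <- function(medium, config = srf_config()) {
  medium <- check_medium(medium)
  unname(config$t_cv_days[medium])
}

check_medium <- function(medium) {
  medium <- tolower(trimws(as.character(medium)))
  bad <- !medium %in% srf_media_levels
  if (any(bad)) {
    abort_srftox("invalid-value",
                 sprintf("unknown medium: %s (expected water, soil or sediment)",
                         paste(unique(medium[bad]), collapse = ", ")))
  }
  medium
}

# classed conditions so callers can distinguish failure modes
abort_srftox <- function(code, message) {
  rlang::abort(message, class = c(paste0("srftox_", code), "srftox_error"),
               code = code)
}
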