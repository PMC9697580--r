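#' Generate a synthetic compound table
#'
#' Draws `n` artificial compound records for property-based testing. Half-
#' life, MEC and PNEC are drawn log-uniformly within their ranges: the
#' quantities span many orders of magnitude in real monitoring data (half-
#' lives from a few days for readily hydrolysed organophosphates to millions
#' of days for bisphenol A; PNECs from below 1 ng/L for potent endocrine
#' disruptors to nearly 1 mg/L for low-toxicity plasticisers), so a uniform
#' draw on the log scale is the realistic choice. Names are synthetic
#' (`SYN-0001`, ...). Identical `seed` and parameters give an identical
#' table; the global RNG state is left untouched.
#'
#' @param n Positive number of compounds.
#' @param half_life_range_days Positive length-2 interval for the
#'   log-uniform half-life draw, in days. The default 1e-1 to 1e7 d covers
#'   the span observed across the bundled case studies.
#' @param mec_range_ng_per_l Positive length-2 interval for the MEC draw
#'   (ng/L).
#' @param pnec_range_ng_per_l Positive length-2 interval for the PNEC draw
#'   (ng/L).
#' @param medium Medium assigned to every record.
#' @param seed Integer seed for the private random stream.
#' @return A tibble in the compound-table schema, valid by construction
#'   (every row passes [validate_record()]).
#' @examples
#' generate_compounds(5, seed = 1)
#' @export
generate_compounds <- function(n,
                               half_life_range_days = c(1e-1, 1e7),
                               mec_range_ng_per_l = c(1e-2, 1e3),
                               pnec_range_ng_per_l = c(1e-2, 1e6),
                               medium = "water",
                               seed = 1L) {
  check_range <- function(r, what) {
    if (length(r) != 2 || any(!is.finite(r)) || any(r <= 0) || r[1] > r[2]) {
      abort_srftox("invalid-spec",
                   sprintf("%s must be a positive interval with lower <= upper",
                           what))
    }
  }
  if (length(n) != 1 || !is.finite(n) || n < 1 || n != round(n)) {
    abort_srftox("invalid-spec", "n must be a positive integer")
  }
  check_range(half_life_range_days, "half_life_range_days")
  check_range(mec_range_ng_per_l, "mec_range_ng_per_l")
  check_range(pnec_range_ng_per_l, "pnec_range_ng_per_l")
  medium <- check_medium(medium)

  r_log_unif <- function(rng, m) 10^runif(m, log10(rng[1]), log10(rng[2]))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  tibble::tibble(
    name = sprintf("SYN-%04d", seq_len(n)),
    cas = NA_character_,
    formula = NA_character_,
    half_life_days = r_log_unif(half_life_range_days, n),
    medium = medium,
    mec_ng_per_l = r_log_unif(mec_range_ng_per_l, n),
    pnec_ng_per_l = r_log_unif(pnec_range_ng_per_l, n),
    c_printed = NA_real_
  )
}
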