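#' Bundled case-study compound tables
#'
#' Three published surface-water monitoring datasets, shipped as packaged
#' CSVs in the compound-table schema:
#'
#' * `ebro_pesticides` — 8 pesticide residues in the Ebro River, Spain
#'   (carbendazim, fenitrothion, hexythiazox, imazalil, metolachlor,
#'   prochloraz, propazine, tebuconazole).
#' * `tianjin_bohai_pfc_ope` — 2 perfluorinated compounds in Tianjin surface
#'   water plus 5 organophosphate esters in the Bohai Sea, China.
#' * `xiangjiang_eds` — 5 endocrine disruptors in the Xiangjiang River,
#'   China (progesterone, testosterone, androstenedione, estrone,
#'   bisphenol A).
#'
#' Each row carries the half-life, MEC and PNEC as published, together with
#' the persistence coefficient as printed in the source table (`c_printed`,
#' rounded to 2-4 significant figures) for use by the `"table"` rounding
#' mode of [srf_assess()]. Two CAS strings in `xiangjiang_eds` are malformed
#' in the source and stored verbatim; CAS warnings are suppressed when
#' loading fixtures.
#'
#' @param which Fixture name; one of the three above.
#' @return A tibble of validated compound records (see [validate_record()]).
#' @examples
#' srf_fixture("ebro_pesticides")
#' srf_fixture_names()
#' @export
srf_fixture <- function(which) {
  stopifnot(is.character(which), length(which) == 1)
  if (!which %in% srf_fixture_names()) {
    abort_srftox("unknown-fixture",
                 sprintf("unknown fixture '%s'; available: %s", which,
                         paste(srf_fixture_names(), collapse = ", ")))
  }
  path <- system.file("extdata", paste0(which, ".csv"), package = "srftox",
                      mustWork = TRUE)
  read_compound_table(path, medium_default = "water", warn_cas = FALSE)
}

#' @rdname srf_fixture
#' @export
srf_fixture_names <- function() {
  c("ebro_pesticides", "tianjin_bohai_pfc_ope", "xiangjiang_eds")
}
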