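#' Parse a concentration value to ng/L
#'
#' Concentrations are interpreted as ng/L unless the cell carries an explicit
#' unit suffix (`"2 ug/L"`, `"0.5 mg/L"`), in which case it is converted
#' (ug/L x 1e3, mg/L x 1e6). Scientific notation is accepted both in plain
#' form (`"1.48e4"`, `"1.48E4"`) and in the typeset form common in published
#' tables (`"1.48 x 10^4^"`, with `x` or the multiplication sign).
#'
#' @param x Numeric or character vector of concentration cells.
#' @return Numeric vector in ng/L; `NA` where the cell could not be parsed.
#' @examples
#' parse_concentration(c("5", "2 ug/L", "1.48 × 10^4^"))
#' @export
parse_concentration <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  unit <- rep(1, length(x))
  has_unit <- grepl("(?i)(ng|µg|ug|mg)\\s*/?\\s*L\\s*$", x, perl = TRUE)
  unit[grepl("(?i)(µg|ug)\\s*/?\\s*L\\s*$", x, perl = TRUE)] <- 1e3
  unit[grepl("(?i)mg\\s*/?\\s*L\\s*$", x, perl = TRUE)] <- 1e6
  x[has_unit] <- sub("(?i)\\s*(ng|µg|ug|mg)\\s*/?\\s*L\\s*$", "", x[has_unit],
                     perl = TRUE)
  parse_quantity(x) * unit
}

#' Parse a numeric cell, accepting typeset scientific notation
#'
#' @param x Numeric or character vector.
#' @return Numeric vector; `NA` where not parseable.
#' @examples
#' parse_quantity(c("8", "1.5 × 10^-5^", "4.02E6"))
#' @export
parse_quantity <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  x <- trimws(as.character(x))
  x <- gsub(",", "", x)                                   # "100,000"
  x <- gsub("−", "-", x)                             # unicode minus
  x <- gsub("\\s*[×x]\\s*10\\^(-?[0-9]+)\\^?", "e\\1", x)  # 1.5 x 10^4^
  x <- sub("^10\\^(-?[0-9]+)\\^?$", "1e\\1", x)           # bare power of ten
  suppressWarnings(as.numeric(x))
}

endpoint_kinds <- c("acute_ec50", "acute_lc50", "chronic_chv")

#' Check a CAS registry number
#'
#' Validates the `NNNNNNN-NN-N` pattern and the mod-10 check digit (the last
#' digit equals the positionally weighted digit sum of the rest, mod 10).
#' Published tables sometimes print malformed CAS strings, so failures are
#' reported, never fatal.
#'
#' @param cas Character vector of CAS strings.
#' @return Logical vector: `TRUE` where pattern and checksum are both valid.
#' @examples
#' cas_is_valid(c("10605-21-7", "1963-5-8"))
#' @export
cas_is_valid <- function(cas) {
  cas <- trimws(as.character(cas))
  ok_pattern <- grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", cas)
  ok <- ok_pattern
  idx <- which(ok_pattern)
  for (i in idx) {
    digits <- as.integer(strsplit(gsub("-", "", cas[i]), "")[[1]])
    nd <- length(digits)
    check <- digits[nd]
    body <- digits[seq_len(nd - 1)]
    ok[i] <- (sum(rev(body) * seq_along(body)) %% 10) == check
  }
  ok
}

# Map loose column names from user tables onto the canonical schema.
canonical_names <- c(
  name = "name", compound = "name",
  cas = "cas",
  formula = "formula", chemical_formula = "formula", chemicalformula = "formula",
  half_life_days = "half_life_days", half_life = "half_life_days",
  halflife = "half_life_days", half_life_d = "half_life_days",
  medium = "medium",
  mec_ng_per_l = "mec_ng_per_l", mec = "mec_ng_per_l",
  pnec_ng_per_l = "pnec_ng_per_l", pnec = "pnec_ng_per_l",
  endpoint_kind = "endpoint_kind",
  endpoint_value_ng_per_l = "endpoint_value_ng_per_l",
  endpoint_value = "endpoint_value_ng_per_l",
  c_printed = "c_printed"
)

normalise_field_names <- function(nms) {
  key <- tolower(gsub("[^a-z0-9]+", "_", tolower(nms)))
  key <- gsub("^_|_$", "", key)
  mapped <- canonical_names[key]
  out <- ifelse(is.na(mapped), nms, mapped)
  unname(out)
}

#' Validate one compound record
#'
#' Turns one row of loosely typed fields (as read from a table) into a
#' validated record. Field names are matched liberally (`half_life` or
#' `half_life_days`, `mec` or `mec_ng_per_l`, ...). Concentrations are
#' interpreted as ng/L unless they carry an explicit unit suffix. Exactly one
#' of a direct PNEC or a toxicity endpoint (kind + value) must be supplied.
#'
#' @param fields Named list or one-row data frame of raw field values.
#' @param medium_default Medium used when the record has none.
#' @param warn_cas Warn on a malformed CAS string (default `TRUE`). The
#'   record is kept either way; CAS problems are never fatal.
#'
#' @return A one-row tibble with columns `name`, `cas`, `formula`,
#'   `half_life_days`, `medium`, `mec_ng_per_l`, `pnec_ng_per_l`,
#'   `endpoint_kind`, `endpoint_value_ng_per_l`, `c_printed`.
#'
#' @section Errors: classed conditions with codes `missing-half-life`
#'   (half-life absent), `invalid-value` (non-positive half-life or PNEC,
#'   negative MEC, unparseable numbers) and `ambiguous-toxicity` (both or
#'   neither of PNEC / endpoint supplied).
#' @examples
#' validate_record(list(name = "Carbendazim", half_life = 8,
#'                      medium = "water", mec = 2.78, pnec = 1.5))
#' @export
validate_record <- function(fields, medium_default = "water", warn_cas = TRUE) {
  fields <- as.list(fields)
  names(fields) <- normalise_field_names(names(fields))

  fld <- function(nm) {
    v <- fields[[nm]]
    if (is.null(v) || length(v) == 0) return(NA)
    v <- v[[1]]
    if (is.character(v) && !nzchar(trimws(v))) return(NA)
    v
  }

  name <- fld("name")
  if (is.na(name)[1] || !nzchar(as.character(name))) {
    abort_srftox("invalid-value", "record has no compound name")
  }
  name <- as.character(name)

  hl_raw <- fld("half_life_days")
  if (length(hl_raw) == 0 || all(is.na(hl_raw))) {
    abort_srftox("missing-half-life", sprintf("%s: half-life is missing", name))
  }
  half_life <- parse_quantity(hl_raw)
  if (is.na(half_life) || half_life <= 0) {
    abort_srftox("invalid-value",
                 sprintf("%s: half-life must be a positive number of days", name))
  }

  medium <- fld("medium")
  medium <- if (is.na(medium)[1]) medium_default else as.character(medium)
  medium <- check_medium(medium)

  mec <- parse_concentration(fld("mec_ng_per_l"))
  if (is.na(mec) || mec < 0) {
    abort_srftox("invalid-value",
                 sprintf("%s: MEC must be a non-negative concentration", name))
  }

  pnec <- parse_concentration(fld("pnec_ng_per_l"))
  ep_kind <- fld("endpoint_kind")
  ep_kind <- if (is.na(ep_kind)[1]) NA_character_ else tolower(as.character(ep_kind))
  ep_value <- parse_concentration(fld("endpoint_value_ng_per_l"))
  has_pnec <- !is.na(pnec)
  has_ep <- !is.na(ep_kind) || !is.na(ep_value)
  if (has_pnec == has_ep) {
    abort_srftox("ambiguous-toxicity",
                 sprintf("%s: supply exactly one of a direct PNEC or a toxicity endpoint",
                         name))
  }
  if (has_pnec && pnec <= 0) {
    abort_srftox("invalid-value",
                 sprintf("%s: PNEC must be a positive concentration", name))
  }
  if (has_ep) {
    if (is.na(ep_kind) || !ep_kind %in% endpoint_kinds) {
      abort_srftox("invalid-value",
                   sprintf("%s: endpoint_kind must be one of %s", name,
                           paste(endpoint_kinds, collapse = ", ")))
    }
    if (is.na(ep_value) || ep_value <= 0) {
      abort_srftox("invalid-value",
                   sprintf("%s: endpoint value must be a positive concentration",
                           name))
    }
  }

  cas <- fld("cas")
  cas <- if (is.na(cas)[1]) NA_character_ else trimws(as.character(cas))
  if (warn_cas && !is.na(cas) && !cas_is_valid(cas)) {
    rlang::warn(sprintf("%s: CAS '%s' fails the pattern or checksum", name, cas),
                class = "srftox_cas_warning")
  }

  formula <- fld("formula")
  formula <- if (is.na(formula)[1]) NA_character_ else as.character(formula)
  c_printed <- parse_quantity(fld("c_printed"))

  tibble::tibble(
    name = name, cas = cas, formula = formula,
    half_life_days = half_life, medium = medium,
    mec_ng_per_l = mec, pnec_ng_per_l = if (has_pnec) pnec else NA_real_,
    endpoint_kind = if (has_ep) ep_kind else NA_character_,
    endpoint_value_ng_per_l = if (has_ep) ep_value else NA_real_,
    c_printed = c_printed
  )
}

#' Validate a table of compound records
#'
#' Row-wise [validate_record()] over a data frame. Invalid rows are collected
#' in a problems table rather than dropped silently; valid rows are returned
#' in input order.
#'
#' @param data Data frame of raw compound rows.
#' @inheritParams validate_record
#' @return A tibble of validated records with attribute `"problems"`: a
#'   tibble with columns `row`, `code`, `message` (zero rows when everything
#'   validated).
#' @examples
#' tbl <- data.frame(name = c("A", "B"), half_life = c(8, -1),
#'                   mec = c(2, 3), pnec = c(1, 1))
#' out <- validate_compounds(tbl)
#' attr(out, "problems")
#' @export
validate_compounds <- function(data, medium_default = "water", warn_cas = TRUE) {
  stopifnot(is.data.frame(data))
  rows <- split(data, seq_len(nrow(data)))
  records <- vector("list", length(rows))
  problems <- list()
  for (i in seq_along(rows)) {
    rec <- tryCatch(
      validate_record(rows[[i]], medium_default = medium_default,
                      warn_cas = warn_cas),
      srftox_error = function(e) e
    )
    if (inherits(rec, "srftox_error")) {
      problems[[length(problems) + 1]] <- tibble::tibble(
        row = i, code = rec$code, message = conditionMessage(rec))
      records[[i]] <- NULL
    } else {
      records[[i]] <- rec
    }
  }
  kept <- !vapply(records, is.null, logical(1))
  out <- dplyr::bind_rows(records)
  if (nrow(out) == 0) {
    out <- validate_record(list(name = "x", half_life = 1, mec = 0, pnec = 1))[0, ]
  }
  # unknown input columns ride along as passthrough metadata
  extra_names <- setdiff(normalise_field_names(names(data)),
                         unname(canonical_names))
  if (length(extra_names) > 0 && nrow(out) > 0) {
    extras <- data
    names(extras) <- normalise_field_names(names(extras))
    out <- dplyr::bind_cols(out, extras[kept, extra_names, drop = FALSE])
  }
  attr(out, "problems") <- if (length(problems)) dplyr::bind_rows(problems) else
    tibble::tibble(row = integer(), code = character(), message = character())
  out
}
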