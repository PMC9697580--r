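# Shared helpers: small in-code tables and utilities.

# minimal valid compound row, overridable field by field
compound_row <- function(...) {
  base <- list(name = "Test compound", half_life = 10, medium = "water",
               mec = 5, pnec = 2)
  utils::modifyList(base, list(...))
}

compound_table <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) tibble::as_tibble(r)))
}

# number of significant digits in the shortest decimal representation of x
n_sig <- function(x) {
  s <- format(x, scientific = TRUE, digits = 15)
  mant <- sub("[eE].*$", "", s)
  mant <- gsub("[^0-9]", "", mant)
  mant <- sub("0+$", "", mant)
  max(nchar(sub("^0+", "", mant)), 1)
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

cli_path <- function() system.file("cli", "srftox.R", package = "srftox")

run_cli <- function(args) {
  out <- suppressWarnings(system2(
    rscript_bin(), c(shQuote(cli_path()), args),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  status <- attr(out, "status")
  list(output = paste(out, collapse = "\n"),
       status = if (is.null(status)) 0L else status)
}
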