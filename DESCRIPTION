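Package: srftox
Title: Persistence-Weighted Environmental Risk Screening of Aquatic Pollutants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-dimensional screening-level ecological risk assessment of
    chemical pollutants in surface water, soil and sediment. Implements the
    synthetic risk factor (SRF), a persistence-weighted extension of the
    classical risk quotient (RQ): an environmental persistence coefficient is
    derived from a compound's half-life and the Stockholm Convention
    persistence boundary value for its medium, predicted no-effect
    concentrations are derived from acute or chronic toxicity endpoints with
    standard assessment factors, and both RQ and SRF are mapped onto a
    four-band risk scale (negligible, minimal, medium, high). Ships readers
    and writers for tabular compound data, bundled case-study datasets for
    pesticides, perfluorinated compounds, organophosphate esters and
    endocrine disruptors, a deterministic synthetic compound-table generator
    for property testing, plotting helpers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
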