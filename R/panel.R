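#' Published perinatal outcome panel
#'
#' The 16 primary and 8 secondary pregnancy and perinatal outcomes of the
#' maternal blood pressure analysis, with published case counts, rounded
#' case percentages and maximum sample sizes, as shipped in
#' `inst/extdata/outcome_panel.tsv`. Continuous outcomes (birth weight,
#' gestational age) have `NA` cases.
#'
#' @return data frame with columns `outcome`, `group`, `type`, `cases`,
#'   `cases_pct`, `n`.
#' @export
outcome_panel <- function() {
  path <- system.file("extdata", "outcome_panel.tsv", package = "mrwide",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
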