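# Packaged reference tables for the nine study lakes, used as desk-check
# inputs for the summary and upscaling chain.

#' Study-lake reference tables
#'
#' `lake_catchment_table()` returns morphometry and long-term mean chemistry
#' for the nine monitored subarctic lakes (areas in km^2, concentrations in
#' ug/L and mg/L). `lake_sequestration_table()` returns the per-lake mean
#' +/- SD areal P and N sequestration densities (ton/km^2) for the two
#' contrast periods (early: 1983-1994, 1983-1992 for Abiskojaure; late:
#' 2001-2020) plus the published relative increases -- the inputs to
#' [summarize_lakes()] and [upscale()].
#'
#' @return A data.frame.
#' @export
lake_catchment_table <- function() {
  utils::read.csv(system.file("extdata", "lake_catchments.csv",
                              package = "greenlakes"),
                  check.names = FALSE)
}

#' @rdname lake_catchment_table
#' @export
lake_sequestration_table <- function() {
  utils::read.csv(system.file("extdata", "lake_sequestration_periods.csv",
                              package = "greenlakes"),
                  check.names = FALSE)
}
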