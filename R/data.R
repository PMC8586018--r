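# Packaged study metadata.

#' Kongsfjorden kittiwake colony metadata
#'
#' The five studied black-legged kittiwake colonies in the Kongsfjorden
#' region (Svalbard): centroid coordinates (0.01 degree precision), colony
#' size in breeding pairs with survey year, and the number of foraging trips
#' and tracked individuals recorded per colony and sex during chick rearing
#' in 2017.
#'
#' @return data frame with one row per colony: `id`, `name`, `lon`, `lat`,
#'   `size`, `survey_year`, `trips_male`, `trips_female`, `trips_total`,
#'   `ind_male`, `ind_female`, `ind_total`.
#' @export
kongsfjorden_colonies <- function() {
  path <- system.file("extdata", "kongsfjorden_colonies.tsv",
                      package = "glacierseg", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
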