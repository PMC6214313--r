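#' Case-study summary tables (Metropolitan City of Cagliari)
#'
#' Published summary tables for a corridor network of the Metropolitan City
#' of Cagliari, Sardinia (6995 patches, 17464 adjacencies, 18 components,
#' 569 cut nodes), shipped as plain-text inputs: the occurrence histogram of
#' the additional component count over all cut nodes, the printed excerpt of
#' the second-size histogram (lower prefix plus the two largest values), the
#' 13-row cut-node indicator table of one 298-patch component, and the
#' network-wide counts. Useful for exercising the percentile and combined
#' score arithmetic against known figures.
#'
#' @return list with data frames `component_count_hist`, `second_size_hist`,
#'   `cut_node_table`, and named numeric vector `summary`
#' @export
cagliari_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "corridorcut",
                                  mustWork = TRUE)
  summary_df <- utils::read.csv(path("cagliari_network_summary.csv"),
                                stringsAsFactors = FALSE)
  list(
    component_count_hist = utils::read.csv(
      path("cagliari_component_count_hist.csv")),
    second_size_hist = utils::read.csv(
      path("cagliari_second_size_hist_prefix.csv")),
    cut_node_table = utils::read.csv(path("cagliari_cut_node_table.csv"),
                                     colClasses = c(node_id = "character")),
    summary = setNames(as.numeric(summary_df$value), summary_df$name)
  )
}
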