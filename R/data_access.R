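#' The packaged study population table
#'
#' The 15 populations (14 native-range, 1 introduced-range) genotyped
#' for the focal endosymbiont strain between 2018 and 2021, as published
#' per population: sample size `n`, number infected `k`, and — where the
#' published table reports a single haplotype for a population — per-
#' individual mitochondrial haplotype calls. Populations reported with
#' mixed haplotypes (Poland, Sweden, Finland) carry no per-individual
#' calls because the published split is not individual-resolved.
#'
#' Coordinates are approximate representative locations for the named
#' sampling areas (the published table names populations but does not
#' print coordinates); they are adequate for examples and for
#' exercising the spatial stages, not for reproducing the native-range
#' surface, which requires the full historical multi-study dataset.
#'
#' @return A validated population tibble with 15 rows.
#' @export
#' @examples
#' wolb_table1() |> estimate_frequencies()
wolb_table1 <- function() {
  read_population_table(
    system.file("extdata", "table1_populations.csv", package = "wolbtrace")
  )
}
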