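#' Published national summary tables for TCM health resources, 2013-2017
#'
#' Published summary statistics of traditional Chinese medicine (TCM) health
#' resources across the 31 mainland-China province-level divisions,
#' 2013-2017, transcribed from yearbook-based national reporting and
#' distributed with the package as plain-text CSV. They provide realistic
#' reference magnitudes for examples and support arithmetic consistency
#' checks of the package's measures (Theil additivity, Malmquist
#' decomposition identities, contribution rates) at national scale without
#' any external download. Province-level raw input/output data are not
#' published at this granularity and are not included.
#'
#' Available tables:
#' * `"density"` — national totals of institutions, beds and health staff
#'   per year, with densities per 1,000 persons and per 1,000 km2.
#' * `"gini"` — Gini coefficients per year, resource and allocation base.
#' * `"theil"` — Theil index per year and resource with within-/
#'   between-region components.
#' * `"theil_regions"` — within-region Theil indices per region.
#' * `"slacks"` — DEA input/output slacks for 2017 (inputs negative).
#' * `"mpi_year"` — Malmquist components per adjacent year pair.
#' * `"mpi_frequency"` — counts of provinces with each component
#'   >1 / =1 / <1 per year pair.
#' * `"mpi_province"` — per-province Malmquist components (multi-year
#'   geometric means).
#'
#' @param name Which table to load.
#' @return A tibble.
#' @examples
#' reference_table("mpi_year")
#' @export
reference_table <- function(name = c("density", "gini", "theil",
                                     "theil_regions", "slacks", "mpi_year",
                                     "mpi_frequency", "mpi_province")) {
  name <- match.arg(name)
  file <- switch(name,
    density = "tcm_density_2013_2017.csv",
    gini = "tcm_gini_2013_2017.csv",
    theil = "tcm_theil_2013_2017.csv",
    theil_regions = "tcm_theil_regions_2013_2017.csv",
    slacks = "tcm_slacks_2017.csv",
    mpi_year = "tcm_mpi_by_year.csv",
    mpi_frequency = "tcm_mpi_frequency.csv",
    mpi_province = "tcm_mpi_by_province.csv")
  path <- system.file("extdata", file, package = "equidea", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
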