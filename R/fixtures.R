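# Accessors for the bundled western-Sichuan spiny-frog survey summaries
# (published per-population microsatellite diversity and F-statistics),
# shipped as plain TSV under inst/extdata. They serve as worked-example
# inputs and as internal-consistency fixtures for the diversity engine.

#' Bundled per-population chromosome-class diversity summary
#'
#' Published theta estimates (stepwise-mutation-model scaled diversity,
#' averaged over loci) for the eight translocation-polymorphic western
#' Sichuan Basin populations of a spiny-frog microsatellite survey:
#' observed theta for Y, X and autosomes, the neutral-ratio expectations,
#' and the translocated/normal X partition where available, plus the
#' column-average row.
#'
#' @param include_average keep the `Average` row (default `TRUE`).
#' @return data.frame with columns `population, theta_Y, theta_X, theta_A,
#'   e_theta_Y, e_theta_X, e_theta_A, theta_XT, theta_XN`.
#' @export
western_theta_table <- function(include_average = TRUE) {
  path <- system.file("extdata", "sichuan_theta.tsv", package = "xylink")
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!include_average) df <- df[df$population != "Average", ]
  df
}

#' Bundled population summary of the spiny-frog survey
#'
#' Sixteen populations with coordinates, sample sizes by sex x karyotype
#' class (FN/FT/MN/MT), published between-sex F-statistics over the six
#' sex-linked loci, and the WEST/EAST group split.
#'
#' @return data.frame, one row per population.
#' @export
survey_populations <- function() {
  path <- system.file("extdata", "sichuan_populations.tsv",
                      package = "xylink")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
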