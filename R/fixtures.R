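#' Load a packaged census fixture
#'
#' Three reference tables for a 93-genome acidophile (Acidithiobacillia
#' class) dataset ship with the package:
#' \describe{
#'   \item{table1_census}{Per-species NAP family census: 16 species rows x
#'     12 family columns with total counts and per-genome dose ranges,
#'     plus per-species genome counts and NAPs-per-genome summaries.
#'     Returned as a list with elements `species` (one row per species)
#'     and `cells` (long lineage x family table: total, dose_min,
#'     dose_max).}
#'   \item{table3_plasmids}{Eight plasmid replicons with their NAP counts
#'     and family lists.}
#'   \item{table4_imges}{Eight integrated mobile elements with their NAP
#'     family entries (semicolon-separated in the `families` column).}
#' }
#' Dose ranges are stored as (min, max) integers; a printed dose of "(1)"
#' is stored as (1, 1) and an absent family as (0, 0).
#'
#' @param name One of "table1_census", "table3_plasmids", "table4_imges".
#' @return A data.frame, or a list of data.frames for `table1_census`.
#' @export
load_fixture <- function(name = c("table1_census", "table3_plasmids",
                                  "table4_imges")) {
  name <- match.arg(name)
  fp <- function(f) system.file("extdata", f, package = "nappan",
                                mustWork = TRUE)
  rd <- function(f) utils::read.delim(fp(f), stringsAsFactors = FALSE,
                                      na.strings = "")
  switch(name,
    table1_census = list(
      species = rd("table1_species.tsv"),
      cells = rd("table1_cells.tsv")
    ),
    table3_plasmids = rd("table3_plasmids.tsv"),
    table4_imges = rd("table4_imges.tsv")
  )
}

#' Build a census table object from the table1_census fixture
#'
#' Re-expresses the packaged species-level census in the same structure
#' that [census()] produces from candidate lists, so the downstream census
#' arithmetic (grand totals, family fractions, core-set recovery) can run
#' on it unchanged.
#'
#' @param fixture Result of `load_fixture("table1_census")`.
#' @return A `census_table` object.
#' @export
fixture_census <- function(fixture = load_fixture("table1_census")) {
  n <- stats::setNames(as.integer(fixture$species$n_genomes),
                       fixture$species$lineage)
  new_census_table(fixture$cells, n)
}

#' Maximum-spread presence reconstruction
#'
#' Reconstructs per-species carrier counts from a census that only reports
#' totals and dose ranges: `carriers = min(n_genomes, floor(total /
#' dose_min))` (0 when the family is absent). This is the deterministic
#' reconstruction that spreads copies over as many genomes as the printed
#' dose range allows; it is consistent with every census cell.
#'
#' @param census A `census_table`.
#' @return data.frame with columns lineage, family, carriers, n_genomes.
#' @export
reconstruct_presence <- function(census) {
  cells <- census$cells
  n <- census$n_genomes[cells$lineage]
  carriers <- ifelse(cells$total == 0 | cells$dose_min == 0, 0L,
                     pmin(as.integer(n),
                          as.integer(floor(cells$total / cells$dose_min))))
  data.frame(lineage = cells$lineage, family = cells$family,
             carriers = carriers, n_genomes = as.integer(n),
             row.names = NULL, stringsAsFactors = FALSE)
}
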