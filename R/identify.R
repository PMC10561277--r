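#' Census table constructor
#'
#' @param cells data.frame with columns lineage, family, total, dose_min,
#'   dose_max (dose over carrier genomes only).
#' @param n_genomes Named integer vector: genomes per lineage.
#' @param per_genome Optional data.frame (genome_id, lineage, n_naps) with
#'   per-genome NAP counts, kept for median/range summaries.
#' @return Object of class `census_table`.
#' @export
new_census_table <- function(cells, n_genomes, per_genome = NULL) {
  stopifnot(all(c("lineage", "family", "total", "dose_min", "dose_max")
                %in% names(cells)),
            all(cells$lineage %in% names(n_genomes)))
  carriers_max <- n_genomes[cells$lineage] * cells$dose_max
  if (any(cells$total > carriers_max)) {
    stop("census cell total exceeds n_genomes * dose_max")
  }
  x <- list(cells = cells, n_genomes = n_genomes, per_genome = per_genome)
  class(x) <- "census_table"
  x
}

#' @export
print.census_table <- function(x, ...) {
  cat(sprintf("<census_table> %d lineages, %d families, grand total %d\n",
              length(x$n_genomes), length(unique(x$cells$family)),
              sum(x$cells$total)))
  invisible(x)
}

#' Grand total of a census
#' @param census A `census_table`.
#' @return Integer: total number of proteins counted.
#' @export
census_grand_total <- function(census) sum(census$cells$total)

#' Validate domain hits and assign one family per protein
#'
#' A protein is retained iff it has at least one hit with
#' `evalue < th$validation_evalue`, a probability that is either absent or
#' `> th$validation_probability`, and a coverage that is either absent or
#' `>= th$bbh_coverage`. Among a protein's passing hits the assigned family
#' is the profile of the minimum e-value (ties broken by higher
#' probability, then lexicographic profile id). Exactly one candidate row
#' is emitted per retained protein; the result is independent of input
#' order and idempotent.
#'
#' @param hits data.frame of domain hits ([read_domain_hits()] layout).
#' @param th A [nap_thresholds()] object.
#' @param protein_info Optional data.frame (protein_id, genome_id, gene_id)
#'   used to annotate candidates; unmatched proteins get NA.
#' @return data.frame of NAP candidates: protein_id, genome_id, gene_id,
#'   family, evalue, probability, coverage.
#' @export
validate_hits <- function(hits, th = nap_thresholds(), protein_info = NULL) {
  empty <- data.frame(protein_id = character(), genome_id = character(),
                      gene_id = character(), family = character(),
                      evalue = numeric(), probability = numeric(),
                      coverage = numeric(), stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0) return(empty)
  pass <- hits$evalue < th$validation_evalue &
    (is.na(hits$probability) | hits$probability > th$validation_probability) &
    (is.na(hits$coverage) | hits$coverage >= th$bbh_coverage)
  h <- hits[pass, , drop = FALSE]
  if (nrow(h) == 0) return(empty)
  # deterministic best hit per protein: min e-value, then max probability,
  # then lexicographic profile id
  prob_key <- ifelse(is.na(h$probability), -Inf, h$probability)
  ord <- order(h$protein_id, h$evalue, -prob_key, h$profile_id)
  h <- h[ord, , drop = FALSE]
  best <- h[!duplicated(h$protein_id), , drop = FALSE]
  out <- data.frame(
    protein_id = best$protein_id,
    genome_id = NA_character_,
    gene_id = NA_character_,
    family = best$profile_id,
    evalue = best$evalue,
    probability = best$probability,
    coverage = best$coverage,
    stringsAsFactors = FALSE
  )
  if (!is.null(protein_info)) {
    idx <- match(out$protein_id, protein_info$protein_id)
    out$genome_id <- protein_info$genome_id[idx]
    if ("gene_id" %in% names(protein_info)) {
      out$gene_id <- protein_info$gene_id[idx]
    }
  }
  rownames(out) <- NULL
  out[order(out$protein_id), , drop = FALSE]
}

#' Census candidate NAPs per lineage and family
#'
#' Counts candidates per lineage x family, with per-genome dose minima and
#' maxima taken over carrier genomes only (genomes not carrying the family
#' do not enter the dose range). Families from [nap_families()] are always
#' present as columns; additional observed families are appended.
#'
#' @param candidates data.frame from [validate_hits()], with genome_id set.
#' @param genomes List of [genome_record()] objects, or a data.frame with
#'   columns genome_id and lineage_id.
#' @return A `census_table` with per-genome counts attached.
#' @export
census <- function(candidates, genomes) {
  if (is.data.frame(genomes)) {
    gmeta <- genomes[, c("genome_id", "lineage_id")]
  } else {
    gmeta <- data.frame(
      genome_id = vapply(genomes, function(g) g$genome_id, character(1)),
      lineage_id = vapply(genomes, function(g) g$lineage_id, character(1)),
      stringsAsFactors = FALSE
    )
  }
  if (anyDuplicated(gmeta$genome_id)) stop("duplicate genome ids")
  orphans <- setdiff(candidates$genome_id, gmeta$genome_id)
  if (length(orphans) > 0) {
    stop("candidates reference unknown genomes: ",
         paste(unique(orphans), collapse = ", "))
  }
  lineages <- unique(gmeta$lineage_id)
  fams <- union(nap_families(), unique(candidates$family))
  n_genomes <- vapply(lineages, function(l) sum(gmeta$lineage_id == l),
                      integer(1))
  grid <- expand.grid(lineage = lineages, family = fams,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$lineage, lineages),
                     match(grid$family, fams)), ]
  cand_lin <- gmeta$lineage_id[match(candidates$genome_id, gmeta$genome_id)]
  key <- paste(cand_lin, candidates$family, sep = "\r")
  tot <- table(key)
  grid$total <- as.integer(tot[paste(grid$lineage, grid$family, sep = "\r")])
  grid$total[is.na(grid$total)] <- 0L
  # dose over carrier genomes
  gkey <- paste(candidates$genome_id, candidates$family, sep = "\r")
  per_gf <- table(gkey)
  dose_min <- integer(nrow(grid)); dose_max <- integer(nrow(grid))
  carriers <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (grid$total[i] == 0L) next
    in_lin <- gmeta$genome_id[gmeta$lineage_id == grid$lineage[i]]
    doses <- per_gf[paste(in_lin, grid$family[i], sep = "\r")]
    doses <- doses[!is.na(doses)]
    dose_min[i] <- min(doses); dose_max[i] <- max(doses)
    carriers[i] <- length(doses)
  }
  grid$dose_min <- dose_min
  grid$dose_max <- dose_max
  grid$carriers <- carriers
  rownames(grid) <- NULL
  per_genome <- data.frame(
    genome_id = gmeta$genome_id,
    lineage = gmeta$lineage_id,
    n_naps = as.integer(table(factor(candidates$genome_id,
                                     levels = gmeta$genome_id))),
    stringsAsFactors = FALSE
  )
  new_census_table(grid, n_genomes, per_genome)
}

#' Per-lineage NAPs-per-genome summary
#'
#' Median and range of NAP counts per genome within each lineage; needs a
#' census built from candidates (not a fixture-derived one).
#'
#' @param census A `census_table` with per-genome counts.
#' @return data.frame: lineage, n_genomes, naps_median, naps_min, naps_max.
#' @export
census_summary <- function(census) {
  pg <- census$per_genome
  if (is.null(pg)) stop("census has no per-genome counts")
  lins <- names(census$n_genomes)
  do.call(rbind, lapply(lins, function(l) {
    v <- pg$n_naps[pg$lineage == l]
    data.frame(lineage = l, n_genomes = census$n_genomes[[l]],
               naps_median = stats::median(v), naps_min = min(v),
               naps_max = max(v), stringsAsFactors = FALSE)
  }))
}

#' Family share of the total census
#'
#' Percentage of all counted proteins belonging to each family, to one
#' decimal.
#'
#' @param census A `census_table` with a positive grand total.
#' @return Named numeric vector of percentages (sums to 100 up to
#'   rounding), sorted decreasing.
#' @export
family_fractions <- function(census) {
  gt <- census_grand_total(census)
  if (gt <= 0) stop("census grand total is zero")
  tot <- tapply(census$cells$total, census$cells$family, sum)
  sort(round(100 * tot / gt, 1), decreasing = TRUE)
}
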