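#' Frequency index of a protein family within a lineage
#'
#' Ratio of the lineage's genomes that carry the family to the lineage's
#' total genome count.
#'
#' @param presence Logical vector, one element per genome of the lineage
#'   (TRUE = carries the family), or a named list of such vectors (one per
#'   lineage).
#' @return Fraction in [0, 1] (or a named vector, one per lineage).
#' @export
frequency_index <- function(presence) {
  if (is.list(presence)) {
    return(vapply(presence, frequency_index, numeric(1)))
  }
  if (length(presence) == 0) stop("lineage has no genomes")
  sum(presence) / length(presence)
}

#' Paralogue index of a family within a lineage
#'
#' Mean per-genome copy number over carrier genomes, divided by the number
#' of distinct protein families (PFs) the family's members form in that
#' lineage. A value near the copy number signals true paralogy (many
#' copies, one PF); a value near 1 signals divergent variants (each copy
#' its own PF).
#'
#' @param doses Integer copy counts per genome (zeros = non-carriers).
#' @param n_distinct_pfs Number of distinct PFs of the family in the
#'   lineage (>= 1).
#' @return Non-negative real.
#' @export
paralogue_index <- function(doses, n_distinct_pfs) {
  if (n_distinct_pfs < 1) stop("n_distinct_pfs must be >= 1")
  carriers <- doses[doses > 0]
  if (length(carriers) == 0) stop("no carrier genomes")
  mean(carriers) / n_distinct_pfs
}

#' Core family set under the class-wide occupancy rule
#'
#' Families whose carriers across all genomes exceed the occupancy
#' threshold (strictly more than `th$core_occupancy` of all genomes,
#' default 90%).
#'
#' @param class_carriers Named integer vector: carrier genomes per family,
#'   across the whole dataset.
#' @param total_genomes Total genome count.
#' @param th A [nap_thresholds()].
#' @return Sorted character vector of core family names.
#' @export
core_family_set <- function(class_carriers, total_genomes,
                            th = nap_thresholds()) {
  if (total_genomes < 1) stop("total_genomes must be >= 1")
  occ <- class_carriers / total_genomes
  sort(names(class_carriers)[occ > th$core_occupancy])
}

#' Classify lineage x family profiles into pangenome compartments
#'
#' A family is `core` when its class-wide occupancy exceeds
#' `th$core_occupancy` of all genomes. Otherwise, within a lineage it is
#' `conserved_flexible` when the lineage frequency index passes
#' `th$conserved_frequency` (comparator `>=` by default, configurable to
#' `>`), else `nonconserved_flexible`; lineages represented by a single
#' genome are only eligible for `conserved_flexible` when
#' `single_genome_conserved = TRUE`, since a frequency of 1/1 is
#' uninformative. Absent families (frequency 0) are labelled `absent`.
#'
#' @param profiles data.frame with columns lineage, family,
#'   frequency_index and n_genomes (genomes in the lineage).
#' @param class_carriers Named integer vector: class-wide carrier genomes
#'   per family.
#' @param total_genomes Total genome count across lineages.
#' @param th A [nap_thresholds()].
#' @param conserved_cmp Comparator for the conserved-frequency rule,
#'   either `>=` or `>`.
#' @param single_genome_conserved Allow single-genome lineages to be
#'   classified as conserved.
#' @return `profiles` with a `compartment` factor column added.
#' @export
classify_compartments <- function(profiles, class_carriers, total_genomes,
                                  th = nap_thresholds(),
                                  conserved_cmp = `>=`,
                                  single_genome_conserved = FALSE) {
  core_fams <- core_family_set(class_carriers, total_genomes, th)
  comp <- character(nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    f <- profiles$frequency_index[i]
    if (f == 0) {
      comp[i] <- "absent"
    } else if (profiles$family[i] %in% core_fams) {
      comp[i] <- "core"
    } else if (conserved_cmp(f, th$conserved_frequency) &&
               (profiles$n_genomes[i] > 1 || single_genome_conserved)) {
      comp[i] <- "conserved_flexible"
    } else {
      comp[i] <- "nonconserved_flexible"
    }
  }
  profiles$compartment <- factor(comp, levels = c("core",
    "conserved_flexible", "nonconserved_flexible", "absent"))
  profiles
}

#' Build pangenome profiles from a census
#'
#' Derives, per lineage x family, the frequency index, mean dose over
#' carriers, paralogue index and pangenome compartment.
#'
#' @param census A `census_table` whose cells carry a `carriers` column
#'   (as produced by [census()]).
#' @param n_pfs Optional data.frame (lineage, family, n_pfs) giving the
#'   number of distinct PFs per lineage x family; defaults to 1.
#' @param th A [nap_thresholds()].
#' @param ... Passed to [classify_compartments()].
#' @return data.frame of class-annotated profiles.
#' @export
pangenome_profiles <- function(census, n_pfs = NULL,
                               th = nap_thresholds(), ...) {
  cells <- census$cells
  if (!"carriers" %in% names(cells)) {
    stop("census cells lack a carriers column; build it with census() or ",
         "reconstruct presence first")
  }
  ng <- census$n_genomes[cells$lineage]
  prof <- data.frame(
    lineage = cells$lineage,
    family = cells$family,
    n_genomes = as.integer(ng),
    frequency_index = cells$carriers / as.numeric(ng),
    mean_dose = ifelse(cells$carriers > 0, cells$total / cells$carriers, 0),
    stringsAsFactors = FALSE
  )
  k <- rep(1, nrow(prof))
  if (!is.null(n_pfs)) {
    idx <- match(paste(prof$lineage, prof$family),
                 paste(n_pfs$lineage, n_pfs$family))
    k[!is.na(idx)] <- n_pfs$n_pfs[idx[!is.na(idx)]]
  }
  prof$paralogue_index <- ifelse(prof$mean_dose > 0, prof$mean_dose / k, 0)
  class_carriers <- tapply(cells$carriers, cells$family, sum)
  classify_compartments(prof, class_carriers, sum(census$n_genomes), th, ...)
}

#' Pearson correlation with a paired-data contract
#'
#' Product-moment correlation over paired observations, requiring at least
#' three complete pairs and non-degenerate variance on both sides.
#'
#' @param x,y Numeric vectors of equal length.
#' @param x_label,y_label Axis labels recorded in the result.
#' @return List of class `correlation_result`: x_label, y_label, n,
#'   pearson_r.
#' @export
pearson <- function(x, y, x_label = deparse(substitute(x)),
                    y_label = deparse(substitute(y))) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  r <- stats::cor(x, y, method = "pearson")
  structure(list(x_label = x_label, y_label = y_label,
                 n = length(x), pearson_r = r),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> %s vs %s: r = %.3f (n = %d)\n",
              x$x_label, x$y_label, x$pearson_r, x$n))
  invisible(x)
}
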