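#' Canonical NAP family labels
#'
#' The twelve nucleoid-associated protein families tracked by the census:
#' Alba_2, EbfC, Fis, H-NS, HU, IHF_A, IHF_B, KfrA, Lrp, MukB, NdpA and SMC.
#' Other profile labels are accepted everywhere; this vector only fixes the
#' column order of census tables.
#'
#' @return Character vector of family labels.
#' @export
nap_families <- function() {
  c("EbfC", "Fis", "H-NS", "HU", "IHF_A", "IHF_B",
    "Lrp", "SMC", "Alba_2", "KfrA", "NdpA", "MukB")
}

#' Analysis thresholds
#'
#' Bundles every cutoff used along the pipeline. Defaults follow the
#' validation and clustering settings of the source workflow: PSI-BLAST
#' significance 0.01, hit validation at e-value < 1e-5 with probability
#' > 90 (when reported), reciprocal-best-hit filtering at 75% coverage and
#' e-value 1e-5, greedy identity clustering at 50%, core occupancy > 90%,
#' conserved-lineage frequency >= 0.90, a 5-kb vicinity window and 10-bp
#' coverage bins.
#'
#' @param psiblast_evalue PSI-BLAST significance cutoff (informational).
#' @param validation_evalue Hit-validation e-value cutoff; hits must be
#'   strictly below it.
#' @param validation_probability Probability cutoff in percent; hits
#'   reporting a probability must strictly exceed it.
#' @param bbh_coverage Minimum pairwise alignment coverage (fraction).
#' @param bbh_evalue Maximum pairwise e-value for best-hit edges.
#' @param identity_cluster_threshold Greedy clustering identity threshold.
#' @param core_occupancy Class-wide occupancy above which a family is core.
#' @param conserved_frequency Lineage frequency index at/above which a
#'   flexible family counts as conserved.
#' @param vicinity_window_bp Gene-vicinity window in bp, each side.
#' @param coverage_bin_bp Coverage bin width in bp.
#' @return An object of class `nap_thresholds` (a named list).
#' @export
nap_thresholds <- function(psiblast_evalue = 0.01,
                           validation_evalue = 1e-5,
                           validation_probability = 90,
                           bbh_coverage = 0.75,
                           bbh_evalue = 1e-5,
                           identity_cluster_threshold = 0.50,
                           core_occupancy = 0.90,
                           conserved_frequency = 0.90,
                           vicinity_window_bp = 5000,
                           coverage_bin_bp = 10) {
  th <- list(
    psiblast_evalue = psiblast_evalue,
    validation_evalue = validation_evalue,
    validation_probability = validation_probability,
    bbh_coverage = bbh_coverage,
    bbh_evalue = bbh_evalue,
    identity_cluster_threshold = identity_cluster_threshold,
    core_occupancy = core_occupancy,
    conserved_frequency = conserved_frequency,
    vicinity_window_bp = vicinity_window_bp,
    coverage_bin_bp = coverage_bin_bp
  )
  stopifnot(
    th$validation_evalue >= 0,
    th$validation_probability >= 0, th$validation_probability <= 100,
    th$bbh_coverage >= 0, th$bbh_coverage <= 1,
    th$identity_cluster_threshold > 0, th$identity_cluster_threshold <= 1,
    th$core_occupancy >= 0, th$core_occupancy <= 1,
    th$conserved_frequency >= 0, th$conserved_frequency <= 1,
    th$vicinity_window_bp >= 1, th$coverage_bin_bp >= 1
  )
  th$vicinity_window_bp <- as.integer(th$vicinity_window_bp)
  th$coverage_bin_bp <- as.integer(th$coverage_bin_bp)
  class(th) <- "nap_thresholds"
  th
}

#' Read thresholds from a YAML file
#'
#' Keys absent from the file keep their defaults; unknown keys are an error.
#'
#' @param path Path to a YAML file whose keys match [nap_thresholds()]
#'   arguments.
#' @return A `nap_thresholds` object.
#' @export
read_thresholds <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(nap_thresholds))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown threshold keys: ", paste(bad, collapse = ", "))
  }
  do.call(nap_thresholds, vals)
}

#' Construct a replicon table
#'
#' @param replicon_id Replicon identifiers (unique).
#' @param length_bp Replicon lengths in bp (> 0).
#' @param topology "circular" or "linear".
#' @param kind "chromosome", "plasmid" or "contig".
#' @param ori_pos,ter_pos 1-based origin/terminus coordinates or NA.
#' @return data.frame with one row per replicon.
#' @export
replicon_table <- function(replicon_id, length_bp,
                           topology = "circular", kind = "chromosome",
                           ori_pos = NA_integer_, ter_pos = NA_integer_) {
  df <- data.frame(
    replicon_id = as.character(replicon_id),
    length_bp = as.integer(length_bp),
    topology = rep_len(topology, length(replicon_id)),
    kind = rep_len(kind, length(replicon_id)),
    ori_pos = rep_len(as.integer(ori_pos), length(replicon_id)),
    ter_pos = rep_len(as.integer(ter_pos), length(replicon_id)),
    stringsAsFactors = FALSE
  )
  stopifnot(
    all(df$length_bp > 0),
    all(df$topology %in% c("circular", "linear")),
    all(df$kind %in% c("chromosome", "plasmid", "contig")),
    !anyDuplicated(df$replicon_id)
  )
  ok <- function(p, len) is.na(p) | (p >= 1 & p <= len)
  if (!all(ok(df$ori_pos, df$length_bp)) || !all(ok(df$ter_pos, df$length_bp))) {
    stop("ori_pos/ter_pos must lie within [1, length_bp]")
  }
  df
}

#' Construct a gene feature table
#'
#' Coordinates are 1-based inclusive (GFF3 convention) throughout the
#' package. Rows are sorted by (replicon_id, start).
#'
#' @param gene_id,replicon_id Identifiers.
#' @param start,end 1-based inclusive coordinates, start <= end.
#' @param strand "+" or "-".
#' @param product Free-text product description.
#' @param kegg_id KEGG ortholog id or NA.
#' @param protein_seq Amino-acid sequence or NA.
#' @return data.frame with class `gene_table`.
#' @export
gene_table <- function(gene_id, replicon_id, start, end, strand = "+",
                       product = NA_character_, kegg_id = NA_character_,
                       protein_seq = NA_character_) {
  n <- length(gene_id)
  df <- data.frame(
    gene_id = as.character(gene_id),
    replicon_id = rep_len(as.character(replicon_id), n),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    product = rep_len(as.character(product), n),
    kegg_id = rep_len(as.character(kegg_id), n),
    protein_seq = rep_len(as.character(protein_seq), n),
    stringsAsFactors = FALSE
  )
  validate_gene_table(df)
}

validate_gene_table <- function(df) {
  if (nrow(df) > 0) {
    if (any(df$start < 1)) stop("gene start coordinates must be >= 1")
    bad <- which(df$end < df$start)
    if (length(bad) > 0) {
      stop("gene end < start for: ", paste(df$gene_id[bad], collapse = ", "))
    }
    if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    df <- df[order(df$replicon_id, df$start), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Construct a genome record
#'
#' @param genome_id Unique genome identifier.
#' @param lineage_id Non-empty species/lineage tag (e.g. "AFE").
#' @param genome_size_bp Total genome size in bp.
#' @param replicons A [replicon_table()].
#' @param genes A [gene_table()].
#' @param completeness_pct Assembly completeness, 0-100, or NA.
#' @param optimal_growth_ph Optimal growth pH or NA.
#' @return Object of class `genome_record`.
#' @export
genome_record <- function(genome_id, lineage_id, genome_size_bp,
                          replicons = replicon_table(character(), integer()),
                          genes = gene_table(character(), character(),
                                             integer(), integer()),
                          completeness_pct = NA_real_,
                          optimal_growth_ph = NA_real_) {
  stopifnot(nzchar(genome_id), nzchar(lineage_id), genome_size_bp >= 0)
  if (!is.na(completeness_pct)) {
    stopifnot(completeness_pct >= 0, completeness_pct <= 100)
  }
  g <- list(
    genome_id = as.character(genome_id),
    lineage_id = as.character(lineage_id),
    genome_size_bp = as.numeric(genome_size_bp),
    completeness_pct = completeness_pct,
    optimal_growth_ph = optimal_growth_ph,
    replicons = replicons,
    genes = validate_gene_table(as.data.frame(genes))
  )
  class(g) <- "genome_record"
  g
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s [%s] %.0f bp, %d replicon(s), %d gene(s)\n",
              x$genome_id, x$lineage_id, x$genome_size_bp,
              nrow(x$replicons), nrow(x$genes)))
  invisible(x)
}
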