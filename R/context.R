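# Gap in bp between two 1-based inclusive intervals on one replicon
# (0 when they touch or overlap); on circular replicons the shorter way
# around is used.
interval_gap <- function(s1, e1, s2, e2, circular = FALSE,
                         length_bp = NA_integer_) {
  direct <- max(0L, max(s1, s2) - min(e1, e2))
  if (!circular || is.na(length_bp)) return(direct)
  # wrap-around gap: from the right end of the downstream interval through
  # the origin to the left start of the upstream interval
  wrap <- max(0L, length_bp - max(e1, e2) + min(s1, s2) - 1L)
  min(direct, wrap)
}

#' Genes within a window around a query gene
#'
#' Returns the CDS (excluding the query itself) on the same replicon whose
#' span lies within `window` bp of the query's span, i.e. whose span
#' intersects `[start - window, end + window]`. On circular replicons the
#' window wraps around the origin. The window is measured from gene
#' boundaries; partial overlap counts; strand is ignored.
#'
#' @param gene_id Query gene id (must be present in `genes`).
#' @param genes A [gene_table()].
#' @param window Window in bp on each side (default 5000).
#' @param replicons Optional [replicon_table()] supplying topology and
#'   length; without it all replicons are treated as linear.
#' @return The neighboring rows of `genes`.
#' @export
neighborhood <- function(gene_id, genes, window = 5000, replicons = NULL) {
  i <- match(gene_id, genes$gene_id)
  if (is.na(i)) stop("gene not found: ", gene_id)
  g <- genes[i, ]
  circular <- FALSE
  len <- NA_integer_
  if (!is.null(replicons)) {
    j <- match(g$replicon_id, replicons$replicon_id)
    if (!is.na(j)) {
      circular <- replicons$topology[j] == "circular"
      len <- replicons$length_bp[j]
    }
  }
  same <- genes[genes$replicon_id == g$replicon_id &
                  genes$gene_id != gene_id, , drop = FALSE]
  if (nrow(same) == 0) return(same)
  gaps <- mapply(interval_gap, same$start, same$end,
                 MoreArgs = list(s2 = g$start, e2 = g$end,
                                 circular = circular, length_bp = len))
  same[gaps <= window, , drop = FALSE]
}

#' KEGG-based vicinity frequency index
#'
#' For every NAP family x KEGG annotation pair, the percentage of the
#' family's genes that have at least one CDS bearing that annotation in
#' their vicinity. An annotation occurring on several neighbors of one NAP
#' gene is counted once; a multi-annotation CDS contributes once per
#' distinct KEGG id.
#'
#' @param candidates data.frame with columns gene_id and family (NAP genes).
#' @param genes A [gene_table()] covering candidates and their neighbors.
#' @param annotations data.frame (gene_id, kegg_id), possibly several rows
#'   per gene, or a named character vector gene_id -> kegg_id.
#' @param window Vicinity window in bp (default 5000).
#' @param replicons Optional [replicon_table()] for circular topology.
#' @param denominator "resolvable" (default): family genes present in
#'   `genes`; "annotated": family genes with at least one annotated
#'   neighbor.
#' @return data.frame: family, kegg_id, n_genes, n_with, frequency_pct;
#'   sorted by family then descending frequency.
#' @export
vicinity_frequency <- function(candidates, genes, annotations,
                               window = 5000, replicons = NULL,
                               denominator = c("resolvable", "annotated")) {
  denominator <- match.arg(denominator)
  if (!is.data.frame(annotations)) {
    annotations <- data.frame(gene_id = names(annotations),
                              kegg_id = unname(annotations),
                              stringsAsFactors = FALSE)
  }
  annotations <- annotations[!is.na(annotations$kegg_id), , drop = FALSE]
  cand <- candidates[candidates$gene_id %in% genes$gene_id, , drop = FALSE]
  out <- list()
  for (fam in unique(cand$family)) {
    fc <- cand[cand$family == fam, , drop = FALSE]
    per_gene <- lapply(fc$gene_id, function(gid) {
      nb <- neighborhood(gid, genes, window, replicons)
      unique(annotations$kegg_id[annotations$gene_id %in% nb$gene_id])
    })
    n_genes <- if (denominator == "resolvable") length(per_gene) else
      sum(vapply(per_gene, length, integer(1)) > 0)
    if (n_genes == 0) next
    keggs <- sort(unique(unlist(per_gene)))
    if (length(keggs) == 0) next
    n_with <- vapply(keggs, function(k) {
      sum(vapply(per_gene, function(v) k %in% v, logical(1)))
    }, integer(1))
    df <- data.frame(family = fam, kegg_id = keggs,
                     n_genes = n_genes, n_with = n_with,
                     frequency_pct = round(100 * n_with / n_genes, 2),
                     stringsAsFactors = FALSE)
    out[[fam]] <- df[order(-df$frequency_pct, df$kegg_id), , drop = FALSE]
  }
  if (length(out) == 0) {
    return(data.frame(family = character(), kegg_id = character(),
                      n_genes = integer(), n_with = integer(),
                      frequency_pct = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Origin-relative gene position
#'
#' Fraction of the replicon from the origin of replication to the gene
#' midpoint, measured in the direction of increasing coordinates on
#' circular coordinates (`((midpoint - ori) mod length) / length`), with
#' the replicon split into four equal quadrants Q1-Q4 starting at the
#' origin.
#'
#' @param gene One-row [gene_table()] slice or list with start and end.
#' @param replicon One-row [replicon_table()] slice with `ori_pos` set.
#' @return List: gene_id, replicon_id, fraction_from_ori in [0, 1),
#'   quadrant.
#' @export
relative_position <- function(gene, replicon) {
  if (is.na(replicon$ori_pos)) stop("replicon has no ori_pos")
  len <- as.numeric(replicon$length_bp)
  mid <- floor((gene$start + gene$end) / 2)
  frac <- ((mid - replicon$ori_pos) %% len) / len
  list(
    gene_id = if (!is.null(gene$gene_id)) gene$gene_id else NA_character_,
    replicon_id = replicon$replicon_id,
    fraction_from_ori = frac,
    quadrant = paste0("Q", pmin(4L, floor(frac * 4) + 1L))
  )
}
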