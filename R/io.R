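#' Read a gene table from GFF3 or TSV
#'
#' GFF3 files are parsed with rtracklayer; only CDS/gene-like rows carrying
#' an ID (or locus_tag) are returned. TSV files must carry the columns of
#' [gene_table()] (gene_id, replicon_id, start, end, strand; product,
#' kegg_id and protein_seq optional). Coordinates are 1-based inclusive.
#'
#' @param path Input file.
#' @param format "gff3" or "tsv".
#' @return A [gene_table()] sorted by (replicon_id, start).
#' @export
read_gene_table <- function(path, format = c("gff3", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "gff3") {
    if (length(readLines(path, warn = FALSE)) == 0 ||
        all(grepl("^#|^\\s*$", readLines(path, warn = FALSE)))) {
      return(gene_table(character(), character(), integer(), integer()))
    }
    gr <- tryCatch(
      rtracklayer::import(path, format = "gff3"),
      error = function(e) stop("GFF3 parse error in ", path, ": ",
                               conditionMessage(e))
    )
    if (length(gr) == 0) {
      return(gene_table(character(), character(), integer(), integer()))
    }
    md <- S4Vectors::mcols(gr)
    ids <- if ("ID" %in% colnames(md)) as.character(md$ID) else
      rep(NA_character_, length(gr))
    if ("locus_tag" %in% colnames(md)) {
      lt <- as.character(md$locus_tag)
      ids <- ifelse(is.na(ids) | !nzchar(ids), lt, ids)
    }
    ids[is.na(ids) | !nzchar(ids)] <-
      paste0("feature_", seq_len(length(gr)))[is.na(ids) | !nzchar(ids)]
    prod <- if ("product" %in% colnames(md)) as.character(md$product) else
      NA_character_
    kegg <- if ("kegg_id" %in% colnames(md)) as.character(md$kegg_id) else
      NA_character_
    strand <- as.character(BiocGenerics::strand(gr))
    strand[!strand %in% c("+", "-")] <- "+"
    gene_table(
      gene_id = ids,
      replicon_id = as.character(GenomicRanges::seqnames(gr)),
      start = BiocGenerics::start(gr),
      end = BiocGenerics::end(gr),
      strand = strand,
      product = prod,
      kegg_id = kegg
    )
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
    if (nrow(df) == 0) {
      return(gene_table(character(), character(), integer(), integer()))
    }
    need <- c("gene_id", "replicon_id", "start", "end")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0) {
      stop("gene TSV missing columns: ", paste(miss, collapse = ", "))
    }
    gene_table(
      gene_id = df$gene_id, replicon_id = df$replicon_id,
      start = df$start, end = df$end,
      strand = if ("strand" %in% names(df)) df$strand else "+",
      product = if ("product" %in% names(df)) df$product else NA_character_,
      kegg_id = if ("kegg_id" %in% names(df)) df$kegg_id else NA_character_,
      protein_seq = if ("protein_seq" %in% names(df)) df$protein_seq else
        NA_character_
    )
  }
}

#' Write a gene table as TSV
#'
#' Inverse of `read_gene_table(path, format = "tsv")`; round-trips all
#' fields.
#'
#' @param genes A [gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(as.data.frame(genes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a domain-hit table
#'
#' TSV with header columns protein_id, profile_id, evalue, probability,
#' coverage. probability (percent, 0-100) and coverage (fraction, 0-1) may
#' be empty/NA. Unknown columns are dropped with a warning.
#'
#' @param path Input TSV.
#' @return data.frame of hits (one row per hit).
#' @export
read_domain_hits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("protein_id", "profile_id", "evalue")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("hit TSV missing columns: ", paste(miss, collapse = ", "))
  }
  extra <- setdiff(names(df), c(need, "probability", "coverage"))
  if (length(extra) > 0) {
    warning("ignoring unknown hit columns: ", paste(extra, collapse = ", "))
  }
  if (!"probability" %in% names(df)) df$probability <- NA_real_
  if (!"coverage" %in% names(df)) df$coverage <- NA_real_
  df <- df[, c(need, "probability", "coverage")]
  df$evalue <- as.numeric(df$evalue)
  df$probability <- as.numeric(df$probability)
  df$coverage <- as.numeric(df$coverage)
  if (nrow(df) > 0) {
    if (any(is.na(df$evalue)) || any(df$evalue < 0)) {
      stop("evalue must be a non-negative number")
    }
    p <- df$probability[!is.na(df$probability)]
    if (any(p < 0 | p > 100)) stop("probability must lie in [0, 100]")
  }
  df
}

#' Write a domain-hit table as TSV
#'
#' @param hits data.frame as returned by [read_domain_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' bedGraph intervals are 0-based half-open on disk; they are expanded to a
#' 1-based per-base depth vector per replicon.
#'
#' @param path bedGraph file.
#' @return Named list: one numeric per-base depth vector per replicon.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- list()
  for (chr in unique(as.character(GenomicRanges::seqnames(gr)))) {
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == chr]
    len <- max(BiocGenerics::end(sub))
    depth <- numeric(len)
    for (i in seq_along(sub)) {
      depth[BiocGenerics::start(sub)[i]:BiocGenerics::end(sub)[i]] <-
        sub$score[i]
    }
    out[[chr]] <- depth
  }
  out
}

#' Write a per-base depth vector as bedGraph
#'
#' Runs of equal depth are collapsed into intervals (0-based half-open on
#' disk).
#'
#' @param depth Named list of per-base numeric depth vectors (or a single
#'   vector, with `replicon_id` supplied).
#' @param path Output path.
#' @param replicon_id Replicon name when `depth` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(depth, path, replicon_id = "chr") {
  if (!is.list(depth)) depth <- stats::setNames(list(depth), replicon_id)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (chr in names(depth)) {
    d <- depth[[chr]]
    r <- rle(d)
    ends <- cumsum(r$lengths)
    starts0 <- ends - r$lengths  # 0-based starts
    writeLines(sprintf("%s\t%d\t%d\t%g", chr, starts0, ends, r$values), con)
  }
  invisible(path)
}
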