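#' Bin a per-base depth vector
#'
#' Each bin holds the mean per-base depth over `bin_size` bases; the final
#' partial bin is averaged over its actual width.
#'
#' @param depth Numeric per-base depth vector (values >= 0).
#' @param bin_size Bin width in bp (default 10).
#' @return Numeric vector of raw bins, with attributes `bin_size` and
#'   `length_bp`.
#' @export
bin_coverage <- function(depth, bin_size = 10) {
  if (bin_size < 1) stop("bin_size must be >= 1")
  if (any(depth < 0)) stop("depth values must be >= 0")
  n <- length(depth)
  if (n == 0) stop("empty depth vector")
  idx <- rep(seq_len(ceiling(n / bin_size)), each = bin_size)[seq_len(n)]
  bins <- as.numeric(tapply(depth, idx, mean))
  attr(bins, "bin_size") <- as.integer(bin_size)
  attr(bins, "length_bp") <- n
  bins
}

bin_widths <- function(n_bases, bin_size, n_bins) {
  w <- rep(bin_size, n_bins)
  rem <- n_bases - (n_bins - 1) * bin_size
  w[n_bins] <- rem
  w
}

#' Normalize binned coverage to 1x genomic content (RPGC)
#'
#' Divides every raw bin by the scaling factor
#' `s = total per-base signal / effective_genome_size`, i.e. the
#' genome-wide mean depth over the effective genome, so the normalized
#' track averages 1.0 over the effective genome. Idempotent, and invariant
#' under rescaling of the raw depths.
#'
#' @param raw_bins Output of [bin_coverage()], or an existing
#'   `coverage_track` (re-normalized).
#' @param effective_genome_size Effective genome size in bp; defaults to
#'   the track length.
#' @param replicon_id Replicon name stored in the track.
#' @return Object of class `coverage_track`: replicon_id, bin_size_bp,
#'   bins (normalized), effective_genome_size_bp, genome_mean_raw.
#' @export
rpgc_normalize <- function(raw_bins, effective_genome_size = NULL,
                           replicon_id = "chr") {
  if (inherits(raw_bins, "coverage_track")) {
    tr <- raw_bins
    bins <- tr$bins
    bin_size <- tr$bin_size_bp
    length_bp <- tr$length_bp
    if (is.null(effective_genome_size)) {
      effective_genome_size <- tr$effective_genome_size_bp
    }
    replicon_id <- tr$replicon_id
  } else {
    bins <- as.numeric(raw_bins)
    bin_size <- attr(raw_bins, "bin_size")
    length_bp <- attr(raw_bins, "length_bp")
    if (is.null(bin_size) || is.null(length_bp)) {
      stop("raw_bins must come from bin_coverage()")
    }
  }
  if (is.null(effective_genome_size)) effective_genome_size <- length_bp
  w <- bin_widths(length_bp, bin_size, length(bins))
  total_signal <- sum(bins * w)
  if (total_signal <= 0) stop("zero total signal")
  s <- total_signal / effective_genome_size
  out <- list(
    replicon_id = replicon_id,
    bin_size_bp = as.integer(bin_size),
    length_bp = as.integer(length_bp),
    bins = bins / s,
    effective_genome_size_bp = as.numeric(effective_genome_size),
    genome_mean_raw = total_signal / length_bp
  )
  class(out) <- "coverage_track"
  out
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "<coverage_track> %s: %d bins of %d bp (%d bp), raw mean %.3f\n",
    x$replicon_id, length(x$bins), x$bin_size_bp, x$length_bp,
    x$genome_mean_raw))
  invisible(x)
}

# Mean normalized coverage over a 1-based inclusive base interval.
track_mean <- function(track, start, end) {
  if (start < 1 || end > track$length_bp || end < start) {
    stop("interval outside track: ", start, "-", end)
  }
  bs <- track$bin_size_bp
  b1 <- (start - 1) %/% bs + 1
  b2 <- (end - 1) %/% bs + 1
  total <- 0
  for (b in b1:b2) {
    lo <- max(start, (b - 1) * bs + 1)
    hi <- min(end, b * bs)
    total <- total + track$bins[b] * (hi - lo + 1)
  }
  total / (end - start + 1)
}

#' Per-gene expression relative to the genome average
#'
#' Mean normalized (RPGC) coverage per gene, for a focus gene and the
#' genes within `flank_bp` of it (all genes on the track when
#' `focus_gene` is NULL). Genes averaging below 1.0 — the genome-wide
#' average by construction of RPGC — are flagged.
#'
#' @param track A `coverage_track` from [rpgc_normalize()].
#' @param genes A [gene_table()] on the track's replicon.
#' @param focus_gene Optional gene id to center on.
#' @param flank_bp Flank around the focus gene (default 5000).
#' @return data.frame: gene_id, start, end, mean_rpgc, below_average.
#' @export
locus_expression <- function(track, genes, focus_gene = NULL,
                             flank_bp = 5000) {
  g <- genes[genes$replicon_id == track$replicon_id |
               length(unique(genes$replicon_id)) == 1, , drop = FALSE]
  if (!is.null(focus_gene)) {
    i <- match(focus_gene, g$gene_id)
    if (is.na(i)) stop("focus gene not found: ", focus_gene)
    lo <- g$start[i] - flank_bp
    hi <- g$end[i] + flank_bp
    g <- g[g$end >= lo & g$start <= hi, , drop = FALSE]
  }
  if (nrow(g) == 0) stop("no genes on track")
  mean_rpgc <- vapply(seq_len(nrow(g)), function(i) {
    track_mean(track, g$start[i], g$end[i])
  }, numeric(1))
  data.frame(
    gene_id = g$gene_id, start = g$start, end = g$end,
    mean_rpgc = mean_rpgc, below_average = mean_rpgc < 1.0,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
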