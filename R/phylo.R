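#' Read an aligned (or plain) protein FASTA
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Pairwise dissimilarity matrix from an alignment
#'
#' For each pair of aligned sequences, the fraction of differing columns
#' among the columns where neither sequence has a gap (pairwise deletion),
#' expressed on the 100 - %identity dissimilarity scale.
#'
#' @param aligned_seqs Named character vector of equal-length aligned
#'   sequences (gap = "-"), at least 2.
#' @return Symmetric numeric matrix (zero diagonal) of dissimilarities in
#'   [0, 100].
#' @export
p_distance_matrix <- function(aligned_seqs) {
  n <- length(aligned_seqs)
  if (n < 2) stop("need at least 2 sequences")
  lens <- nchar(aligned_seqs)
  if (length(unique(lens)) != 1) stop("sequences must be aligned (equal length)")
  m <- do.call(rbind, strsplit(aligned_seqs, ""))
  taxa <- names(aligned_seqs)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(shared)) stop("no shared non-gap columns between ",
                             taxa[i], " and ", taxa[j])
      p <- mean(m[i, shared] != m[j, shared])
      d[i, j] <- d[j, i] <- 100 * p
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining (via ape); negative branch
#' lengths are clamped to zero. Additive input metrics are recovered
#' exactly.
#'
#' @param dm Symmetric numeric matrix with zero diagonal, >= 3 taxa.
#' @return Unrooted `phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  if (any(diag(dm) != 0)) stop("diagonal must be zero")
  tree <- ape::nj(as.dist(dm))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Robinson-Foulds distance between two trees
#'
#' Number of bipartitions present in exactly one of the two unrooted
#' trees (unweighted). Zero means identical topologies.
#'
#' @param t1,t2 `phylo` trees (or Newick strings) on the same leaf set.
#' @return Non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  if (is.character(t1)) t1 <- ape::read.tree(text = t1)
  if (is.character(t2)) t2 <- ape::read.tree(text = t2)
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees must share an identical leaf set")
  }
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

#' Synthetic 16-lineage reference tree
#'
#' A rooted binary reference tree over the 16 lineage tags used by the
#' packaged census fixture, with branch lengths on the per-site divergence
#' scale of conserved single-copy markers (maximum pairwise distance
#' around 0.12 substitutions/site). It serves as ground truth for
#' marker-recovery experiments: sequences evolved along it by
#' [generate_marker_sequences()] should, for long markers, yield a
#' neighbor-joining tree with Robinson-Foulds distance zero to it.
#'
#' @return A rooted `phylo` object with 16 tips.
#' @export
reference_class_tree <- function() {
  nwk <- paste0(
    "(((TTP:0.030,AMS:0.028):0.015,((ICO:0.012,IYE:0.014):0.020,",
    "FCA:0.030):0.012):0.012,(((ATH:0.015,ACO:0.013):0.012,",
    "(ASU:0.014,(AMA:0.012,AMO:0.013):0.012):0.012):0.015,",
    "((AFE:0.012,(AFG:0.010,AFD:0.011):0.012):0.012,",
    "((AFP:0.012,AFV:0.013):0.012,AFN:0.020):0.012):0.015):0.012);")
  ape::read.tree(text = nwk)
}
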