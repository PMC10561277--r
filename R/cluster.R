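.pkg_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

check_aa_string <- function(seq, what = "sequence") {
  if (length(seq) != 1 || is.na(seq) || nchar(seq) == 0) {
    stop(what, " must be a non-empty amino-acid string")
  }
  aa <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(aa), rownames(blosum62()))
  if (length(bad) > 0) {
    stop(what, " contains non-amino-acid characters: ",
         paste(bad, collapse = ", "))
  }
  paste(aa, collapse = "")
}

#' Global alignment identity between two proteins
#'
#' Needleman-Wunsch global alignment (BLOSUM62; a gap of length L costs
#' `10 + L`). Identity is matches divided by total alignment columns,
#' gap columns included; coverage is the aligned (non-gap) span of the
#' shorter sequence divided by its length, which for a global alignment is
#' 1 by construction.
#'
#' @param seq_a,seq_b Non-empty amino-acid strings.
#' @return Named list: identity, coverage, score.
#' @export
global_align_identity <- function(seq_a, seq_b) {
  seq_a <- check_aa_string(seq_a, "seq_a")
  seq_b <- check_aa_string(seq_b, "seq_b")
  pa <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global",
    substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 1
  )
  al_a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  al_b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ncol_aln <- length(al_a)
  matches <- sum(al_a == al_b & al_a != "-")
  shorter_len <- min(nchar(seq_a), nchar(seq_b))
  shorter <- if (nchar(seq_a) <= nchar(seq_b)) al_a else al_b
  coverage <- sum(shorter != "-") / shorter_len
  list(identity = matches / ncol_aln, coverage = coverage,
       score = Biostrings::score(pa))
}

#' Greedy centroid clustering at an identity threshold
#'
#' Sequences are processed sorted by length descending (ties broken by
#' lexicographic id, so the result is independent of input order). Each
#' sequence joins the first existing centroid it matches at
#' `identity >= threshold` under [global_align_identity()]; otherwise it
#' opens a new cluster with itself as centroid.
#'
#' @param seqs Named character vector of protein sequences.
#' @param threshold Identity threshold in (0, 1].
#' @param family Optional named character vector protein_id -> family
#'   label; a cluster inherits its centroid's family.
#' @return data.frame: pf_id, family, protein_id, is_centroid.
#' @export
greedy_identity_cluster <- function(seqs, threshold = 0.50, family = NULL) {
  if (length(seqs) < 1) stop("need at least one sequence")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named")
  }
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  ord <- order(-nchar(seqs), names(seqs))
  ids <- names(seqs)[ord]
  centroids <- character(0)
  assignment <- stats::setNames(character(length(ids)), ids)
  for (id in ids) {
    placed <- FALSE
    for (c_id in centroids) {
      aln <- global_align_identity(seqs[[id]], seqs[[c_id]])
      if (aln$identity >= threshold) {
        assignment[[id]] <- c_id
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, id)
      assignment[[id]] <- id
    }
  }
  pf_ids <- stats::setNames(sprintf("PF%04d", seq_along(centroids)),
                            centroids)
  fam <- function(id) {
    if (!is.null(family) && id %in% names(family)) family[[id]]
    else NA_character_
  }
  out <- data.frame(
    pf_id = unname(pf_ids[assignment[ids]]),
    family = vapply(unname(assignment[ids]), fam, character(1)),
    protein_id = ids,
    is_centroid = ids == assignment[ids],
    stringsAsFactors = FALSE
  )
  out[order(out$pf_id, out$protein_id), , drop = FALSE]
}

# Best hit of each query into each target genome: max score, then min
# e-value, then lexicographic subject.
best_hits_by_genome <- function(hits, genome_of) {
  hits$qg <- genome_of[hits$query]
  hits$sg <- genome_of[hits$subject]
  hits <- hits[hits$qg != hits$sg, , drop = FALSE]
  ord <- order(hits$query, hits$sg, -hits$score, hits$evalue, hits$subject)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(paste(hits$query, hits$sg, sep = "\r")), , drop = FALSE]
}

#' Reciprocal-best-hit triangle clustering
#'
#' Pairwise hits are first filtered to `coverage >= th$bbh_coverage` and
#' `evalue <= th$bbh_evalue`. Bidirectional best hits (BBH) are computed
#' between genome pairs (best = maximum score, ties broken by minimum
#' e-value then lexicographic subject id). Triangles of BBH edges spanning
#' three distinct genomes seed protein families; triangles sharing an edge
#' (hence two proteins) are merged, and any vertex-sharing cluster pair is
#' merged as well so that the output partitions the input. Proteins in no
#' triangle remain singletons.
#'
#' @param hits data.frame with columns query, subject, coverage, score,
#'   evalue (identity optional).
#' @param genome_of Named character vector protein_id -> genome_id,
#'   covering every protein in the analysis (defines the protein
#'   universe).
#' @param th A [nap_thresholds()].
#' @return data.frame: pf_id, protein_id, is_centroid (centroid =
#'   lexicographically smallest member), in_triangle.
#' @export
bbh_triangle_cluster <- function(hits, genome_of, th = nap_thresholds()) {
  prots <- sort(names(genome_of))
  unknown <- setdiff(unique(c(hits$query, hits$subject)), prots)
  if (length(unknown) > 0) {
    stop("hits reference proteins with unknown genome: ",
         paste(unknown, collapse = ", "))
  }
  keep <- (is.na(hits$coverage) | hits$coverage >= th$bbh_coverage) &
    hits$evalue <= th$bbh_evalue
  h <- hits[keep, , drop = FALSE]
  edges <- character(0)
  if (nrow(h) > 0) {
    bh <- best_hits_by_genome(h, genome_of)
    fwd <- paste(bh$query, bh$subject, sep = "\r")
    rev <- paste(bh$subject, bh$query, sep = "\r")
    mutual <- fwd[fwd %in% rev]
    if (length(mutual) > 0) {
      # undirected, deduplicated edge list
      pairs <- unique(t(apply(
        do.call(rbind, strsplit(mutual, "\r")), 1, sort)))
      edges <- paste(pairs[, 1], pairs[, 2], sep = "\r")
    }
  }
  # adjacency for triangle enumeration
  adj <- list()
  for (e in edges) {
    pq <- strsplit(e, "\r")[[1]]
    adj[[pq[1]]] <- c(adj[[pq[1]]], pq[2])
    adj[[pq[2]]] <- c(adj[[pq[2]]], pq[1])
  }
  parent <- stats::setNames(prots, prots)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[[max(ra, rb)]] <<- min(ra, rb)
  }
  in_tri <- stats::setNames(rep(FALSE, length(prots)), prots)
  for (e in edges) {
    pq <- strsplit(e, "\r")[[1]]
    p <- pq[1]; q <- pq[2]
    common <- intersect(adj[[p]], adj[[q]])
    for (r in common) {
      gs <- unique(genome_of[c(p, q, r)])
      if (length(gs) == 3) {
        union2(p, q); union2(q, r)
        in_tri[c(p, q, r)] <- TRUE
      }
    }
  }
  comp <- vapply(prots, find, character(1))
  comp_ids <- sort(unique(comp))
  pf_ids <- stats::setNames(sprintf("PF%04d", seq_along(comp_ids)), comp_ids)
  out <- data.frame(
    pf_id = unname(pf_ids[comp]),
    protein_id = prots,
    is_centroid = prots == comp,
    in_triangle = unname(in_tri[prots]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$pf_id, out$protein_id), , drop = FALSE]
}
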