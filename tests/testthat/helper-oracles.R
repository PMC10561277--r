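# Independent oracles used to cross-check the package's implementations on
# tiny inputs. Deliberately naive: enumeration and direct definitions only.

# --- exhaustive global alignment oracle (affine gaps: length-L gap costs
# --- open + L * ext, matching the package aligner's convention) ----------
oracle_align <- function(a, b, open = 10, ext = 1) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- new.env()
  best$score <- -Inf
  best$identities <- numeric(0)
  recurse <- function(i, j, score, matches, cols, prev) {
    if (i > length(av) && j > length(bv)) {
      if (score > best$score) {
        best$score <- score
        best$identities <- matches / cols
      } else if (score == best$score) {
        best$identities <- unique(c(best$identities, matches / cols))
      }
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      s <- B[av[i], bv[j]]
      recurse(i + 1, j + 1, score + s, matches + (av[i] == bv[j]),
              cols + 1, "M")
    }
    if (i <= length(av)) {  # gap in b
      cost <- if (prev == "I") ext else open + ext
      recurse(i + 1, j, score - cost, matches, cols + 1, "I")
    }
    if (j <= length(bv)) {  # gap in a
      cost <- if (prev == "D") ext else open + ext
      recurse(i, j + 1, score - cost, matches, cols + 1, "D")
    }
  }
  recurse(1, 1, 0, 0, 0, "M")
  list(score = best$score, identities = best$identities)
}

# --- brute-force BBH triangle clustering oracle --------------------------
oracle_bbh_triangles <- function(hits, genome_of, th = nap_thresholds()) {
  prots <- sort(names(genome_of))
  keep <- (is.na(hits$coverage) | hits$coverage >= th$bbh_coverage) &
    hits$evalue <= th$bbh_evalue
  h <- hits[keep, , drop = FALSE]
  best_of <- function(q, tg) {
    rows <- h[h$query == q & genome_of[h$subject] == tg &
                genome_of[h$query] != tg, , drop = FALSE]
    if (nrow(rows) == 0) return(NA_character_)
    rows <- rows[order(-rows$score, rows$evalue, rows$subject), ,
                 drop = FALSE]
    rows$subject[1]
  }
  is_bbh <- function(p, q) {
    identical(best_of(p, genome_of[[q]]), q) &&
      identical(best_of(q, genome_of[[p]]), p)
  }
  # all protein triples spanning three genomes with all edges mutual
  comp <- stats::setNames(seq_along(prots), prots)
  if (length(prots) >= 3) {
    trios <- utils::combn(prots, 3)
    for (k in seq_len(ncol(trios))) {
      t3 <- trios[, k]
      if (length(unique(genome_of[t3])) != 3) next
      if (is_bbh(t3[1], t3[2]) && is_bbh(t3[2], t3[3]) &&
          is_bbh(t3[1], t3[3])) {
        cid <- min(comp[t3])
        comp[comp %in% comp[t3]] <- cid
      }
    }
  }
  # canonical partition as sorted list of sorted member vectors
  parts <- split(prots, comp[prots])
  unname(lapply(parts[order(vapply(parts, min, character(1)))], sort))
}

# --- brute-force inverted repeat oracle ----------------------------------
# Checks every (left_start, stem, loop) candidate directly against the
# definition. Stems are enumerated up to `max_stem` (callers assert the
# implementation reports nothing longer on the tested sequences).
oracle_inverted_repeats <- function(seq, min_stem, max_loop,
                                    max_mismatch = 0, max_stem = 40) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  x <- strsplit(toupper(seq), "")[[1]]
  n <- length(x)
  # mismatch indicator for position pairs at a fixed gap g: entry p tests
  # the pair (p, p + g); N never matches, a base never pairs with itself
  max_gap <- 2 * max_stem + max_loop + 2
  gap_mism <- lapply(0:max_gap, function(g) {
    if (g >= n) return(integer(0))
    p <- seq_len(n - g)
    q <- p + g
    as.integer(!(x[p] != "N" & x[q] != "N" & comp[x[p]] == x[q] & g > 0))
  })
  mm_pair <- function(p, q) {
    if (p < 1 || q > n || q < p) return(NA_integer_)
    gap_mism[[q - p + 1]][p]
  }
  out <- list()
  for (stem in min_stem:max_stem) {
    for (loop in 0:max_loop) {
      width <- 2 * stem + loop
      if (width > n) next
      nls <- n - width + 1
      mm <- integer(nls)
      for (k in 0:(stem - 1)) {
        g <- loop + 1 + 2 * k
        pvec <- seq_len(nls) + stem - 1 - k
        mm <- mm + gap_mism[[g + 1]][pvec]
      }
      for (ls in which(mm <= max_mismatch)) {
        le <- ls + stem - 1; rs <- le + loop + 1; re <- rs + stem - 1
        inward <- if (loop >= 2) mm_pair(le + 1, rs - 1) else NA_integer_
        outward <- mm_pair(ls - 1, re + 1)
        inward_ok <- !is.na(inward) && mm[ls] + inward <= max_mismatch
        outward_ok <- !is.na(outward) && mm[ls] + outward <= max_mismatch
        if (inward_ok || outward_ok) next
        out[[length(out) + 1]] <- c(ls, le, rs, re, stem, loop, mm[ls])
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      stem_len = integer(), loop_len = integer(),
                      mismatches = integer()))
  }
  m <- unique(do.call(rbind, out))
  df <- data.frame(left_start = m[, 1], left_end = m[, 2],
                   right_start = m[, 3], right_end = m[, 4],
                   stem_len = m[, 5], loop_len = m[, 6],
                   mismatches = m[, 7])
  df <- df[order(df$left_start, df$right_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# --- shared builders ------------------------------------------------------
random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n, seed) {
  aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  set.seed(seed)
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# a small two-lineage pangenome spec used across tests
small_spec <- function(seed = 1, mge_rate = 1, n1 = 10, n2 = 5) {
  lins <- data.frame(lineage_id = c("L1", "L2"), n_genomes = c(n1, n2),
                     mean_genome_size_bp = 3e5, size_sd = 2e4)
  fams <- data.frame(lineage_id = rep(c("L1", "L2"), each = 2),
                     family = rep(c("HU", "KfrA"), 2),
                     presence_fraction = c(1, 0.5, 1, 0.5),
                     dose_min = 1, dose_max = c(3, 2, 2, 1))
  pangenome_spec(lins, fams, mge_rate = mge_rate, seed = seed)
}

genome_meta <- function(pg) {
  data.frame(
    genome_id = names(pg$genomes),
    lineage_id = vapply(pg$genomes, function(g) g$lineage_id, character(1)),
    stringsAsFactors = FALSE
  )
}
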