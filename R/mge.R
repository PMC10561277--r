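#' Construct an MGE region table
#'
#' @param element_id Element identifiers (unique).
#' @param replicon_id Host replicon.
#' @param start,end 1-based inclusive bounds (ignored for whole-replicon
#'   elements).
#' @param whole_replicon TRUE for plasmid replicons treated as one element.
#' @return data.frame of regions.
#' @export
mge_region_table <- function(element_id, replicon_id, start = NA_integer_,
                             end = NA_integer_, whole_replicon = FALSE) {
  n <- length(element_id)
  df <- data.frame(
    element_id = as.character(element_id),
    replicon_id = rep_len(as.character(replicon_id), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    whole_replicon = rep_len(as.logical(whole_replicon), n),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(df$element_id))
  bad <- !df$whole_replicon & (is.na(df$start) | is.na(df$end) |
                                 df$end < df$start)
  if (any(bad)) stop("integrated regions need start <= end")
  df
}

#' Map NAP candidates to MGE regions
#'
#' A NAP is assigned to a region iff its gene midpoint lies within the
#' region's span, or its replicon is a whole-replicon (plasmid) element.
#' When regions nest or overlap, the innermost (shortest) wins, so no gene
#' is assigned twice.
#'
#' @param candidates data.frame with protein_id, gene_id, family.
#' @param genes A [gene_table()] resolving candidate gene coordinates.
#' @param regions An [mge_region_table()].
#' @return data.frame: element_id, protein_id, gene_id, family.
#' @export
map_naps_to_mges <- function(candidates, genes, regions) {
  out <- list()
  span <- function(r) {
    if (regions$whole_replicon[r]) Inf
    else regions$end[r] - regions$start[r] + 1
  }
  for (i in seq_len(nrow(candidates))) {
    j <- match(candidates$gene_id[i], genes$gene_id)
    if (is.na(j)) next
    mid <- floor((genes$start[j] + genes$end[j]) / 2)
    hit <- which(regions$replicon_id == genes$replicon_id[j] &
                   (regions$whole_replicon |
                      (!is.na(regions$start) & regions$start <= mid &
                         mid <= regions$end)))
    if (length(hit) == 0) next
    best <- hit[order(vapply(hit, span, numeric(1)), regions$element_id[hit])][1]
    out[[length(out) + 1]] <- data.frame(
      element_id = regions$element_id[best],
      protein_id = candidates$protein_id[i],
      gene_id = candidates$gene_id[i],
      family = candidates$family[i],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(element_id = character(), protein_id = character(),
                      gene_id = character(), family = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$element_id, res$protein_id), , drop = FALSE]
}

#' Classify a mobile element from its hallmark genes
#'
#' Rules, applied in order: a whole-replicon element is a `plasmid`; an
#' integrated element with both a type IV secretion system and an
#' integrase is an `ICE`; one with a relaxase and an integrase but no T4SS
#' is an `IME`; anything else is an `island`.
#'
#' @param whole_replicon Logical flag (plasmid replicon).
#' @param roles Character vector of hallmark roles present on the element
#'   (subset of relaxase, t4ss, integrase, transposase, toxin_antitoxin,
#'   parA, rm_system).
#' @return One of "plasmid", "ICE", "IME", "island".
#' @export
classify_element <- function(whole_replicon, roles) {
  if (isTRUE(whole_replicon)) return("plasmid")
  if ("t4ss" %in% roles && "integrase" %in% roles) return("ICE")
  if ("relaxase" %in% roles && "integrase" %in% roles &&
      !"t4ss" %in% roles) return("IME")
  "island"
}

#' Classify every region in a table
#'
#' @param regions An [mge_region_table()].
#' @param hallmarks data.frame (element_id, gene_id, role).
#' @return `regions` with an `mge_class` column added.
#' @export
classify_elements <- function(regions, hallmarks) {
  regions$mge_class <- vapply(seq_len(nrow(regions)), function(i) {
    roles <- hallmarks$role[hallmarks$element_id == regions$element_id[i]]
    classify_element(regions$whole_replicon[i], roles)
  }, character(1))
  regions
}

#' Map annotation keywords to hallmark roles
#'
#' Convenience mapper from free-text product annotations to MGE hallmark
#' roles: virB/trb/tra -> t4ss; mob/relaxase -> relaxase; xerD/integrase
#' -> integrase; transposase -> transposase; toxin/antitoxin ->
#' toxin_antitoxin; parA -> parA; restriction -> rm_system.
#'
#' @param products Character vector of product descriptions.
#' @return Character vector of roles (NA where no keyword matches).
#' @export
hallmark_role_from_product <- function(products) {
  p <- tolower(products)
  role <- rep(NA_character_, length(p))
  role[grepl("virb|\\btrb|\\btra\\b|t4ss|type iv secretion", p)] <- "t4ss"
  role[is.na(role) & grepl("relaxase|\\bmob", p)] <- "relaxase"
  role[is.na(role) & grepl("integrase|xerd|recombinase", p)] <- "integrase"
  role[is.na(role) & grepl("transposase", p)] <- "transposase"
  role[is.na(role) & grepl("toxin|antitoxin|addiction", p)] <-
    "toxin_antitoxin"
  role[is.na(role) & grepl("para|partitioning", p)] <- "parA"
  role[is.na(role) & grepl("restriction|methyltransferase", p)] <-
    "rm_system"
  role
}

#' Covariation between NAP counts and hallmark counts per genome
#'
#' Pearson correlation between per-genome counts of DNA-bending NAPs
#' (typically HU + IHF_A + IHF_B) and per-genome counts of a hallmark role
#' (e.g. relaxases or transposases).
#'
#' @param nap_counts Named numeric: NAP count per genome.
#' @param hallmark_counts Named numeric: hallmark gene count per genome.
#' @return A `correlation_result`.
#' @export
covariation <- function(nap_counts, hallmark_counts) {
  shared <- intersect(names(nap_counts), names(hallmark_counts))
  if (length(shared) < 3) stop("need at least 3 genomes")
  pearson(nap_counts[shared], hallmark_counts[shared],
          "nap_count", "hallmark_count")
}

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# TRUE when base at i pairs (Watson-Crick) with base at j; N never matches.
.pairs_ok <- function(chars, i, j) {
  a <- chars[i]; b <- chars[j]
  (a != "N") && (b != "N") && (.complement[[a]] == b)
}

#' Find maximal inverted repeats
#'
#' Exhaustive seed-and-extend scan for inverted repeats: a left arm and a
#' right arm of equal length (the stem) separated by a loop of 0 to
#' `max_loop` bases, the right arm being the reverse complement of the
#' left arm up to `max_mismatch` mismatched pairs (N never matches). Only
#' maximal repeats are reported: extending the stem by one pair inward or
#' outward must run off the sequence, close the loop below zero, or exceed
#' the mismatch budget. No two reported repeats share identical arm
#' coordinates.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param min_stem Minimum stem length (>= 4).
#' @param max_loop Maximum loop length.
#' @param max_mismatch Mismatch budget within the stem.
#' @return data.frame: left_start, left_end, right_start, right_end,
#'   stem_len, loop_len, mismatches; sorted by left_start.
#' @export
find_inverted_repeats <- function(seq, min_stem = 8, max_loop = 10,
                                  max_mismatch = 0) {
  if (min_stem < 4) stop("min_stem must be >= 4")
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) == 0) stop("empty sequence")
  bad <- setdiff(unique(chars), names(.complement))
  if (length(bad) > 0) {
    stop("invalid DNA characters: ", paste(bad, collapse = ", "))
  }
  n <- length(chars)
  mm_at <- function(i, j) {
    if (i < 1 || j > n) return(NA)  # out of bounds
    if (.pairs_ok(chars, i, j)) 0L else 1L
  }
  hits <- list()
  for (le in seq_len(n - 1)) {
    for (loop in 0:max_loop) {
      rs <- le + loop + 1
      if (rs > n) break
      # extend outward from innermost pair (le, rs)
      mm <- 0L
      stem <- 0L
      k <- 0L
      repeat {
        cost <- mm_at(le - k, rs + k)
        if (is.na(cost) || mm + cost > max_mismatch) break
        mm <- mm + cost
        stem <- stem + 1L
        k <- k + 1L
      }
      if (stem < min_stem) next
      # inward maximality: pair (le + 1, rs - 1) must not be addable
      if (loop >= 2) {
        inner_cost <- mm_at(le + 1, rs - 1)
        if (!is.na(inner_cost) && mm + inner_cost <= max_mismatch) next
      }
      hits[[length(hits) + 1]] <- data.frame(
        left_start = le - stem + 1L, left_end = le,
        right_start = rs, right_end = rs + stem - 1L,
        stem_len = stem, loop_len = loop, mismatches = mm
      )
    }
  }
  if (length(hits) == 0) {
    return(data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      stem_len = integer(), loop_len = integer(),
                      mismatches = integer()))
  }
  res <- unique(do.call(rbind, hits))
  res <- res[order(res$left_start, res$right_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Reverse complement of a DNA string
#' @param seq DNA string over A/C/G/T/N.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  paste(rev(unname(.complement[chars])), collapse = "")
}

#' Packaged oriT-like example sequence
#'
#' A synthetic origin-of-transfer-like sequence shipped with the package:
#' a random background carrying exactly two planted inverted repeats, with
#' stems of 8 and 10 nucleotides and 4-nucleotide loops, mimicking the
#' double-IR architecture found upstream of mobilization relaxase genes.
#' The background was verified to contain no other inverted repeat at
#' min_stem 6, max_loop 10, zero mismatches.
#'
#' @return DNA string.
#' @export
orit_example_sequence <- function() {
  path <- system.file("extdata", "orit_synthetic.fna", package = "nappan",
                      mustWork = TRUE)
  lines <- readLines(path, warn = FALSE)
  paste(lines[!grepl("^>", lines)], collapse = "")
}
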