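#' Specification for a synthetic pangenome
#'
#' Describes the study conditions a generated pangenome emulates: lineage
#' sizes, per-lineage family presence fractions and dose ranges, the MGE
#' load, and how often flexible-family copies ride on mobile elements.
#'
#' @param lineages data.frame: lineage_id, n_genomes, mean_genome_size_bp,
#'   size_sd.
#' @param families data.frame: lineage_id, family, presence_fraction in
#'   [0, 1], dose_min, dose_max.
#' @param mge_rate Expected MGE regions per genome at the dataset mean
#'   genome size; a genome's expected MGE count scales with its absolute
#'   size, so MGE load — and with it flexible NAP content — covaries with
#'   genome size the way real pangenomes do.
#' @param flexible_in_mge_fraction Probability that a copy of a flexible
#'   family (lineage presence fraction < 1) is placed inside an MGE.
#' @param decoy_fraction Fraction of genes receiving an additional
#'   non-NAP decoy hit with e-value log-uniform in [1e-4, 1] (above the
#'   validation cutoff, so decoys must be filtered out).
#' @param hallmark_vicinity_rate Probability that an MGE-resident NAP gets
#'   a partitioning-protein (ParA) gene planted within the vicinity window.
#' @param seed Integer seed driving all randomness.
#' @return Object of class `pangenome_spec`.
#' @export
pangenome_spec <- function(lineages, families, mge_rate = 0.5,
                           flexible_in_mge_fraction = 0.5,
                           decoy_fraction = 0.10,
                           hallmark_vicinity_rate = 0.5,
                           seed = 1) {
  stopifnot(
    all(c("lineage_id", "n_genomes", "mean_genome_size_bp", "size_sd")
        %in% names(lineages)),
    all(c("lineage_id", "family", "presence_fraction", "dose_min",
          "dose_max") %in% names(families)),
    all(lineages$n_genomes >= 1),
    all(families$presence_fraction >= 0 & families$presence_fraction <= 1),
    all(families$dose_min <= families$dose_max),
    all(families$dose_min >= 1),
    mge_rate >= 0,
    flexible_in_mge_fraction >= 0 && flexible_in_mge_fraction <= 1
  )
  sp <- list(lineages = lineages, families = families, mge_rate = mge_rate,
             flexible_in_mge_fraction = flexible_in_mge_fraction,
             decoy_fraction = decoy_fraction,
             hallmark_vicinity_rate = hallmark_vicinity_rate,
             seed = as.integer(seed))
  class(sp) <- "pangenome_spec"
  sp
}

#' Generate a synthetic pangenome with planted ground truth
#'
#' Emits one genome record per genome: a single circular chromosome (size
#' drawn per lineage), NAP genes planted per family with the spec's
#' presence probability and a dose uniform over the dose range, MGE
#' regions (count Poisson with mean proportional to genome size; lengths
#' log-uniform between 10 and 300 kb) carrying relaxase and integrase
#' hallmark genes (plus a T4SS half the time, yielding an ICE/IME mix),
#' flexible-family copies placed inside MGEs with the spec probability
#' (with ParA genes planted in their vicinity at the hallmark rate), and a
#' domain-hit table where every planted NAP passes the validation
#' thresholds and decoy hits do not. Deterministic for a fixed seed.
#'
#' @param spec A [pangenome_spec()].
#' @return List: `genomes` (list of [genome_record()]), `hits` (domain-hit
#'   data.frame), `protein_info` (protein_id, genome_id, gene_id),
#'   `regions` ([mge_region_table()] across genomes), `hallmarks`
#'   (element_id, gene_id, role), `truth` (planted copy numbers, per-NAP
#'   MGE membership, planted vicinity annotations, seed).
#' @export
generate_pangenome <- function(spec) {
  stopifnot(inherits(spec, "pangenome_spec"))
  set.seed(spec$seed)
  genomes <- list()
  hits <- list()
  pinfo <- list()
  regions <- list()
  hallmarks <- list()
  copy_numbers <- list()
  nap_mge <- list()
  vicinity <- list()
  decoy_profiles <- c("PIN_domain", "ABC_tran", "DUF4011")
  window <- nap_thresholds()$vicinity_window_bp
  # genome-size reference for the MGE intensity: dataset-wide mean, so MGE
  # load scales with absolute genome size across lineages
  ref_size <- stats::weighted.mean(spec$lineages$mean_genome_size_bp,
                                   spec$lineages$n_genomes)

  for (li in seq_len(nrow(spec$lineages))) {
    lin <- spec$lineages$lineage_id[li]
    fam_rows <- spec$families[spec$families$lineage_id == lin, , drop = FALSE]
    for (gi in seq_len(spec$lineages$n_genomes[li])) {
      gid <- sprintf("%s_%03d", lin, gi)
      chrom <- paste0(gid, "_chr")
      size <- max(100000L, as.integer(round(stats::rnorm(
        1, spec$lineages$mean_genome_size_bp[li], spec$lineages$size_sd[li]))))
      # MGE regions; expected count scales with genome size
      lambda <- spec$mge_rate * size / ref_size
      n_mge <- stats::rpois(1, lambda)
      gregions <- NULL
      if (n_mge > 0) {
        lens <- pmin(as.integer(round(exp(stats::runif(
          n_mge, log(1e4), log(3e5))))), as.integer(size %/% 3))
        # place regions without overlap (integrated elements do not nest);
        # a region that cannot be placed after a few tries is dropped
        placed_s <- integer(0); placed_e <- integer(0)
        for (L in lens) {
          for (attempt in 1:20) {
            s0 <- sample.int(size - L, 1)
            e0 <- s0 + L - 1L
            if (!any(s0 <= placed_e & e0 >= placed_s)) {
              placed_s <- c(placed_s, s0); placed_e <- c(placed_e, e0)
              break
            }
          }
        }
        if (length(placed_s) > 0) {
          gregions <- mge_region_table(
            element_id = sprintf("%s_mge%02d", gid, seq_along(placed_s)),
            replicon_id = chrom, start = placed_s, end = placed_e
          )
          regions[[length(regions) + 1]] <- gregions
        }
      }
      # per-genome accumulators (vectors; bound into frames once per genome)
      g_id <- character(0); g_start <- integer(0); g_len <- integer(0)
      g_product <- character(0); g_kegg <- character(0)
      new_gene <- function(start, len, product, kegg = NA_character_) {
        id <- sprintf("%s_g%04d", gid, length(g_id) + 1L)
        start <- max(1L, min(as.integer(start), size - as.integer(len)))
        g_id[length(g_id) + 1L] <<- id
        g_start[length(g_start) + 1L] <<- start
        g_len[length(g_len) + 1L] <<- as.integer(len)
        g_product[length(g_product) + 1L] <<- product
        g_kegg[length(g_kegg) + 1L] <<- kegg
        id
      }
      hm_elem <- character(0); hm_gene <- character(0); hm_role <- character(0)
      nap_id <- character(0); nap_fam <- character(0)
      nap_elem <- character(0); nap_inmge <- logical(0)
      nap_para <- logical(0)
      cn_fam <- character(0); cn_dose <- integer(0)
      # hallmark genes on every MGE region
      if (!is.null(gregions)) {
        for (r in seq_len(nrow(gregions))) {
          roles <- c("relaxase", "integrase",
                     if (stats::runif(1) < 0.5) "t4ss")
          pos <- gregions$start[r] + 100L
          for (role in roles) {
            hid <- new_gene(pos, 900L, paste0(role, " protein"),
                            kegg = paste0("K_", role))
            hm_elem[length(hm_elem) + 1L] <- gregions$element_id[r]
            hm_gene[length(hm_gene) + 1L] <- hid
            hm_role[length(hm_role) + 1L] <- role
            pos <- pos + 1200L
          }
        }
      }
      # NAP genes per family
      for (fi in seq_len(nrow(fam_rows))) {
        fam <- fam_rows$family[fi]
        pf <- fam_rows$presence_fraction[fi]
        carrier <- stats::runif(1) < pf
        dose <- if (carrier) {
          dmin <- fam_rows$dose_min[fi]; dmax <- fam_rows$dose_max[fi]
          if (dmin == dmax) dmin else dmin + sample.int(dmax - dmin + 1, 1) - 1
        } else 0L
        flexible <- pf < 1
        # carrier genomes of flexible families gain one extra copy per MGE
        # region with the spec probability: MGE-borne NAPs ride on the
        # elements, so NAP content covaries with MGE load and genome size
        mge_of_copy <- integer(0)
        if (dose > 0L && flexible && !is.null(gregions)) {
          on_mge <- stats::runif(nrow(gregions)) < spec$flexible_in_mge_fraction
          mge_of_copy <- which(on_mge)
        }
        total_dose <- dose + length(mge_of_copy)
        cn_fam[length(cn_fam) + 1L] <- fam
        cn_dose[length(cn_dose) + 1L] <- as.integer(total_dose)
        if (total_dose == 0L) next
        for (ci in seq_len(total_dose)) {
          len <- sample(300:1500, 1)
          in_mge <- ci > dose
          if (in_mge) {
            r <- mge_of_copy[ci - dose]
            lo <- gregions$start[r] + 4000L
            hi <- gregions$end[r] - len - 4000L
            if (hi <= lo) { lo <- gregions$start[r]; hi <- gregions$end[r] - len }
            start <- as.integer(round(stats::runif(1, lo, hi)))
            element <- gregions$element_id[r]
          } else {
            start <- sample.int(size - len, 1)
            element <- NA_character_
          }
          nid <- new_gene(start, len, paste0(fam, " family NAP"))
          nap_id[length(nap_id) + 1L] <- nid
          nap_fam[length(nap_fam) + 1L] <- fam
          nap_elem[length(nap_elem) + 1L] <- element
          nap_inmge[length(nap_inmge) + 1L] <- in_mge
          planted_para <- in_mge &&
            stats::runif(1) < spec$hallmark_vicinity_rate
          if (planted_para) {
            gap <- sample(100:(window - 1500L), 1)
            new_gene(start + len + gap, 700L,
                     "chromosome partitioning protein ParA",
                     kegg = "K03496")
          }
          nap_para[length(nap_para) + 1L] <- planted_para
        }
      }
      n_genes <- length(g_id)
      gdf <- data.frame(
        gene_id = g_id, replicon_id = rep(chrom, n_genes),
        start = g_start, end = g_start + g_len - 1L,
        strand = sample(c("+", "-"), n_genes, replace = TRUE),
        product = g_product, kegg_id = g_kegg,
        protein_seq = rep(NA_character_, n_genes),
        stringsAsFactors = FALSE
      )
      # true NAP hits pass all validation thresholds
      n_nap <- length(nap_id)
      if (n_nap > 0) {
        hits[[paste0(gid, "_nap")]] <- data.frame(
          protein_id = nap_id, profile_id = nap_fam,
          evalue = 10^(-stats::runif(n_nap, 20, 50)),
          probability = stats::runif(n_nap, 95, 100),
          coverage = stats::runif(n_nap, 0.85, 1),
          stringsAsFactors = FALSE)
        pinfo[[gid]] <- data.frame(
          protein_id = nap_id, genome_id = rep(gid, n_nap),
          gene_id = nap_id, stringsAsFactors = FALSE)
        nap_mge[[gid]] <- data.frame(
          protein_id = nap_id, family = nap_fam,
          genome_id = rep(gid, n_nap), element_id = nap_elem,
          in_mge = nap_inmge, stringsAsFactors = FALSE)
        vicinity[[gid]] <- data.frame(
          protein_id = nap_id, family = nap_fam, in_mge = nap_inmge,
          planted_para = nap_para, stringsAsFactors = FALSE)
      }
      if (length(hm_elem) > 0) {
        hallmarks[[gid]] <- data.frame(
          element_id = hm_elem, gene_id = hm_gene, role = hm_role,
          stringsAsFactors = FALSE)
      }
      copy_numbers[[gid]] <- data.frame(
        genome_id = rep(gid, length(cn_fam)),
        lineage = rep(lin, length(cn_fam)),
        family = cn_fam, dose = cn_dose, stringsAsFactors = FALSE)
      # decoy hits on a fraction of all genes, above the e-value cutoff
      if (n_genes > 0 && spec$decoy_fraction > 0) {
        decoy <- which(stats::runif(n_genes) < spec$decoy_fraction)
        if (length(decoy) > 0) {
          hits[[paste0(gid, "_decoy")]] <- data.frame(
            protein_id = g_id[decoy],
            profile_id = sample(decoy_profiles, length(decoy),
                                replace = TRUE),
            evalue = 10^stats::runif(length(decoy), -4, 0),
            probability = stats::runif(length(decoy), 0, 100),
            coverage = stats::runif(length(decoy), 0.5, 1),
            stringsAsFactors = FALSE)
        }
      }
      genomes[[gid]] <- genome_record(
        genome_id = gid, lineage_id = lin, genome_size_bp = size,
        replicons = replicon_table(chrom, size, topology = "circular",
                                   kind = "chromosome", ori_pos = 1L,
                                   ter_pos = as.integer(size %/% 2)),
        genes = validate_gene_table(gdf)
      )
    }
  }
  bind <- function(x, proto) if (length(x) > 0) do.call(rbind, x) else proto
  list(
    genomes = genomes,
    hits = bind(hits, data.frame(protein_id = character(),
                                 profile_id = character(),
                                 evalue = numeric(), probability = numeric(),
                                 coverage = numeric())),
    protein_info = bind(pinfo, data.frame(protein_id = character(),
                                          genome_id = character(),
                                          gene_id = character())),
    regions = bind(regions, mge_region_table(character(), character())),
    hallmarks = bind(hallmarks, data.frame(element_id = character(),
                                           gene_id = character(),
                                           role = character())),
    truth = list(
      copy_numbers = do.call(rbind, copy_numbers),
      nap_mge = bind(nap_mge, data.frame(protein_id = character(),
                                         family = character(),
                                         genome_id = character(),
                                         element_id = character(),
                                         in_mge = logical())),
      vicinity = bind(vicinity, data.frame(protein_id = character(),
                                           family = character(),
                                           in_mge = logical(),
                                           planted_para = logical())),
      seed = spec$seed
    )
  )
}

.aa_alphabet <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Evolve marker sequences along a tree
#'
#' Independent-site substitution along every branch: each site is replaced
#' with probability `1 - exp(-subst_rate * branch_length)`, the
#' replacement drawn uniformly from the other 19 residues. The expected
#' per-branch difference fraction therefore has a closed form, making
#' statistical checks of the generator exact.
#'
#' @param tree Rooted `phylo` tree with branch lengths, or a Newick
#'   string.
#' @param root_seq_length Marker length in residues (>= 50).
#' @param subst_rate Rate multiplier applied to branch lengths (>= 0).
#' @param seed Integer seed.
#' @return Named character vector: one ungapped, equal-length sequence per
#'   leaf (a trivially aligned FASTA-ready set).
#' @export
generate_marker_sequences <- function(tree, root_seq_length, subst_rate = 1,
                                      seed = 1) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (root_seq_length < 50) stop("root_seq_length must be >= 50")
  if (subst_rate < 0) stop("subst_rate must be >= 0")
  set.seed(as.integer(seed))
  L <- as.integer(root_seq_length)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1
  seqs <- vector("list", max(tree$edge))
  seqs[[root]] <- sample(.aa_alphabet, L, replace = TRUE)
  # preorder: ape edges are already usable root-down after reorder
  tree <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    p <- 1 - exp(-subst_rate * tree$edge.length[e])
    s <- seqs[[parent]]
    mut <- which(stats::runif(L) < p)
    if (length(mut) > 0) {
      s[mut] <- vapply(s[mut], function(old) {
        sample(setdiff(.aa_alphabet, old), 1)
      }, character(1))
    }
    seqs[[child]] <- s
  }
  out <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""),
                character(1))
  stats::setNames(out, tree$tip.label)
}

#' Generate a per-base coverage track with planted expression
#'
#' Per-base depth is Poisson-distributed with mean `mean_depth *
#' multiplier` inside genes named in `expression_map` and `mean_depth *
#' baseline` elsewhere (and in unnamed genes).
#'
#' @param genome A [genome_record()] (first replicon is used).
#' @param expression_map Named numeric: gene_id -> multiplier (>= 0).
#' @param mean_depth Baseline mean depth (> 0).
#' @param seed Integer seed.
#' @param baseline Background multiplier (default 1).
#' @return Named list with one per-base numeric depth vector (the
#'   replicon), suitable for [write_bedgraph()] and [bin_coverage()].
#' @export
generate_coverage <- function(genome, expression_map = numeric(0),
                              mean_depth = 10, seed = 1, baseline = 1) {
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (length(expression_map) > 0 && any(expression_map < 0)) {
    stop("multipliers must be >= 0")
  }
  set.seed(as.integer(seed))
  rep1 <- genome$replicons[1, ]
  L <- rep1$length_bp
  mult <- rep(baseline, L)
  genes <- genome$genes[genome$genes$replicon_id == rep1$replicon_id, ,
                        drop = FALSE]
  for (i in seq_len(nrow(genes))) {
    m <- expression_map[genes$gene_id[i]]
    if (!is.na(m)) mult[genes$start[i]:genes$end[i]] <- m
  }
  depth <- stats::rpois(L, mean_depth * mult)
  stats::setNames(list(as.numeric(depth)), rep1$replicon_id)
}

#' Pangenome spec matching the packaged census fixture
#'
#' Builds a [pangenome_spec()] whose lineages and per-lineage family
#' presence fractions and dose ranges are derived from the packaged
#' species census via the maximum-spread presence reconstruction, so the
#' expected census of a generated pangenome reproduces the fixture's
#' species-by-family structure (16 lineages, 93 genomes).
#'
#' @param mean_genome_size_bp,size_sd Genome size model (the census does
#'   not record sizes; defaults are typical for the taxon, ~3 Mb).
#' @param ... Passed to [pangenome_spec()] (mge_rate, seed, ...).
#' @return A `pangenome_spec`.
#' @export
table1_spec <- function(mean_genome_size_bp = 3e6, size_sd = 2e5, ...) {
  fx <- load_fixture("table1_census")
  pres <- reconstruct_presence(fixture_census(fx))
  lineages <- data.frame(
    lineage_id = fx$species$lineage,
    n_genomes = fx$species$n_genomes,
    mean_genome_size_bp = mean_genome_size_bp,
    size_sd = size_sd,
    stringsAsFactors = FALSE
  )
  cells <- fx$cells
  keep <- cells$total > 0
  families <- data.frame(
    lineage_id = cells$lineage[keep],
    family = cells$family[keep],
    presence_fraction = pres$carriers[keep] / pres$n_genomes[keep],
    dose_min = cells$dose_min[keep],
    dose_max = cells$dose_max[keep],
    stringsAsFactors = FALSE
  )
  pangenome_spec(lineages, families, ...)
}
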