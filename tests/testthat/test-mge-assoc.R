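test_that("NAP genes map to elements by midpoint, innermost region wins", {
  genes <- gene_table(c("n1", "n2", "n3"), c("chr", "chr", "pls"),
                      start = c(50, 15000, 2000),
                      end = c(950, 15900, 2600))
  regions <- mge_region_table(
    element_id = c("big", "inner", "plasmid1"),
    replicon_id = c("chr", "chr", "pls"),
    start = c(1, 14000, NA), end = c(20000, 16000, NA),
    whole_replicon = c(FALSE, FALSE, TRUE)
  )
  cand <- data.frame(protein_id = c("p1", "p2", "p3"),
                     gene_id = c("n1", "n2", "n3"),
                     family = c("HU", "IHF_A", "KfrA"))
  m <- map_naps_to_mges(cand, genes, regions)
  expect_equal(m$element_id[m$gene_id == "n1"], "big")
  expect_equal(m$element_id[m$gene_id == "n2"], "inner")  # nested -> innermost
  expect_equal(m$element_id[m$gene_id == "n3"], "plasmid1")
  expect_equal(anyDuplicated(m$gene_id), 0)
})

test_that("fixture tabulations give 14 plasmid-borne and 13 iMGE-borne NAPs", {
  t3 <- load_fixture("table3_plasmids")
  expect_equal(sum(t3$nap_count), 14)
  expect_equal(sum(lengths(strsplit(t3$families, ";"))), 14)
  t4 <- load_fixture("table4_imges")
  expect_equal(sum(lengths(strsplit(t4$families, ";"))), 13)
  fams <- unlist(strsplit(t4$families, ";"))
  expect_setequal(unique(fams), c("IHF_A", "IHF_B", "HU", "Alba_2"))
})

test_that("element classification follows the hallmark rules and is total", {
  expect_equal(classify_element(TRUE, character(0)), "plasmid")
  expect_equal(classify_element(FALSE, c("t4ss", "integrase")), "ICE")
  expect_equal(classify_element(FALSE, c("relaxase", "integrase")), "IME")
  expect_equal(classify_element(FALSE,
                                c("relaxase", "integrase", "t4ss")), "ICE")
  expect_equal(classify_element(FALSE, "transposase"), "island")
  expect_equal(classify_element(FALSE, character(0)), "island")
  # every region gets a class
  regions <- mge_region_table(c("e1", "e2"), "chr", c(1, 100), c(50, 150))
  hm <- data.frame(element_id = "e1", gene_id = "g",
                   role = "integrase", stringsAsFactors = FALSE)
  out <- classify_elements(regions, hm)
  expect_false(any(is.na(out$mge_class)))
})

test_that("keyword mapper assigns hallmark roles from products", {
  expect_equal(
    hallmark_role_from_product(c("VirB4 ATPase", "MobM relaxase family",
                                 "integrase/recombinase XerD",
                                 "IS66 transposase",
                                 "RelB antitoxin",
                                 "chromosome partitioning protein ParA",
                                 "hypothetical protein")),
    c("t4ss", "relaxase", "integrase", "transposase", "toxin_antitoxin",
      "parA", NA))
})

test_that("covariation recovers planted dependence and the null stays flat", {
  x <- stats::setNames(c(1, 2, 3, 4, 5), paste0("g", 1:5))
  expect_equal(covariation(x, 3 * x)$pearson_r, 1.0)
  # independently drawn counts, n = 200: |r| < 0.2
  set.seed(99)
  a <- stats::setNames(rpois(200, 4), paste0("g", 1:200))
  b <- stats::setNames(rpois(200, 4), paste0("g", 1:200))
  expect_lt(abs(covariation(a, b)$pearson_r), 0.2)
  expect_error(covariation(x[1:2], x[1:2]), "at least 3")
})

test_that("NAP counts covary with relaxase counts when NAPs ride on MGEs", {
  lins <- data.frame(lineage_id = "L1", n_genomes = 40,
                     mean_genome_size_bp = 3e5, size_sd = 3e4)
  fams <- data.frame(lineage_id = "L1", family = c("HU", "IHF_A", "IHF_B"),
                     presence_fraction = 0.9, dose_min = 1, dose_max = 2)
  ok <- vapply(1:20, function(i) {
    sp <- pangenome_spec(lins, fams, mge_rate = 2,
                         flexible_in_mge_fraction = 0.8, seed = 700 + i)
    pg <- generate_pangenome(sp)
    cand <- validate_hits(pg$hits, protein_info = pg$protein_info)
    napn <- table(factor(cand$genome_id, levels = names(pg$genomes)))
    relg <- pg$hallmarks$gene_id[pg$hallmarks$role == "relaxase"]
    reln <- table(factor(sub("_g[0-9]+$", "", relg),
                         levels = names(pg$genomes)))
    covariation(stats::setNames(as.numeric(napn), names(pg$genomes)),
                stats::setNames(as.numeric(reln),
                                names(pg$genomes)))$pearson_r > 0
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("inverted repeats with the published stem/loop dimensions are found", {
  S8 <- "GATTCACG"
  ir8 <- find_inverted_repeats(paste0(S8, "AAAA", revcomp(S8)),
                               min_stem = 6, max_loop = 10)
  expect_equal(nrow(ir8), 1)
  expect_equal(ir8$stem_len, 8)
  expect_equal(ir8$loop_len, 4)

  S10 <- "CCATGAGTAC"
  ir10 <- find_inverted_repeats(paste0(S10, "AAAA", revcomp(S10)),
                                min_stem = 6, max_loop = 10)
  expect_equal(ir10$stem_len, 10)
  expect_equal(ir10$loop_len, 4)

  expect_error(find_inverted_repeats("ACGT", min_stem = 2), ">= 4")
  expect_error(find_inverted_repeats("ACGU", min_stem = 4), "invalid")
})

test_that("IR finder equals the brute-force oracle across parameters", {
  cases <- list(
    list(n = 300, seed = 1, min_stem = 5, max_loop = 8, mm = 0),
    list(n = 300, seed = 2, min_stem = 4, max_loop = 4, mm = 1),
    list(n = 500, seed = 3, min_stem = 6, max_loop = 10, mm = 0),
    list(n = 500, seed = 4, min_stem = 5, max_loop = 6, mm = 1),
    list(n = 2000, seed = 5, min_stem = 8, max_loop = 10, mm = 0)
  )
  for (cs in cases) {
    s <- random_dna(cs$n, cs$seed)
    impl <- find_inverted_repeats(s, cs$min_stem, cs$max_loop, cs$mm)
    orc <- oracle_inverted_repeats(s, cs$min_stem, cs$max_loop, cs$mm)
    expect_equal(impl, orc,
                 label = sprintf("IR oracle n=%d stem>=%d loop<=%d mm=%d",
                                 cs$n, cs$min_stem, cs$max_loop, cs$mm))
  }
  # N never matches
  expect_equal(nrow(find_inverted_repeats("AAAANNNNTTTT", 4, 10, 0)), 1)
  withN <- find_inverted_repeats("AAAANNNNTTTT", 4, 10, 0)
  expect_equal(withN$stem_len, 4)
})

test_that("a long random sequence has no long perfect inverted repeat", {
  s <- random_dna(1000, seed = 77)
  impl <- find_inverted_repeats(s, min_stem = 12, max_loop = 10, 0)
  expect_equal(nrow(impl), 0)
  expect_equal(nrow(oracle_inverted_repeats(s, 12, 10, 0)), 0)
})

test_that("synthetic MGE pipeline links flexible NAPs to classified elements", {
  lins <- data.frame(lineage_id = "L1", n_genomes = 15,
                     mean_genome_size_bp = 3e5, size_sd = 2e4)
  fams <- data.frame(lineage_id = "L1", family = "IHF_A",
                     presence_fraction = 0.8, dose_min = 1, dose_max = 2)
  pg <- generate_pangenome(pangenome_spec(lins, fams, mge_rate = 2,
                                          flexible_in_mge_fraction = 1,
                                          seed = 15))
  cand <- validate_hits(pg$hits, protein_info = pg$protein_info)
  all_genes <- do.call(rbind, lapply(pg$genomes,
                                     function(g) as.data.frame(g$genes)))
  m <- map_naps_to_mges(cand, all_genes, pg$regions)
  truth <- pg$truth$nap_mge
  planted <- truth[truth$in_mge, ]
  idx <- match(planted$protein_id, m$protein_id)
  expect_false(any(is.na(idx)))
  expect_equal(m$element_id[idx], planted$element_id)
  cls <- classify_elements(pg$regions, pg$hallmarks)
  expect_true(all(cls$mge_class %in% c("ICE", "IME")))
})
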