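test_that("global alignment identity matches direct expectations", {
  same <- global_align_identity("MKQLA", "MKQLA")
  expect_equal(same$identity, 1.0)
  expect_equal(same$coverage, 1.0)
  one_diff <- global_align_identity("ACDE", "ACDF")
  expect_equal(one_diff$identity, 0.75)
  expect_error(global_align_identity("A", ""), "non-empty")
  expect_error(global_align_identity("AC1E", "ACDE"), "non-amino-acid")
})

test_that("aligner agrees with the exhaustive alignment oracle on short strings", {
  pairs <- list(
    c("ACDE", "ACDF"), c("MK", "MKW"), c("WWW", "W"),
    c("HILK", "HLK"), c("CCC", "GGG")
  )
  set.seed(42)
  for (k in 1:5) {
    pairs[[length(pairs) + 1]] <- c(random_protein(sample(3:6, 1), 100 + k),
                                    random_protein(sample(3:6, 1), 200 + k))
  }
  for (p in pairs) {
    impl <- global_align_identity(p[1], p[2])
    orc <- oracle_align(p[1], p[2])
    expect_equal(impl$score, orc$score,
                 label = paste("score", p[1], "vs", p[2]))
    expect_true(any(abs(impl$identity - orc$identities) < 1e-12),
                label = paste("identity", p[1], "vs", p[2]))
  }
})

test_that("greedy identity clustering separates families and is order-invariant", {
  # three identical sequences collapse to one cluster
  s3 <- c(a = "MKVLAWQHE", b = "MKVLAWQHE", c = "MKVLAWQHE")
  cl3 <- greedy_identity_cluster(s3)
  expect_equal(length(unique(cl3$pf_id)), 1)

  # two divergent groups (cross-identity well below 50%) split in two;
  # verified against the all-pairs identity matrix
  grp1 <- c(x1 = "MKKVLAAWQHEDERKKL", x2 = "MKKVLAAWQHEDERKKI")
  grp2 <- c(y1 = "CCPGGFTTYNNSSPPGG", y2 = "CCPGGFTTYNNSSPPGA")
  seqs <- c(grp1, grp2)
  idm <- outer(names(seqs), names(seqs), Vectorize(function(i, j) {
    global_align_identity(seqs[[i]], seqs[[j]])$identity
  }))
  dimnames(idm) <- list(names(seqs), names(seqs))
  expect_true(all(idm["x1", c("y1", "y2")] < 0.5))
  expect_true(idm["x1", "x2"] > 0.9 && idm["y1", "y2"] > 0.9)
  cl <- greedy_identity_cluster(seqs, 0.5)
  expect_equal(length(unique(cl$pf_id)), 2)
  expect_equal(cl$pf_id[cl$protein_id == "x1"],
               cl$pf_id[cl$protein_id == "x2"])
  # input order does not matter
  cl_rev <- greedy_identity_cluster(seqs[c(3, 1, 4, 2)], 0.5)
  expect_equal(cl, cl_rev)

  # threshold 1.0 on all-distinct sequences: one cluster per sequence
  distinct <- c(a = "MKVLAWQHE", b = "MKVLAWQHD", c = "MKVLAWQHC")
  expect_equal(length(unique(greedy_identity_cluster(distinct, 1.0)$pf_id)), 3)
  expect_error(greedy_identity_cluster(distinct, 0), "threshold")
})

test_that("clustering output partitions the input", {
  pg_seqs <- generate_marker_sequences(reference_class_tree(), 60, 1, seed = 5)
  cl <- greedy_identity_cluster(pg_seqs, 0.5)
  expect_setequal(cl$protein_id, names(pg_seqs))
  expect_equal(anyDuplicated(cl$protein_id), 0)
  expect_true(all(tapply(cl$is_centroid, cl$pf_id, sum) == 1))
})

bbh_hit <- function(q, s, score, ev = 1e-20, cov = 1) {
  data.frame(query = q, subject = s, score = score, evalue = ev,
             coverage = cov, stringsAsFactors = FALSE)
}

sym_hits <- function(pairs) {
  do.call(rbind, lapply(pairs, function(p) {
    rbind(bbh_hit(p[[1]], p[[2]], p[[3]]), bbh_hit(p[[2]], p[[1]], p[[3]]))
  }))
}

cluster_partition <- function(cl) {
  parts <- split(cl$protein_id, cl$pf_id)
  unname(lapply(parts[order(vapply(parts, min, character(1)))], sort))
}

test_that("BBH triangles form protein families with spec'd filtering", {
  genome_of <- c(a1 = "GA", b1 = "GB", c1 = "GC")
  hits <- sym_hits(list(list("a1", "b1", 100), list("b1", "c1", 100),
                        list("a1", "c1", 100)))
  cl <- bbh_triangle_cluster(hits, genome_of)
  expect_equal(length(unique(cl$pf_id)), 1)
  expect_true(all(cl$in_triangle))

  # a low-coverage edge is excluded, breaking the triangle
  hits_lc <- hits
  hits_lc$coverage[hits_lc$query == "a1" & hits_lc$subject == "b1"] <- 0.6
  hits_lc$coverage[hits_lc$query == "b1" & hits_lc$subject == "a1"] <- 0.6
  cl2 <- bbh_triangle_cluster(hits_lc, genome_of)
  expect_equal(length(unique(cl2$pf_id)), 3)

  # two triangles sharing an edge merge into one family of four
  genome_of4 <- c(a1 = "GA", b1 = "GB", c1 = "GC", d1 = "GD")
  hits4 <- sym_hits(list(list("a1", "b1", 100), list("b1", "c1", 100),
                         list("a1", "c1", 100), list("b1", "d1", 100),
                         list("c1", "d1", 100)))
  cl4 <- bbh_triangle_cluster(hits4, genome_of4)
  expect_equal(length(unique(cl4$pf_id)), 1)
  expect_equal(sum(cl4$in_triangle), 4)

  expect_error(bbh_triangle_cluster(hits, genome_of[-1]), "unknown")
})

test_that("BBH clustering matches the brute-force triangle oracle", {
  # several small random instances with paralogs and asymmetric scores
  for (seed in 1:6) {
    set.seed(seed)
    genomes <- c("G1", "G2", "G3", "G4")
    prots <- paste0("p", 1:8)
    genome_of <- stats::setNames(sample(genomes, 8, replace = TRUE), prots)
    pairs <- t(utils::combn(prots, 2))
    keep <- stats::runif(nrow(pairs)) < 0.6
    pairs <- pairs[keep, , drop = FALSE]
    hits <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      sc <- sample(50:100, 1)
      rbind(bbh_hit(pairs[i, 1], pairs[i, 2], sc),
            bbh_hit(pairs[i, 2], pairs[i, 1], sc))
    }))
    impl <- cluster_partition(bbh_triangle_cluster(hits, genome_of))
    orc <- oracle_bbh_triangles(hits, genome_of)
    expect_equal(impl, orc, label = paste("BBH oracle, seed", seed))
  }
})

test_that("clusters recover planted marker families at low cross-identity", {
  # two marker families evolved on the same tree from unrelated roots
  tr <- "((A:0.05,B:0.05):0.02,(C:0.05,D:0.05):0.02);"
  fam1 <- generate_marker_sequences(tr, 80, 1, seed = 31)
  fam2 <- generate_marker_sequences(tr, 80, 1, seed = 77)
  names(fam1) <- paste0("f1_", names(fam1))
  names(fam2) <- paste0("f2_", names(fam2))
  cl <- greedy_identity_cluster(c(fam1, fam2), 0.5)
  expect_equal(length(unique(cl$pf_id)), 2)
  got <- split(cl$protein_id, cl$pf_id)
  expect_true(setequal(got[[1]], names(fam1)) ||
                setequal(got[[1]], names(fam2)))
})
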