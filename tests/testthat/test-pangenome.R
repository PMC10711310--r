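fake_entry <- function(genome_id, ids, seqs) {
  list(genome = NULL,
       genes = data.frame(gene_id = ids, genome_id = genome_id,
                          contig_id = "c", start = 1L, end = 3L, strand = "+",
                          nt_seq = "NNN", aa_seq = seqs,
                          internal_stop = FALSE, stringsAsFactors = FALSE))
}

test_that("greedy clustering follows the stated representative rule", {
  # identical protein in two genomes -> one family in both
  fams <- cluster_gene_families(list(fake_entry("g1", "g1|x", "MKVLW"),
                                     fake_entry("g2", "g2|x", "MKVLW")))
  expect_length(fams$families, 1)
  m <- build_matrix(fams, c("g1", "g2"))
  expect_equal(unname(rowSums(m)), 2)

  # unrelated proteins -> singleton families
  fams2 <- cluster_gene_families(list(fake_entry("g1", "g1|x", "MMMMMMMMMM"),
                                      fake_entry("g2", "g2|x", "WCWCWCWCWC")))
  expect_length(fams2$families, 2)

  # constructed identities: id(A,B)=0.96 joins, id(A,C)=0.92 founds anew,
  # even though id(B,C)=0.96 — membership is measured against the
  # representative only
  set.seed(23)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- sample(aas, 25, replace = TRUE)
  sub_at <- function(v, pos) {
    v[pos] <- vapply(v[pos], function(x) sample(setdiff(aas, x), 1), "")
    v
  }
  A <- paste(base, collapse = "")
  BC <- sub_at(base, 5)
  B <- paste(BC, collapse = "")
  C <- paste(sub_at(BC, 15), collapse = "")
  expect_equal(aligned_identity(A, B), 0.96)
  expect_equal(aligned_identity(A, C), 0.92)
  expect_equal(aligned_identity(B, C), 0.96)
  fams3 <- cluster_gene_families(list(fake_entry("g1", "a_A", A),
                                      fake_entry("g2", "b_B", B),
                                      fake_entry("g3", "c_C", C)))
  expect_equal(unname(lengths(fams3$families)), c(2L, 1L))
  expect_setequal(fams3$families[[1]], c("a_A", "b_B"))
  expect_equal(unname(fams3$representative), c("a_A", "c_C"))
})

test_that("clustering is invariant to genome input order", {
  set.seed(31)
  cfg <- sim_config(n_group1 = 2, n_group2 = 2, n_core_families = 15,
                    n_planted_group_genes = 2, n_planted_variants = 5,
                    shared_accessory = 5, accessory_novel_per_genome = 2,
                    seed = 9)
  sim <- simulate_collection(cfg)
  f1 <- cluster_gene_families(sim$genomes)
  f2 <- cluster_gene_families(rev(sim$genomes))
  expect_identical(f1$families, f2$families)
  # conservation: every gene in exactly one family
  expect_equal(sort(unlist(f1$families, use.names = FALSE)),
               sort(f1$genes$gene_id))
})

test_that("clustering recovers planted families exactly at low divergence", {
  cfg <- sim_config(n_group1 = 3, n_group2 = 3, n_core_families = 30,
                    n_planted_group_genes = 3, n_planted_variants = 10,
                    shared_accessory = 8, accessory_novel_per_genome = 2,
                    background_aa_divergence = 0.01, seed = 4)
  sim <- simulate_collection(cfg)
  fams <- cluster_gene_families(sim$genomes)
  truth <- setNames(sim$truth$gene_truth$truth_family,
                    sim$truth$gene_truth$gene_id)
  # identical partitions: each cluster maps to exactly one truth family
  # and each truth family to exactly one cluster (Rand index 1)
  per_cluster <- lapply(fams$families, function(gg) unique(truth[gg]))
  expect_true(all(lengths(per_cluster) == 1))
  expect_equal(anyDuplicated(unlist(per_cluster)), 0)
})

test_that("presence matrix collapses paralogs and matches recounts", {
  e1 <- fake_entry("g1", c("g1|a", "g1|b"), c("MKVLWMKVLW", "MKVLWMKVLW"))
  e2 <- fake_entry("g2", "g2|a", "MKVLWMKVLW")
  fams <- cluster_gene_families(list(e1, e2))
  m <- build_matrix(fams, c("g1", "g2", "g3"))
  expect_equal(m["fam_00001", ], c(g1 = 1L, g2 = 1L, g3 = 0L))
  pr <- paralog_report(fams)
  expect_equal(pr$genome_id, "g1")
  expect_equal(pr$n_copies, 2L)
  expect_error(build_matrix(fams, "g1"), "absent from genome_ids")

  # column sums equal independent per-genome family counts
  cfg <- sim_config(n_group1 = 2, n_group2 = 2, n_core_families = 10,
                    n_planted_group_genes = 2, n_planted_variants = 0,
                    shared_accessory = 6, accessory_novel_per_genome = 1,
                    seed = 3)
  sim <- simulate_collection(cfg)
  fams2 <- cluster_gene_families(sim$genomes)
  m2 <- build_matrix(fams2, sim$metadata$genome_id)
  gmap <- setNames(fams2$genes$genome_id, fams2$genes$gene_id)
  for (g in colnames(m2)) {
    n_fam <- sum(vapply(fams2$families, function(gg) g %in% gmap[gg],
                        logical(1)))
    expect_equal(unname(colSums(m2)[g]), n_fam)
  }
})

test_that("core/shell/cloud partition follows the fraction rule", {
  ids <- paste0("f", 1:4)
  m <- matrix(0L, 4, 15, dimnames = list(ids, paste0("g", 1:15)))
  m[1, 1:15] <- 1L # 15/15 -> core
  m[2, 1:14] <- 1L # 14/15 = 0.933 < 0.95 -> shell
  m[3, 1:3] <- 1L  # 3/15 = 0.2 -> shell
  m[4, 1:2] <- 1L  # 2/15 = 0.133 -> cloud
  p <- partition_pangenome(m)
  expect_equal(p$core_ids, "f1")
  expect_setequal(p$shell_ids, c("f2", "f3"))
  expect_equal(p$cloud_ids, "f4")

  # partition completeness on random matrices
  set.seed(41)
  for (rep in 1:5) {
    r <- matrix(rbinom(30 * 7, 1, runif(1, 0.1, 0.9)), 30, 7,
                dimnames = list(paste0("f", 1:30), paste0("g", 1:7)))
    pp <- partition_pangenome(r)
    expect_equal(length(pp$core_ids) + length(pp$shell_ids) +
                   length(pp$cloud_ids), 30)
    expect_length(intersect(pp$core_ids, pp$cloud_ids), 0)
  }
})

test_that("rarefaction curve has exact means on analytic cases", {
  # identical content -> constant curve
  m <- matrix(1L, 7, 5, dimnames = list(paste0("f", 1:7), paste0("g", 1:5)))
  cu <- rarefaction_curve(m, 20, seed = 1)
  expect_equal(cu$mean_pangenome_size, rep(7, 5))

  # two disjoint genomes, sizes 5 and 7: (1, 6.0), (2, 12.0)
  m2 <- matrix(0L, 12, 2, dimnames = list(paste0("f", 1:12), c("g1", "g2")))
  m2[1:5, 1] <- 1L
  m2[6:12, 2] <- 1L
  cu2 <- rarefaction_curve(m2, 40, seed = 2)
  expect_equal(cu2$mean_pangenome_size, c(6, 12))
  expect_equal(cu2$mean_new_genes, c(6, 6))

  # determinism and terminal value
  set.seed(43)
  m3 <- matrix(rbinom(80, 1, 0.5), 16, 5,
               dimnames = list(paste0("f", 1:16), paste0("g", 1:5)))
  a <- rarefaction_curve(m3, 10, seed = 9)
  b <- rarefaction_curve(m3, 10, seed = 9)
  expect_identical(a, b)
  expect_equal(a$mean_pangenome_size[5], sum(rowSums(m3) > 0))
})

test_that("Heaps' fit recovers exact power laws and classifies openness", {
  flat <- data.frame(N = 1:10, mean_pangenome_size = 500)
  hf <- fit_heaps(flat)
  expect_equal(hf$gamma, 0, tolerance = 1e-12)
  expect_equal(hf$openness, "CLOSED")

  pl <- data.frame(N = 1:15, mean_pangenome_size = 100 * (1:15)^0.3)
  hp <- fit_heaps(pl)
  expect_equal(hp$kappa, 100, tolerance = 1e-10)
  expect_equal(hp$gamma, 0.3, tolerance = 1e-10)
  expect_equal(hp$openness, "OPEN")

  expect_error(fit_heaps(flat[1:2, ]), "at least 3")

  # infinitely-many-genes regime: u novel families per genome -> open
  set.seed(47)
  img_matrix <- function(u, g = 10, core = 100) {
    novel <- rpois(g, u)
    rows <- core + sum(novel)
    m <- matrix(0L, rows, g,
                dimnames = list(paste0("f", seq_len(rows)), paste0("g", 1:g)))
    m[seq_len(core), ] <- 1L
    at <- core
    for (gi in seq_len(g)) {
      if (novel[gi] > 0) m[at + seq_len(novel[gi]), gi] <- 1L
      at <- at + novel[gi]
    }
    m
  }
  fit <- fit_heaps(rarefaction_curve(img_matrix(20), 50, seed = 8))
  expect_equal(fit$openness, "OPEN")
  expect_gt(fit$gamma, 0.01)
})
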