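small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_group1 = 3, n_group2 = 3, n_core_families = 25,
         core_gene_len_aa = 120, n_planted_group_genes = 3,
         n_planted_variants = 12, shared_accessory = 6,
         accessory_novel_per_genome = 2, seed = 101),
    list(...))
  do.call(sim_config, args)
}

test_that("simulated collections are reproducible byte-for-byte", {
  s1 <- simulate_collection(small_cfg())
  s2 <- simulate_collection(small_cfg())
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$truth, s2$truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_collection(s1, d1)
  write_collection(s2, d2)
  for (f in list.files(d1, recursive = TRUE))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)

  s3 <- simulate_collection(small_cfg(seed = 202))
  expect_false(identical(s1$genomes, s3$genomes))
})

test_that("written collections read back to the same genes", {
  sim <- simulate_collection(small_cfg())
  d <- withr::local_tempdir()
  write_collection(sim, d)
  back <- read_collection(d)
  expect_equal(back$metadata, sim$metadata)
  for (i in seq_along(sim$genomes)) {
    a <- sim$genomes[[i]]$genes
    b <- back$genomes[[i]]$genes
    expect_equal(b$gene_id, a$gene_id)
    expect_equal(b$nt_seq, a$nt_seq)     # strand handling round-trips
    expect_equal(b$aa_seq, a$aa_seq)     # translation matches the generator
  }
})

test_that("planted signals are recovered exactly without noise", {
  sim <- simulate_collection(small_cfg())
  fams <- cluster_gene_families(sim$genomes)
  m <- build_matrix(fams, sim$metadata$genome_id)
  truth <- setNames(sim$truth$gene_truth$truth_family,
                    sim$truth$gene_truth$gene_id)
  fam_truth <- vapply(fams$families, function(gg)
    unique(truth[gg])[1], "")

  # association: planted group families and only they reach the minimal p
  assoc <- associate_families(m, sim$metadata)
  top <- assoc$family_id[assoc$p_value == min(assoc$p_value)]
  expect_setequal(unname(fam_truth[top]), sim$truth$planted_group_family_ids)

  # variant scan: exactly the planted (family, position) pairs
  msas <- core_family_msas(fams, sim$metadata$genome_id)
  found <- do.call(rbind, lapply(names(msas), function(f) {
    v <- scan_group_variants(msas[[f]], sim$metadata, "PTB")
    if (nrow(v) == 0) return(NULL)
    data.frame(family = fam_truth[[f]], position = v$column,
               res = v$target_residues)
  }))
  pv <- sim$truth$planted_variants
  expect_equal(nrow(found), nrow(pv))
  key <- function(f, p) paste(f, p)
  expect_setequal(key(found$family, found$position),
                  key(pv$family_id, pv$position))
  res_map <- setNames(pv$group1_residue, key(pv$family_id, pv$position))
  expect_equal(unname(res_map[key(found$family, found$position)]), found$res)
})

test_that("a closed configuration yields a flat curve and CLOSED verdict", {
  cfg <- small_cfg(accessory_novel_per_genome = 0, shared_accessory = 0,
                   n_planted_group_genes = 0, n_planted_variants = 0)
  sim <- simulate_collection(cfg)
  fams <- cluster_gene_families(sim$genomes)
  m <- build_matrix(fams, sim$metadata$genome_id)
  cu <- rarefaction_curve(m, 20, seed = 5)
  expect_equal(cu$mean_pangenome_size, rep(25, 6))
  expect_equal(fit_heaps(cu)$openness, "CLOSED")
  expect_equal(sim$truth$regime, "CLOSED")
})

test_that("presence flip noise degrades association recall monotonically", {
  recall_one <- function(eps, seed) {
    cfg <- sim_config(n_group1 = 5, n_group2 = 5, n_core_families = 10,
                      core_gene_len_aa = 60, n_planted_group_genes = 8,
                      n_planted_variants = 0, shared_accessory = 0,
                      accessory_novel_per_genome = 0,
                      presence_flip_noise = eps, seed = seed)
    sim <- simulate_collection(cfg)
    fams <- cluster_gene_families(sim$genomes)
    m <- build_matrix(fams, sim$metadata$genome_id)
    truth <- setNames(sim$truth$gene_truth$truth_family,
                      sim$truth$gene_truth$gene_id)
    assoc <- associate_families(m, sim$metadata)
    perfect <- assoc$family_id[assoc$p_value <= 1 / choose(10, 5) * 2 + 1e-12]
    hits <- unique(unlist(lapply(fams$families[perfect],
                                 function(gg) unique(truth[gg]))))
    length(intersect(hits, sim$truth$planted_group_family_ids)) /
      length(sim$truth$planted_group_family_ids)
  }
  recall_at <- function(eps)
    mean(vapply(33:36, function(s) recall_one(eps, s), numeric(1)))
  r0 <- recall_at(0)
  r2 <- recall_at(0.2)
  r4 <- recall_at(0.45)
  expect_equal(r0, 1)
  expect_true(r0 >= r2, info = paste(r0, r2))
  expect_true(r2 >= r4, info = paste(r2, r4))
})

test_that("MAG degradation keeps genes binomially and records bookkeeping", {
  cfg <- sim_config(n_group1 = 2, n_group2 = 2, n_core_families = 400,
                    core_gene_len_aa = 40, n_planted_group_genes = 0,
                    n_planted_variants = 0, shared_accessory = 0,
                    accessory_novel_per_genome = 0, seed = 55)
  sim <- simulate_collection(cfg)
  entry <- sim$genomes[[1]]
  donor <- sim$genomes[[2]]
  deg <- degrade_to_mag(entry, completeness = 90, contamination_rate = 0.02,
                        donor = donor, seed = 7)
  n_native <- sum(!grepl("contam", deg$genes$gene_id))
  expect_gt(n_native, 900 * 400 / 1000 - 3 * sqrt(400 * 0.9 * 0.1)) # 3 sigma
  expect_lt(n_native, 360 + 3 * sqrt(400 * 0.9 * 0.1))
  expect_equal(deg$genome$completeness, 100 * n_native / 400)
  expect_equal(deg$genome$source, "MAG")
  expect_error(degrade_to_mag(entry, 90, 0.02, entry), "different genome")

  # identity degradation: completeness 100, contamination 0
  same <- degrade_to_mag(entry, 100, 0, donor, seed = 8)
  expect_equal(same$genes$nt_seq, entry$genes$nt_seq)
  expect_equal(same$genome$completeness, 100)

  # end-to-end: a simulated MAG fraction flows into metadata and QC
  cfg2 <- sim_config(n_group1 = 3, n_group2 = 3, n_core_families = 30,
                     core_gene_len_aa = 60, n_planted_group_genes = 0,
                     n_planted_variants = 0, shared_accessory = 0,
                     accessory_novel_per_genome = 0, mag_fraction = 0.5,
                     mag_completeness_range = c(70, 95), seed = 77)
  sim2 <- simulate_collection(cfg2)
  expect_equal(sum(sim2$metadata$source == "MAG"), 3)
  expect_true(all(sim2$metadata$completeness[sim2$metadata$source == "MAG"] < 100))
})
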