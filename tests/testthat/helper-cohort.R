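# The default synthetic cohort (6 PTB + 9 FTB, 500 core families, 14 planted
# group genes, 185 planted variants) is expensive to build, so acceptance
# blocks share one lazily computed instance.
.cohort_cache <- new.env(parent = emptyenv())

acceptance_cohort <- function() {
  if (is.null(.cohort_cache$res)) {
    sim <- simulate_collection(sim_config(seed = 1))
    fams <- cluster_gene_families(sim$genomes)
    m <- build_matrix(fams, sim$metadata$genome_id)
    msas <- core_family_msas(fams, sim$metadata$genome_id)
    truth <- setNames(sim$truth$gene_truth$truth_family,
                      sim$truth$gene_truth$gene_id)
    fam_truth <- vapply(fams$families, function(gg) unique(truth[gg])[1], "")
    .cohort_cache$res <- list(sim = sim, fams = fams, m = m, msas = msas,
                              fam_truth = fam_truth)
  }
  .cohort_cache$res
}
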