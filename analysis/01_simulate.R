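#!/usr/bin/env Rscript

# Stage 1 — build the study cohort.
#
# Generates the default synthetic cohort: 6 preterm (PTB) and 9 full-term
# (FTB) Lactobacillus-like genomes at ~99% ANI with a 500-family core,
# a half-present shared accessory plus ~10 genome-private families each
# (open pangenome regime), 14 planted PTB-specific gene families and 185
# planted PTB-fixed amino-acid variants in core genes. The collection is
# written as plain FASTA + GFF3 + metadata TSV + truth JSON under
# scratch/collection/, exactly the shape real annotated assemblies arrive in;
# downstream stages only read those files.

suppressPackageStartupMessages(library(pangsig))

out <- "scratch/collection"
cfg <- sim_config(seed = 1)
message("simulating ", cfg$n_group1, " PTB + ", cfg$n_group2, " FTB genomes ...")
sim <- simulate_collection(cfg)
write_collection(sim, out)

n_genes <- vapply(sim$genomes, function(e) nrow(e$genes), integer(1))
message(sprintf("wrote %d genomes (%d-%d genes each, %d total) to %s",
                length(sim$genomes), min(n_genes), max(n_genes),
                sum(n_genes), out))
message(sprintf("planted truth: %d group-specific families, %d group-fixed variants in %d core genes",
                length(sim$truth$planted_group_family_ids),
                nrow(sim$truth$planted_variants),
                length(unique(sim$truth$planted_variants$family_id))))
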