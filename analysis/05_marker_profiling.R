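#!/usr/bin/env Rscript

# Stage 5 — quality gating and marker-cluster profiling.
#
# Applies the high-quality genome gates (completeness >= 90%, contamination
# < 5%), then uses the PTB-specific gene cluster (the planted group genes,
# taken from one PTB genome as the database — mirroring how an identified
# cell-surface cluster is profiled across a collection) to build a
# marker x genome presence/absence profile and its per-clade concordance.

suppressPackageStartupMessages(library(pangsig))
dir.create("results", showWarnings = FALSE)

coll <- read_collection("scratch/collection")
qc <- filter_genomes(coll$metadata, min_completeness = 90,
                     max_contamination = 5)
message(sprintf("QC: %d genomes kept, %d dropped", length(qc$kept),
                nrow(qc$dropped)))
keep <- vapply(coll$genomes, function(e) e$genome$genome_id %in% qc$kept,
               logical(1))
genomes <- coll$genomes[keep]
metadata <- coll$metadata[coll$metadata$genome_id %in% qc$kept, ]

# marker database: the planted PTB cluster's proteins from the first PTB
# genome carrying all of them
planted <- coll$truth$planted_group_family_ids
ptb1 <- metadata$genome_id[metadata$group == "PTB"][1]
src <- genomes[[which(vapply(genomes, function(e)
  e$genome$genome_id == ptb1, logical(1)))]]$genes
marker_ids <- paste(ptb1, planted, sep = "|")
markers <- marker_set(setNames(src$aa_seq[match(marker_ids, src$gene_id)],
                               planted),
                      min_identity = 0.7, min_coverage = 0.8)

message("profiling ", length(planted), " markers across ", length(genomes),
        " genomes ...")
profile <- profile_markers(markers, genomes)
write_marker_profile(profile, "results/marker_profile.tsv")
write.table(profile$best_hits, "results/marker_hits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

clades <- setNames(ifelse(metadata$group == "PTB", "Clade-I", "Clade-II"),
                   metadata$genome_id)
cc <- clade_concordance(profile, clades)
write.table(cc, "results/marker_clade_concordance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("mean marker concordance between clades: %.3f (1 = perfectly clade-restricted)",
                mean(cc$concordance)))
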