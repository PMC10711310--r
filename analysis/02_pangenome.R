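#!/usr/bin/env Rscript

# Stage 2 — pangenome reconstruction.
#
# Reads the collection written by 01_simulate.R, clusters proteins into gene
# families at 95% identity, builds the presence/absence matrix, partitions
# core/shell/cloud, and fits Heaps' law to the rarefaction curve to classify
# the pangenome as open or closed. Tables go to results/.

suppressPackageStartupMessages(library(pangsig))
dir.create("results", showWarnings = FALSE)

coll <- read_collection("scratch/collection")
message("clustering ", sum(vapply(coll$genomes, function(e) nrow(e$genes), 0L)),
        " proteins from ", length(coll$genomes), " genomes ...")
fams <- cluster_gene_families(coll$genomes, threshold = 0.95)
print(fams)

# family membership table so later stages can rebuild families without
# re-clustering
membership <- data.frame(
  family_id = rep(names(fams$families), lengths(fams$families)),
  gene_id = unlist(fams$families, use.names = FALSE))
write.table(membership, "results/gene_families.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

m <- build_matrix(fams, coll$metadata$genome_id)
write_presence_absence(m, "results/gene_presence_absence.Rtab")

part <- partition_pangenome(m, core_frac = 0.95, shell_min_frac = 0.15)
print(part)
write.table(part$table, "results/pangenome_partition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

curve <- rarefaction_curve(m, n_permutations = 100, seed = 11)
write.table(curve, "results/rarefaction_curve.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
heaps <- fit_heaps(curve)
print(heaps)
writeLines(jsonlite::toJSON(list(kappa = heaps$kappa, gamma = heaps$gamma,
                                 openness = heaps$openness),
                            auto_unbox = TRUE, digits = NA),
           "results/heaps_fit.json")
message("pangenome tables written to results/")
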