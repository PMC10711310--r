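#!/usr/bin/env Rscript

# Stage 3 — phenotype-group signatures.
#
# Two discriminative analyses over the pangenome: (i) Fisher-exact
# association of gene-family presence with birth outcome (PTB vs FTB), with
# Bonferroni and Benjamini-Hochberg corrections; (ii) a scan of per-family
# core-gene protein alignments for PTB-fixed amino-acid variants absent from
# FTB genomes (strict mode), with the gap-tolerant lenient count reported
# alongside.

suppressPackageStartupMessages(library(pangsig))
dir.create("results", showWarnings = FALSE)

coll <- read_collection("scratch/collection")
genes <- do.call(rbind, lapply(coll$genomes, `[[`, "genes"))
fams <- as_gene_family_set(read.delim("results/gene_families.tsv"), genes)
m <- read_presence_absence("results/gene_presence_absence.Rtab")

message("testing ", nrow(m), " families for association with birth outcome ...")
assoc <- associate_families(m, coll$metadata, groups = c("PTB", "FTB"))
write_association(assoc, "results/association.tsv")
top <- assoc[assoc$p_value == min(assoc$p_value), ]
message(sprintf("%d families tested; %d at the minimal p = %.3g (all %s)",
                nrow(assoc), nrow(top), min(assoc$p_value),
                paste(unique(top$direction), collapse = "/")))

message("aligning core families and scanning for PTB-fixed variants ...")
msas <- core_family_msas(fams, coll$metadata$genome_id)
strict <- lapply(msas, scan_group_variants, metadata = coll$metadata,
                 target_group = "PTB", strict = TRUE)
lenient <- lapply(msas, scan_group_variants, metadata = coll$metadata,
                  target_group = "PTB", strict = FALSE)
write_variants(strict, "results/group_variants.tsv")
vsum <- summarize_variants(strict, min_count = 2)
write.table(vsum$report, "results/variant_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("strict: %d PTB-specific variants in %d of %d core families (%d families with >= 2)",
                vsum$total_variants, vsum$total_families_with_variants,
                length(msas), nrow(vsum$report)))
message(sprintf("lenient (gap-tolerant): %d variants",
                sum(vapply(lenient, nrow, integer(1)))))
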