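AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Configuration for the synthetic pangenome generator
#'
#' Defaults emulate the study cohort: 6 preterm (PTB) + 9 full-term (FTB)
#' genomes of one species at ~99-99.9% ANI, a 500-family core of 300-aa
#' proteins (a desk-scale stand-in for the ~1163-family core), 14 planted
#' PTB-specific gene families, 185 planted PTB-fixed amino-acid variants,
#' 0.5% per-site background amino-acid divergence, a half-present shared
#' accessory and 10 genome-private novel families per genome (an open,
#' infinitely-many-genes accessory regime).
#'
#' @param n_group1,n_group2 genomes per phenotype group (group 1 = PTB).
#' @param n_core_families core families shared by all genomes.
#' @param core_gene_len_aa core protein length (aa).
#' @param accessory_novel_per_genome Poisson mean of genome-private novel
#'   families (u; u > 0 gives an open pangenome).
#' @param shared_accessory accessory families at random 50% presence.
#' @param n_planted_group_genes families present in all group-1, absent in
#'   group-2 genomes (before flip noise).
#' @param n_planted_variants group-fixed amino-acid differences planted into
#'   core genes (distinct family x position pairs, protected from background
#'   mutation).
#' @param background_aa_divergence per-site amino-acid mutation probability
#'   per genome copy.
#' @param presence_flip_noise probability a planted group gene's presence is
#'   flipped in any genome (epsilon).
#' @param mag_fraction fraction of genomes degraded to MAG quality.
#' @param mag_completeness_range completeness (percent) range for degraded
#'   genomes.
#' @param mag_contamination_rate expected contaminating-gene fraction for
#'   degraded genomes.
#' @param seed RNG seed; the full output is byte-reproducible given the seed.
#' @return A `sim_config`.
#' @export
sim_config <- function(n_group1 = 6, n_group2 = 9, n_core_families = 500,
                       core_gene_len_aa = 300,
                       accessory_novel_per_genome = 10,
                       shared_accessory = 100,
                       n_planted_group_genes = 14,
                       n_planted_variants = 185,
                       background_aa_divergence = 0.005,
                       presence_flip_noise = 0,
                       mag_fraction = 0,
                       mag_completeness_range = c(90, 99),
                       mag_contamination_rate = 0.02,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_group1 + cfg$n_group2 >= 4,
            cfg$n_core_families >= 1, cfg$core_gene_len_aa >= 10,
            cfg$accessory_novel_per_genome >= 0, cfg$shared_accessory >= 0,
            cfg$n_planted_group_genes >= 0, cfg$n_planted_variants >= 0,
            cfg$background_aa_divergence >= 0,
            cfg$background_aa_divergence <= 1,
            cfg$presence_flip_noise >= 0, cfg$presence_flip_noise <= 1,
            cfg$mag_fraction >= 0, cfg$mag_fraction <= 1)
  if (cfg$n_planted_variants > cfg$n_core_families * cfg$core_gene_len_aa)
    stop("config error: more planted variants than core positions")
  structure(cfg, class = "sim_config")
}

#' Simulate a genome collection with planted ground truth
#'
#' Generates closely related bacterial genomes in two phenotype groups with
#' (i) a shared core whose proteins diverge by a background per-site mutation
#' rate, (ii) planted group-fixed amino-acid variants in core genes
#' (protected from background mutation, so the truth is exact), (iii) planted
#' group-1-specific gene families (with optional presence flip noise),
#' (iv) a shared 50%-presence accessory plus Poisson(u) genome-private novel
#' families (u > 0 makes the pangenome open), (v) reverse translation to DNA
#' (ancestral codons drawn uniformly among synonyms; mutated sites re-drawn)
#' and assembly into contigs with random spacers and strands, and (vi)
#' optional degradation of a fraction of genomes to MAG quality (gene loss +
#' contamination from another genome).
#'
#' @param cfg a [sim_config()].
#' @return list with `genomes` (list of `list(genome = genome_record,
#'   genes = <gene table>)`), `metadata` (data.frame), and `truth` (list:
#'   `planted_group_family_ids`, `planted_variants`, `gene_truth`,
#'   `family_content`, `regime`).
#' @export
simulate_collection <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  gids <- c(sprintf("PTB%02d", seq_len(cfg$n_group1)),
            sprintf("FTB%02d", seq_len(cfg$n_group2)))
  groups <- rep(c("PTB", "FTB"), c(cfg$n_group1, cfg$n_group2))
  G <- length(gids)
  L <- cfg$core_gene_len_aa
  gc11 <- Biostrings::getGeneticCode("11")
  codons_of <- split(names(gc11), unname(gc11))
  stops <- codons_of[["*"]]

  withr_seed(cfg$seed, {
    # --- ancestral core proteins and planted variants -----------------------
    core_ids <- sprintf("core_%05d", seq_len(cfg$n_core_families))
    anc <- lapply(core_ids, function(f) sample.int(20, L, replace = TRUE))
    names(anc) <- core_ids
    pv <- NULL
    protect <- setNames(vector("list", length(core_ids)), core_ids)
    if (cfg$n_planted_variants > 0) {
      slots <- sample.int(cfg$n_core_families * L, cfg$n_planted_variants)
      fam_i <- (slots - 1) %/% L + 1
      pos <- (slots - 1) %% L + 1
      res <- t(vapply(seq_along(slots), function(i) sample.int(20, 2),
                      integer(2)))
      pv <- data.frame(family_id = core_ids[fam_i], position = pos,
                       group1_residue = AA20[res[, 1]],
                       group2_residue = AA20[res[, 2]],
                       stringsAsFactors = FALSE)
      ordv <- order(pv$family_id, pv$position)
      pv <- pv[ordv, ]
      rownames(pv) <- NULL
      for (i in seq_len(nrow(pv)))
        protect[[pv$family_id[i]]] <- c(protect[[pv$family_id[i]]],
                                        pv$position[i])
      pv_res <- res[ordv, , drop = FALSE]
    }

    # --- accessory ancestries ----------------------------------------------
    acc_len <- function(n) sample(round(0.6 * L):round(1.2 * L), n,
                                  replace = TRUE)
    grp_ids <- if (cfg$n_planted_group_genes > 0)
      sprintf("grp_%03d", seq_len(cfg$n_planted_group_genes)) else character(0)
    grp_anc <- lapply(seq_along(grp_ids), function(i)
      sample.int(20, L, replace = TRUE))
    names(grp_anc) <- grp_ids
    acc_ids <- if (cfg$shared_accessory > 0)
      sprintf("acc_%04d", seq_len(cfg$shared_accessory)) else character(0)
    acc_lens <- acc_len(length(acc_ids))
    acc_anc <- lapply(seq_along(acc_ids), function(i)
      sample.int(20, acc_lens[i], replace = TRUE))
    names(acc_anc) <- acc_ids

    # presence tables
    grp_pres <- matrix(rep(groups == "PTB", each = length(grp_ids)),
                       nrow = length(grp_ids), ncol = G,
                       dimnames = list(grp_ids, gids))
    if (cfg$presence_flip_noise > 0 && length(grp_ids)) {
      flips <- matrix(runif(length(grp_pres)) < cfg$presence_flip_noise,
                      nrow = nrow(grp_pres))
      grp_pres <- xor(grp_pres, flips)
    }
    acc_pres <- matrix(runif(length(acc_ids) * G) < 0.5,
                       nrow = length(acc_ids), ncol = G,
                       dimnames = list(acc_ids, gids))

    # ancestral codons (shared across genomes; mutated sites re-drawn)
    anc_codons <- function(ints) {
      aa <- AA20[ints]
      cods <- character(length(ints))
      for (u in unique(aa))
        cods[aa == u] <- sample(codons_of[[u]], sum(aa == u), replace = TRUE)
      cods
    }
    all_anc <- c(anc, grp_anc, acc_anc)
    all_cod <- lapply(all_anc, anc_codons)
    all_stop <- vapply(all_anc, function(x) sample(stops, 1), "")

    mutate_ints <- function(v, protect_pos) {
      hit <- which(runif(length(v)) < cfg$background_aa_divergence)
      hit <- setdiff(hit, protect_pos)
      if (length(hit))
        v[hit] <- ((v[hit] - 1 + sample.int(19, length(hit), replace = TRUE))
                   %% 20) + 1
      v
    }
    recodon <- function(cods, anc_ints, ints) {
      ch <- which(ints != anc_ints)
      if (length(ch)) {
        aa <- AA20[ints[ch]]
        for (u in unique(aa))
          cods[ch[aa == u]] <- sample(codons_of[[u]], sum(aa == u),
                                      replace = TRUE)
      }
      cods
    }

    # --- per-genome gene sets ----------------------------------------------
    entries <- vector("list", G)
    gene_truth <- list()
    family_content <- setNames(vector("list", G), gids)
    nov_counter <- 0
    for (gi in seq_len(G)) {
      gid <- gids[gi]
      fams <- core_ids
      if (length(grp_ids)) fams <- c(fams, grp_ids[grp_pres[, gi]])
      if (length(acc_ids)) fams <- c(fams, acc_ids[acc_pres[, gi]])
      n_nov <- if (cfg$accessory_novel_per_genome > 0)
        rpois(1, cfg$accessory_novel_per_genome) else 0
      nov_ids <- if (n_nov > 0)
        sprintf("nov_%05d", nov_counter + seq_len(n_nov)) else character(0)
      nov_counter <- nov_counter + n_nov
      nov_lens <- acc_len(n_nov)
      nov_anc <- lapply(seq_len(n_nov), function(i)
        sample.int(20, nov_lens[i], replace = TRUE))
      names(nov_anc) <- nov_ids

      nt <- character(length(fams) + n_nov)
      aa <- character(length(fams) + n_nov)
      for (fi in seq_along(fams)) {
        f <- fams[fi]
        ints <- mutate_ints(all_anc[[f]], protect[[f]])
        if (!is.null(pv) && f %in% pv$family_id) {
          rows <- which(pv$family_id == f)
          ints[pv$position[rows]] <-
            if (groups[gi] == "PTB") pv_res[rows, 1] else pv_res[rows, 2]
        }
        cods <- recodon(all_cod[[f]], all_anc[[f]], ints)
        nt[fi] <- paste0(paste(cods, collapse = ""), all_stop[[f]])
        aa[fi] <- paste(AA20[ints], collapse = "")
      }
      for (ni in seq_len(n_nov)) {
        ints <- nov_anc[[ni]]
        cods <- anc_codons(ints)
        nt[length(fams) + ni] <- paste0(paste(cods, collapse = ""),
                                        sample(stops, 1))
        aa[length(fams) + ni] <- paste(AA20[ints], collapse = "")
      }
      truth_fams <- c(fams, nov_ids)
      gene_ids <- paste(gid, truth_fams, sep = "|")
      entries[[gi]] <- list(gid = gid, gene_ids = gene_ids,
                            truth_fams = truth_fams, nt = nt, aa = aa)
      family_content[[gid]] <- truth_fams
    }

    # --- MAG degradation -----------------------------------------------------
    is_mag <- rep(FALSE, G)
    comp <- rep(100, G)
    contam <- rep(0, G)
    n_mag <- round(cfg$mag_fraction * G)
    if (n_mag > 0) {
      mag_idx <- sort(sample.int(G, n_mag))
      for (gi in mag_idx) {
        is_mag[gi] <- TRUE
        target_comp <- runif(1, cfg$mag_completeness_range[1],
                             cfg$mag_completeness_range[2])
        e <- entries[[gi]]
        ntot <- length(e$gene_ids)
        keep <- runif(ntot) < target_comp / 100
        donor <- sample(setdiff(seq_len(G), gi), 1)
        dn <- entries[[donor]]
        n_con <- rbinom(1, ntot, cfg$mag_contamination_rate)
        pick <- if (n_con > 0) sample.int(length(dn$gene_ids),
                                          min(n_con, length(dn$gene_ids)))
                else integer(0)
        contam_ids <- if (length(pick))
          paste0(e$gid, "|contam|", dn$truth_fams[pick]) else character(0)
        entries[[gi]] <- list(
          gid = e$gid,
          gene_ids = make.unique(c(e$gene_ids[keep], contam_ids), sep = "_"),
          truth_fams = c(e$truth_fams[keep], dn$truth_fams[pick]),
          nt = c(e$nt[keep], dn$nt[pick]),
          aa = c(e$aa[keep], dn$aa[pick]))
        comp[gi] <- 100 * sum(keep) / ntot
        contam[gi] <- 100 * length(pick) / ntot
        family_content[[e$gid]] <- entries[[gi]]$truth_fams
      }
    }

    # --- assemble contigs, emit records --------------------------------------
    # gene orientation and intergenic spacers are ancestral (conserved within
    # the species); per-genome spacer copies diverge at the background rate
    all_fams <- unique(unlist(lapply(entries, `[[`, "truth_fams")))
    strand_anc <- setNames(sample(c("+", "-"), length(all_fams),
                                  replace = TRUE), all_fams)
    rand_nt <- function(lo = 80, hi = 120)
      paste(sample(c("A", "C", "G", "T"), sample(lo:hi, 1), replace = TRUE),
            collapse = "")
    spacer_anc <- setNames(vapply(all_fams, function(f) rand_nt(), ""),
                           all_fams)
    lead_anc <- rand_nt()
    genomes <- vector("list", G)
    for (gi in seq_len(G)) {
      e <- entries[[gi]]
      sp <- vapply(e$truth_fams, function(f)
        mutate_nt(spacer_anc[[f]], cfg$background_aa_divergence), "")
      rec <- assemble_genome(e$gid, e$gene_ids, e$nt, e$aa,
                             group = groups[gi],
                             source = if (is_mag[gi]) "MAG" else "ISOLATE",
                             completeness = comp[gi],
                             contamination = contam[gi],
                             strands = unname(strand_anc[e$truth_fams]),
                             spacers = unname(c(
                               mutate_nt(lead_anc,
                                         cfg$background_aa_divergence), sp)))
      genomes[[gi]] <- rec
      gene_truth[[gi]] <- data.frame(gene_id = e$gene_ids,
                                     truth_family = e$truth_fams,
                                     stringsAsFactors = FALSE)
    }
  })

  metadata <- data.frame(
    genome_id = gids, group = groups,
    source = vapply(genomes, function(g) g$genome$source, ""),
    completeness = vapply(genomes, function(g) g$genome$completeness, 0),
    contamination = vapply(genomes, function(g) g$genome$contamination, 0),
    stringsAsFactors = FALSE)

  truth <- list(
    planted_group_family_ids = grp_ids,
    planted_variants = pv,
    gene_truth = do.call(rbind, gene_truth),
    family_content = family_content,
    regime = if (cfg$accessory_novel_per_genome > 0) "OPEN" else "CLOSED")

  list(genomes = genomes, metadata = metadata, truth = truth, config = cfg)
}

# uniform substitutions over a plain ACGT string
mutate_nt <- function(s, rate) {
  if (rate <= 0) return(s)
  v <- strsplit(s, "")[[1]]
  i <- which(runif(length(v)) < rate)
  if (length(i)) {
    b <- c("A", "C", "G", "T")
    v[i] <- b[(match(v[i], b) +
                 sample(3, length(i), replace = TRUE) - 1) %% 4 + 1]
  }
  paste(v, collapse = "")
}

# build one genome entry from CDS sequences: one contig, 1-based inclusive
# coordinates; strands/spacers default to fresh random draws when not supplied
assemble_genome <- function(genome_id, gene_ids, nt, aa, group, source,
                            completeness, contamination,
                            strands = NULL, spacers = NULL) {
  n <- length(gene_ids)
  if (is.null(strands)) strands <- sample(c("+", "-"), n, replace = TRUE)
  if (is.null(spacers)) {
    spacer_len <- sample(80:120, n + 1, replace = TRUE)
    spacers <- vapply(spacer_len, function(l)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
            collapse = ""), "")
  }
  spacer_len <- nchar(spacers)
  segs <- character(2 * n + 1)
  starts <- integer(n)
  ends <- integer(n)
  off <- 0L
  for (i in seq_len(n)) {
    segs[2 * i - 1] <- spacers[i]
    off <- off + spacer_len[i]
    starts[i] <- off + 1L
    ends[i] <- off + nchar(nt[i])
    segs[2 * i] <- if (strands[i] == "-") revcomp(nt[i]) else nt[i]
    off <- ends[i]
  }
  segs[2 * n + 1] <- spacers[n + 1]
  contig <- paste(segs, collapse = "")
  contig_id <- paste0(genome_id, "_c1")
  rec <- genome_record(genome_id, setNames(contig, contig_id), group = group,
                       source = source, completeness = completeness,
                       contamination = contamination)
  genes <- data.frame(gene_id = gene_ids, genome_id = genome_id,
                      contig_id = contig_id, start = starts, end = ends,
                      strand = strands, nt_seq = nt, aa_seq = aa,
                      internal_stop = FALSE, stringsAsFactors = FALSE)
  list(genome = rec, genes = genes)
}

#' Degrade a genome to MAG quality
#'
#' Keeps each gene independently with probability `completeness/100`, adds
#' contaminating genes sampled from a donor genome at the given rate, and
#' reassembles the contig. Metadata fields are set to the realized values
#' (kept/total and added/total, as percentages).
#'
#' @param entry `list(genome = genome_record, genes = <gene table>)`.
#' @param completeness target completeness percent in (0, 100\].
#' @param contamination_rate expected contaminating fraction (of the
#'   original gene count).
#' @param donor entry providing contamination (must differ from the target).
#' @param seed RNG seed.
#' @return Degraded entry of the same shape.
#' @export
degrade_to_mag <- function(entry, completeness, contamination_rate, donor,
                           seed = 1) {
  stopifnot(completeness > 0, completeness <= 100, contamination_rate >= 0)
  if (identical(donor$genome$genome_id, entry$genome$genome_id))
    stop("donor must be a different genome")
  withr_seed(seed, {
    g <- entry$genes
    keep <- runif(nrow(g)) < completeness / 100
    n_con <- rbinom(1, nrow(g), contamination_rate)
    pick <- if (n_con > 0)
      sample.int(nrow(donor$genes), min(n_con, nrow(donor$genes)))
    else integer(0)
    dg <- donor$genes[pick, , drop = FALSE]
    if (nrow(dg)) dg$gene_id <- paste0(entry$genome$genome_id, "|contam|",
                                       dg$gene_id)
    out <- assemble_genome(
      entry$genome$genome_id,
      make.unique(c(g$gene_id[keep], dg$gene_id), sep = "_"),
      c(g$nt_seq[keep], dg$nt_seq),
      c(g$aa_seq[keep], dg$aa_seq),
      group = entry$genome$group, source = "MAG",
      completeness = 100 * sum(keep) / nrow(g),
      contamination = 100 * length(pick) / nrow(g))
  })
  out
}

#' Write or read a simulated collection as standard files
#'
#' Emits one nucleotide FASTA and one GFF3 (CDS features) per genome under
#' `dir/genomes/`, the metadata TSV, and the ground truth as JSON — the same
#' formats real annotated assemblies arrive in.
#'
#' @param sim result of [simulate_collection()].
#' @param dir output directory (created if needed).
#' @export
write_collection <- function(sim, dir) {
  gdir <- file.path(dir, "genomes")
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
  for (e in sim$genomes) {
    gid <- e$genome$genome_id
    write_fasta(e$genome$contigs, file.path(gdir, paste0(gid, ".fna")))
    gff <- c("##gff-version 3",
             sprintf("%s\tpangsig_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     e$genes$contig_id, e$genes$start, e$genes$end,
                     e$genes$strand, e$genes$gene_id))
    writeLines(gff, file.path(gdir, paste0(gid, ".gff3")))
  }
  write_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  if (!is.null(sim$truth))
    jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_collection
#' @param dir directory written by [write_collection()].
#' @return list with `genomes`, `metadata`, and `truth` (if present).
#' @export
read_collection <- function(dir) {
  metadata <- read_metadata(file.path(dir, "metadata.tsv"))
  genomes <- lapply(seq_len(nrow(metadata)), function(i) {
    gid <- metadata$genome_id[i]
    fa <- read_fasta(file.path(dir, "genomes", paste0(gid, ".fna")))
    rec <- genome_record(gid,
                         setNames(vapply(fa, `[[`, "", "seq"), names(fa)),
                         group = metadata$group[i],
                         source = if ("source" %in% names(metadata))
                           metadata$source[i] else "ISOLATE",
                         completeness = if ("completeness" %in% names(metadata))
                           metadata$completeness[i] else 100,
                         contamination = if ("contamination" %in% names(metadata))
                           metadata$contamination[i] else 0)
    genes <- read_gff_genes(file.path(dir, "genomes", paste0(gid, ".gff3")),
                            rec)
    list(genome = rec, genes = genes)
  })
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  list(genomes = genomes, metadata = metadata, truth = truth)
}
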