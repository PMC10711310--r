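#' Derive a per-stage RNG seed from the pipeline seed
#'
#' Stage names are hashed (polynomial over UTF-8 bytes, mod 2^31 - 1) and
#' combined with the base seed, so every stochastic stage gets its own
#' reproducible stream and adding a stage never perturbs another's.
#'
#' @param seed base integer seed.
#' @param stage stage name.
#' @return Integer seed in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(seed, stage) {
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% m
  as.integer((seed %% m + h) %% m)
}

#' Run the full comparative-pangenomics pipeline
#'
#' Stages, in order: QC filter -> gene-family clustering -> presence/absence
#' matrix -> partition + rarefaction + Heaps' fit -> group association ->
#' core-family alignments -> group-variant scan -> core-genome NJ tree with
#' bootstrap -> (optional) ANI matrix -> (optional) marker profile. Each
#' stage writes fixed-name artifacts under `out_dir/<stage>/` and is recorded
#' in a manifest (configuration echo, per-stage seeds, output MD5 hashes and
#' record counts).
#'
#' @param collection list with `genomes` and `metadata`
#'   ([simulate_collection()] / [read_collection()] shape).
#' @param out_dir output directory.
#' @param identity_threshold gene-family clustering identity.
#' @param core_frac,shell_min_frac partition thresholds.
#' @param min_completeness,max_contamination QC gates.
#' @param groups the two phenotype labels (group 1 first).
#' @param n_permutations rarefaction permutations.
#' @param n_bootstrap bootstrap replicates.
#' @param seed base seed for all stochastic stages.
#' @param markers optional [marker_set()] for profiling.
#' @param run_ani compute the pairwise ANI matrix (costly for many genomes).
#' @param ani_max_fragments fragment cap per genome pair, see
#'   [fragment_ani()].
#' @param skip character vector of stage names to skip (downstream stages
#'   that do not depend on them still run): any of `"tree"`, `"ani"`,
#'   `"profile"`.
#' @return The run manifest (list), invisibly; artifacts under `out_dir`.
#' @export
run_pipeline <- function(collection, out_dir,
                         identity_threshold = 0.95,
                         core_frac = 0.95, shell_min_frac = 0.15,
                         min_completeness = 90, max_contamination = 5,
                         groups = c("PTB", "FTB"),
                         n_permutations = 100, n_bootstrap = 100,
                         seed = 1, markers = NULL, run_ani = FALSE,
                         ani_max_fragments = 50, skip = character(0)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pangsig")),
    seed = seed,
    config = list(identity_threshold = identity_threshold,
                  core_frac = core_frac, shell_min_frac = shell_min_frac,
                  min_completeness = min_completeness,
                  max_contamination = max_contamination,
                  groups = groups, n_permutations = n_permutations,
                  n_bootstrap = n_bootstrap,
                  run_ani = run_ani && !("ani" %in% skip),
                  ani_max_fragments = ani_max_fragments, skip = skip),
    stages = list())
  t_all <- proc.time()[["elapsed"]]
  record <- function(stage, outputs, n_in, n_out, t0, skipped = FALSE) {
    manifest$stages[[stage]] <<- list(
      stage = stage, skipped = skipped,
      seed = derive_seed(seed, stage),
      outputs = outputs,
      md5 = if (length(outputs)) unname(tools::md5sum(outputs)) else character(0),
      n_in = n_in, n_out = n_out,
      wall_seconds = round(proc.time()[["elapsed"]] - t0, 3))
    message(sprintf("[%s] %s: %d in, %d out (%.1fs)", stage,
                    if (skipped) "skipped" else "done", n_in, n_out,
                    manifest$stages[[stage]]$wall_seconds))
  }
  stage_dir <- function(stage) {
    d <- file.path(out_dir, stage)
    dir.create(d, showWarnings = FALSE)
    d
  }

  # --- qc ------------------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  qc <- filter_genomes(collection$metadata, min_completeness,
                       max_contamination)
  keep <- vapply(collection$genomes,
                 function(e) e$genome$genome_id %in% qc$kept, logical(1))
  genomes <- collection$genomes[keep]
  metadata <- collection$metadata[collection$metadata$genome_id %in% qc$kept, ]
  gids <- metadata$genome_id
  d <- stage_dir("qc")
  write_metadata(metadata, file.path(d, "metadata_kept.tsv"))
  write.table(qc$dropped, file.path(d, "dropped.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  record("qc", file.path(d, c("metadata_kept.tsv", "dropped.tsv")),
         nrow(collection$metadata), length(gids), t0)
  if (length(gids) < 2) stop("stage qc: fewer than 2 genomes pass the gates")

  # --- cluster -------------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  fams <- cluster_gene_families(genomes, identity_threshold)
  d <- stage_dir("cluster")
  reps <- data.frame(family_id = names(fams$families),
                     representative = unname(fams$representative),
                     n_members = unname(lengths(fams$families)))
  write.table(reps, file.path(d, "families.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(paralog_report(fams), file.path(d, "paralogs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  record("cluster", file.path(d, c("families.tsv", "paralogs.tsv")),
         nrow(fams$genes), length(fams$families), t0)

  # --- matrix --------------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  m <- build_matrix(fams, gids)
  d <- stage_dir("matrix")
  write_presence_absence(m, file.path(d, "gene_presence_absence.Rtab"))
  record("matrix", file.path(d, "gene_presence_absence.Rtab"),
         length(fams$families), nrow(m), t0)

  # --- pangenome (partition + rarefaction + Heaps) -------------------------
  t0 <- proc.time()[["elapsed"]]
  part <- partition_pangenome(m, core_frac, shell_min_frac)
  curve <- rarefaction_curve(m, n_permutations,
                             seed = derive_seed(seed, "pangenome"))
  heaps <- fit_heaps(curve)
  d <- stage_dir("pangenome")
  write.table(part$table, file.path(d, "partition.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(curve, file.path(d, "rarefaction.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(jsonlite::toJSON(list(kappa = heaps$kappa, gamma = heaps$gamma,
                                   openness = heaps$openness),
                              auto_unbox = TRUE, digits = NA),
             file.path(d, "heaps.json"))
  record("pangenome",
         file.path(d, c("partition.tsv", "rarefaction.tsv", "heaps.json")),
         nrow(m), nrow(part$table), t0)

  # --- association ---------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  assoc <- associate_families(m, metadata, groups)
  d <- stage_dir("association")
  write_association(assoc, file.path(d, "association.tsv"))
  record("association", file.path(d, "association.tsv"), nrow(m),
         nrow(assoc), t0)

  # --- core alignments + variant scan --------------------------------------
  t0 <- proc.time()[["elapsed"]]
  msas <- core_family_msas(fams, gids)
  variants <- lapply(msas, scan_group_variants, metadata = metadata,
                     target_group = groups[1], strict = TRUE)
  vsum <- summarize_variants(variants, min_count = 2)
  d <- stage_dir("variants")
  write_variants(variants, file.path(d, "group_variants.tsv"))
  write.table(vsum$report, file.path(d, "variant_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  record("variants",
         file.path(d, c("group_variants.tsv", "variant_summary.tsv")),
         length(msas), vsum$total_variants, t0)

  # --- tree ----------------------------------------------------------------
  tree <- NULL
  t0 <- proc.time()[["elapsed"]]
  if (!("tree" %in% skip)) {
    concat <- concatenate_core_alignment(msas, gids)
    tree <- bootstrap_supports(concat, n_bootstrap,
                               seed = derive_seed(seed, "tree"))
    d <- stage_dir("tree")
    write_newick(tree, file.path(d, "core_genome_nj.nwk"))
    record("tree", file.path(d, "core_genome_nj.nwk"), length(msas),
           length(tree$tip.label), t0)
  } else record("tree", character(0), 0, 0, t0, skipped = TRUE)

  # --- ani -----------------------------------------------------------------
  ani <- NULL
  t0 <- proc.time()[["elapsed"]]
  if (run_ani && !("ani" %in% skip)) {
    ani <- ani_matrix(lapply(genomes, `[[`, "genome"),
                      max_fragments = ani_max_fragments)
    d <- stage_dir("ani")
    write.table(data.frame(genome_id = rownames(ani), ani,
                           check.names = FALSE),
                file.path(d, "ani_matrix.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    record("ani", file.path(d, "ani_matrix.tsv"), length(genomes),
           length(genomes), t0)
  } else record("ani", character(0), 0, 0, t0, skipped = TRUE)

  # --- marker profile ------------------------------------------------------
  profile <- NULL
  t0 <- proc.time()[["elapsed"]]
  if (!is.null(markers) && !("profile" %in% skip)) {
    profile <- profile_markers(markers, genomes)
    d <- stage_dir("profile")
    write_marker_profile(profile, file.path(d, "marker_profile.tsv"))
    write.table(profile$best_hits, file.path(d, "marker_hits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    record("profile",
           file.path(d, c("marker_profile.tsv", "marker_hits.tsv")),
           length(markers$markers), sum(profile$matrix), t0)
  } else record("profile", character(0), 0, 0, t0, skipped = TRUE)

  manifest$wall_seconds <- round(proc.time()[["elapsed"]] - t_all, 3)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(manifest = manifest, qc = qc, families = fams, matrix = m,
                 partition = part, curve = curve, heaps = heaps,
                 association = assoc, msas = msas, variants = variants,
                 variant_summary = vsum, tree = tree, ani = ani,
                 profile = profile))
}
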