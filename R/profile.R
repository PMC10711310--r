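#' Quality-gate a genome collection
#'
#' Keeps genomes with completeness >= `min_completeness` and contamination
#' strictly below `max_contamination` (the MAG high-quality convention:
#' completeness >= 90%, contamination < 5%). Idempotent and
#' order-independent.
#'
#' @param metadata metadata table with `genome_id`, `completeness`,
#'   `contamination`.
#' @param min_completeness percent floor (default 90).
#' @param max_contamination strict percent ceiling (default 5).
#' @return list with `kept` (ids) and `dropped`
#'   (data.frame `genome_id`, `reason`).
#' @export
filter_genomes <- function(metadata, min_completeness = 90,
                           max_contamination = 5) {
  req <- c("genome_id", "completeness", "contamination")
  if (!all(req %in% names(metadata)) ||
      anyNA(metadata[, c("completeness", "contamination")]))
    stop("metadata error: completeness/contamination required for every genome")
  low_cmp <- metadata$completeness < min_completeness
  high_con <- metadata$contamination >= max_contamination
  reason <- ifelse(low_cmp & high_con, "completeness;contamination",
                   ifelse(low_cmp, "completeness",
                          ifelse(high_con, "contamination", "")))
  list(kept = metadata$genome_id[reason == ""],
       dropped = data.frame(genome_id = metadata$genome_id[reason != ""],
                            reason = reason[reason != ""],
                            stringsAsFactors = FALSE))
}

#' Construct a marker set
#'
#' A database of marker proteins (e.g. the genes of a cell-surface synthesis
#' cluster) with the identity and marker-coverage thresholds a hit must meet.
#'
#' @param markers named character vector of protein sequences.
#' @param min_identity identity floor in (0, 1\] (default 0.7).
#' @param min_coverage fraction of the marker the local alignment must span,
#'   in (0, 1\] (default 0.8).
#' @return A `marker_set`.
#' @export
marker_set <- function(markers, min_identity = 0.7, min_coverage = 0.8) {
  stopifnot(is.character(markers), length(markers) >= 1,
            !is.null(names(markers)), all(nzchar(markers)),
            min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  structure(list(markers = markers, min_identity = min_identity,
                 min_coverage = min_coverage), class = "marker_set")
}

#' Profile marker presence/absence across genomes
#'
#' BLASTp-like seeded search: for each (marker, genome), candidate genes are
#' those sharing at least two 6-mers with the marker (all genes for very
#' short markers); the best local alignment by score wins, ties broken by
#' gene id. A marker is present in a genome iff its best hit reaches the
#' marker set's identity and marker-coverage thresholds. Coverage is
#' measured on the marker, so fused or split genes in MAGs still count.
#'
#' @param markers a [marker_set()].
#' @param genomes list of `list(genome = genome_record, genes = <gene table>)`.
#' @param scheme protein [scoring_scheme()].
#' @return A `marker_profile`: list with `matrix` (markers x genomes, 0/1)
#'   and `best_hits` (data.frame `marker_id`, `genome_id`, `gene_id`,
#'   `identity`, `coverage`, `score`).
#' @export
profile_markers <- function(markers, genomes,
                            scheme = scoring_scheme_protein()) {
  stopifnot(inherits(markers, "marker_set"), length(genomes) >= 1)
  gids <- vapply(genomes, function(g) g$genome$genome_id, "")
  mids <- names(markers$markers)
  mat <- matrix(0L, length(mids), length(gids), dimnames = list(mids, gids))
  hits <- list()
  k <- 6L
  kmers_of <- function(s) {
    L <- nchar(s)
    if (L < k) character(0) else unique(substring(s, 1:(L - k + 1), k:L))
  }
  mk <- lapply(markers$markers, kmers_of)
  for (gi in seq_along(genomes)) {
    genes <- genomes[[gi]]$genes
    if (is.null(genes) || nrow(genes) == 0) next
    gk <- lapply(genes$aa_seq, kmers_of)
    ord <- order(genes$gene_id)
    for (mi in seq_along(mids)) {
      m_seq <- markers$markers[[mi]]
      shared <- vapply(gk, function(x) sum(x %in% mk[[mi]]), integer(1))
      cand <- if (nchar(m_seq) < 20) ord else ord[shared[ord] >= 2]
      best <- NULL
      for (ci in cand) {
        al <- align_local(m_seq, genes$aa_seq[ci], scheme)
        if (is.null(best) || al$score > best$al$score)
          best <- list(al = al, gene = genes$gene_id[ci])
      }
      if (is.null(best) || best$al$score <= 0) next
      ident <- best$al$identity
      cov <- best$al$coverage_a
      hits[[length(hits) + 1]] <- data.frame(
        marker_id = mids[mi], genome_id = gids[gi], gene_id = best$gene,
        identity = ident, coverage = cov, score = best$al$score,
        stringsAsFactors = FALSE)
      if (ident >= markers$min_identity && cov >= markers$min_coverage)
        mat[mi, gi] <- 1L
    }
  }
  best_hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(marker_id = character(0), genome_id = character(0),
               gene_id = character(0), identity = numeric(0),
               coverage = numeric(0), score = numeric(0),
               stringsAsFactors = FALSE)
  structure(list(matrix = mat, best_hits = best_hits,
                 min_identity = markers$min_identity,
                 min_coverage = markers$min_coverage),
            class = "marker_profile")
}

#' Per-clade presence fractions of profiled markers
#'
#' For each (marker, clade): the fraction of that clade's genomes carrying
#' the marker; per-marker concordance is the absolute difference between the
#' two clades' fractions (max minus min when more than two clades).
#'
#' @param profile a [profile_markers()] result.
#' @param clades named character vector: genome id -> clade label.
#' @return data.frame with one row per marker: a `frac_<clade>` column per
#'   clade plus `concordance`.
#' @export
clade_concordance <- function(profile, clades) {
  stopifnot(inherits(profile, "marker_profile"))
  gids <- colnames(profile$matrix)
  miss <- setdiff(gids, names(clades))
  if (length(miss))
    stop("genome(s) without a clade assignment: ", paste(miss, collapse = ", "))
  cl <- clades[gids]
  lv <- sort(unique(cl))
  if (any(!table(factor(cl, lv))))
    stop("every clade must contain at least one genome")
  fr <- sapply(lv, function(x)
    rowMeans(profile$matrix[, cl == x, drop = FALSE]))
  fr <- matrix(fr, nrow = nrow(profile$matrix),
               dimnames = list(rownames(profile$matrix), paste0("frac_", lv)))
  out <- data.frame(marker_id = rownames(profile$matrix), fr,
                    concordance = apply(fr, 1, function(z) max(z) - min(z)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a marker profile as TSV (markers x genomes 0/1)
#'
#' The thresholds used are echoed in header comment lines for provenance.
#'
#' @param profile a [profile_markers()] result.
#' @param path TSV file.
#' @export
write_marker_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# min_identity=%g min_coverage=%g",
                     profile$min_identity, profile$min_coverage), con)
  df <- data.frame(Marker = rownames(profile$matrix), profile$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
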