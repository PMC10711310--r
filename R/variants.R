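#' Scan a core-gene alignment for group-exclusive amino-acid variants
#'
#' Finds alignment columns where the target phenotype group carries residues
#' never observed in the other group — the protein-level notion of
#' "non-synonymous mutations specific to" one group (aligned amino-acid
#' differences are non-synonymous by construction).
#'
#' Strict mode (default): a column qualifies iff every target-group row
#' carries the same residue (no gaps in the target group) and that residue is
#' absent from every other-group row (other-group gaps are permitted).
#' Lenient mode: rows with gaps are ignored and the column qualifies iff the
#' two groups' residue sets are non-empty and disjoint.
#'
#' @param msa an `msa` whose row names are genome ids.
#' @param metadata metadata table with `genome_id` and `group`.
#' @param target_group group whose fixed residues are sought (e.g. `"PTB"`).
#' @param strict logical; see above.
#' @return data.frame `column` (1-based), `target_residues`,
#'   `other_residues` (comma-collapsed sets), `strict`.
#' @export
scan_group_variants <- function(msa, metadata, target_group = "PTB",
                                strict = TRUE) {
  validate_metadata(metadata)
  ids <- names(msa)
  miss <- setdiff(ids, metadata$genome_id)
  if (length(miss))
    stop("alignment row(s) missing from metadata: ",
         paste(miss, collapse = ", "))
  grp <- setNames(metadata$group, metadata$genome_id)[ids]
  tgt <- grp == target_group
  oth <- grp != target_group & grp != "UNKNOWN"
  if (!any(tgt) || !any(oth))
    stop("both the target and the other group must be represented")
  mm <- msa_matrix(msa)
  tm <- mm[tgt, , drop = FALSE]
  om <- mm[oth, , drop = FALSE]
  hits <- integer(0)
  tres <- character(0)
  ores <- character(0)
  for (j in seq_len(ncol(mm))) {
    tj <- tm[, j]
    oj <- om[, j]
    if (strict) {
      u <- unique(tj)
      if (length(u) != 1 || u == "-") next
      if (u %in% oj) next
      hits <- c(hits, j)
      tres <- c(tres, u)
      ores <- c(ores, paste(sort(unique(oj[oj != "-"])), collapse = ","))
    } else {
      ts <- unique(tj[tj != "-"])
      os <- unique(oj[oj != "-"])
      if (!length(ts) || !length(os) || length(intersect(ts, os))) next
      hits <- c(hits, j)
      tres <- c(tres, paste(sort(ts), collapse = ","))
      ores <- c(ores, paste(sort(os), collapse = ","))
    }
  }
  data.frame(column = hits, target_residues = tres, other_residues = ores,
             strict = rep(strict, length(hits)), stringsAsFactors = FALSE)
}

#' Summarize group-exclusive variants across families
#'
#' Counts variants per family and filters the report to families with at
#' least `min_count` variants (the convention used when plotting per-gene
#' variant loads); totals cover all families regardless of the filter.
#'
#' @param per_family_variants named list: family id -> data.frame from
#'   [scan_group_variants()].
#' @param min_count minimum variants for a family to enter the report.
#' @param annotations optional named character vector (family id -> gene
#'   annotation, e.g. `ldhD`), passed through to the report.
#' @return A `variant_summary`: list with `report` (family_id, n_variants,
#'   annotation), `total_variants`, `total_families_with_variants`.
#' @export
summarize_variants <- function(per_family_variants, min_count = 2,
                               annotations = NULL) {
  counts <- vapply(per_family_variants, nrow, integer(1))
  keep <- counts >= min_count
  report <- data.frame(family_id = names(counts)[keep],
                       n_variants = unname(counts[keep]),
                       stringsAsFactors = FALSE)
  report$annotation <- if (!is.null(annotations))
    unname(annotations[report$family_id]) else
      rep(NA_character_, nrow(report))
  if (nrow(report) > 0)
    report <- report[order(-report$n_variants, report$family_id), ,
                     drop = FALSE]
  rownames(report) <- NULL
  structure(list(report = report,
                 total_variants = sum(counts),
                 total_families_with_variants = sum(counts > 0)),
            class = "variant_summary")
}

#' @export
print.variant_summary <- function(x, ...) {
  cat(sprintf("group-exclusive variants: %d in %d families (%d families pass the report filter)\n",
              x$total_variants, x$total_families_with_variants,
              nrow(x$report)))
  invisible(x)
}

#' Write per-family variant tables as one TSV
#' @param per_family_variants named list of [scan_group_variants()] results.
#' @param path TSV file.
#' @export
write_variants <- function(per_family_variants, path) {
  rows <- lapply(names(per_family_variants), function(f) {
    v <- per_family_variants[[f]]
    if (nrow(v) == 0) return(NULL)
    cbind(family_id = f, v)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(family_id = character(0), column = integer(0),
                      target_residues = character(0),
                      other_residues = character(0), strict = logical(0))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
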