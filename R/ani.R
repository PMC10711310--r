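#' Fragment-based average nucleotide identity
#'
#' fastANI-style one-way ANI: the query genome's contigs are split into
#' consecutive `frag_len` windows (tails shorter than `frag_len` discarded);
#' each fragment is placed on the reference by shared 16-mer seeding (best
#' exact diagonal), locally aligned to the corresponding reference window,
#' and counted when the local alignment covers at least `min_frag_coverage`
#' of the fragment at identity >= `min_frag_identity`. ANI is 100 x the mean
#' identity over counted fragments. If no fragment passes, the ANI is
#' undefined (`NA`), never 0.
#'
#' ANI is approximately symmetric; query and reference roles are not
#' averaged silently — swap the arguments to measure the other direction.
#'
#' @param a query [genome_record()].
#' @param b reference [genome_record()].
#' @param frag_len fragment length (default 1000 bp).
#' @param min_frag_identity per-fragment identity floor (default 0.8).
#' @param min_frag_coverage fraction of the fragment the local alignment must
#'   span (default 0.9).
#' @param max_fragments use at most this many fragments, evenly spaced along
#'   the query (default all); a problem-size knob for large collections.
#' @param scheme DNA [scoring_scheme()].
#' @return An `ani_result`: list with `query_id`, `ref_id`, `ani` (percent or
#'   `NA`), `fragments_used`, `fragments_total`.
#' @export
fragment_ani <- function(a, b, frag_len = 1000, min_frag_identity = 0.8,
                         min_frag_coverage = 0.9, max_fragments = Inf,
                         scheme = scoring_scheme_dna()) {
  stopifnot(inherits(a, "genome_record"), inherits(b, "genome_record"))
  if (sum(nchar(a$contigs)) < frag_len || sum(nchar(b$contigs)) < frag_len)
    stop("both genomes must be at least one fragment long")
  frags <- character(0)
  for (ct in a$contigs) {
    nw <- nchar(ct) %/% frag_len
    if (nw >= 1)
      frags <- c(frags, substring(ct, (0:(nw - 1)) * frag_len + 1,
                                  (1:nw) * frag_len))
  }
  total <- length(frags)
  if (total == 0)
    return(structure(list(query_id = a$genome_id, ref_id = b$genome_id,
                          ani = NA_real_, fragments_used = 0L,
                          fragments_total = 0L), class = "ani_result"))
  if (is.finite(max_fragments) && max_fragments < total) {
    pick <- unique(round(seq(1, total, length.out = max_fragments)))
    frags <- frags[pick]
  }
  # seed in both orientations (genes may lie on either strand of the
  # reference); per fragment the orientation with more seed votes wins
  frags_rc <- revcomp(frags)
  hits_f <- .map_fragments(frags, unname(b$contigs), 16L, 64L)
  hits_r <- .map_fragments(frags_rc, unname(b$contigs), 16L, 64L)
  margin <- 50L
  idents <- rep(NA_real_, length(frags))
  for (f in seq_along(frags)) {
    fwd <- !is.na(hits_f$contig[f]) &&
      (is.na(hits_r$contig[f]) || hits_f$votes[f] >= hits_r$votes[f])
    hits <- if (fwd) hits_f else hits_r
    ci <- hits$contig[f]
    if (is.na(ci)) next
    ct <- b$contigs[[ci]]
    lo <- max(1L, hits$diag[f] + 1L - margin)
    hi <- min(nchar(ct), hits$diag[f] + frag_len + margin)
    if (hi - lo + 1 < 16) next
    al <- align_local(if (fwd) frags[f] else frags_rc[f],
                      substr(ct, lo, hi), scheme)
    if (al$coverage_a >= min_frag_coverage) idents[f] <- al$identity
  }
  used <- !is.na(idents) & idents >= min_frag_identity
  structure(list(query_id = a$genome_id, ref_id = b$genome_id,
                 ani = if (any(used)) 100 * mean(idents[used]) else NA_real_,
                 fragments_used = sum(used),
                 fragments_total = length(frags)),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("ANI %s -> %s: %s (%d/%d fragments)\n", x$query_id, x$ref_id,
              if (is.na(x$ani)) "undefined" else sprintf("%.2f%%", x$ani),
              x$fragments_used, x$fragments_total))
  invisible(x)
}

#' Pairwise ANI matrix over a genome collection
#'
#' One-way [fragment_ani()] for every ordered pair; the diagonal is 100.
#'
#' @param genomes list of [genome_record()]s.
#' @param ... passed to [fragment_ani()].
#' @return Numeric matrix (queries x references), `NA` where undefined.
#' @export
ani_matrix <- function(genomes, ...) {
  ids <- vapply(genomes, `[[`, "", "genome_id")
  n <- length(genomes)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    m[i, j] <- fragment_ani(genomes[[i]], genomes[[j]], ...)$ani
  }
  m
}

#' Assign a genome to a species by best ANI against references
#'
#' The genome takes the species of the reference with the highest defined
#' ANI, provided that ANI meets `threshold` (the conventional 95% species
#' boundary); otherwise `"UNASSIGNED"`. Ties break to the lexicographically
#' smallest species name.
#'
#' @param genome query [genome_record()].
#' @param refs list of `list(species =, genome = genome_record)`.
#' @param threshold ANI percent cutoff (default 95).
#' @param ... passed to [fragment_ani()].
#' @return list with `species` (or `"UNASSIGNED"`), `best_ani`, and the
#'   per-reference `ani` vector.
#' @export
assign_species_by_ani <- function(genome, refs, threshold = 95, ...) {
  stopifnot(length(refs) >= 1)
  species <- vapply(refs, `[[`, "", "species")
  ani <- vapply(refs, function(r)
    fragment_ani(genome, r$genome, ...)$ani, numeric(1))
  names(ani) <- species
  if (all(is.na(ani)))
    return(list(species = "UNASSIGNED", best_ani = NA_real_, ani = ani))
  ok <- which(!is.na(ani))
  ord <- ok[order(-ani[ok], species[ok])]
  best <- ord[1]
  list(species = if (ani[best] >= threshold) species[best] else "UNASSIGNED",
       best_ani = unname(ani[best]), ani = ani)
}
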