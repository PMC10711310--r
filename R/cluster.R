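#' Cluster proteins into gene families at an identity threshold
#'
#' Greedy incremental (CD-HIT-like) clustering: proteins are sorted by
#' decreasing length (ties by gene id), and each protein joins the first
#' existing family (in founding order) whose representative it matches at
#' global-alignment identity >= `threshold` (identity = matches / columns,
#' gaps counting against); otherwise it founds a new family with itself as
#' representative. The procedure is deterministic and invariant to the input
#' order of genomes.
#'
#' A conservative shared-k-mer prescreen (k = 5) skips representatives that
#' provably cannot reach the threshold, so no alignment that matters is ever
#' skipped: a pair at identity >= t over lengths (La, Lb) shares at least
#' `(min - k + 1) - k * (ceil((1 - t)/t * max) + 1)` k-mers, and identity is
#' bounded above by `min/max`.
#'
#' @param genomes list of `list(genome = genome_record, genes = <gene table>)`
#'   as produced by [read_gff_genes()] or [simulate_collection()].
#' @param threshold identity threshold in (0, 1\]; default 0.95, the
#'   conventional within-species gene-family cutoff.
#' @param scheme protein [scoring_scheme()].
#' @return A `gene_family_set`: list with `families` (named list: family id ->
#'   member gene ids), `representative` (family id -> gene id), `genes` (the
#'   pooled gene table), `identity_threshold`.
#' @export
cluster_gene_families <- function(genomes, threshold = 0.95,
                                  scheme = scoring_scheme_protein()) {
  stopifnot(threshold > 0, threshold <= 1)
  genes <- do.call(rbind, lapply(genomes, `[[`, "genes"))
  if (is.null(genes) || nrow(genes) == 0)
    stop("cluster_gene_families() needs at least one gene")
  if (any(!nzchar(genes$aa_seq)))
    stop("every gene needs a non-empty aa_seq")
  if (anyDuplicated(genes$gene_id))
    stop("gene ids must be unique across the collection")
  ord <- order(-nchar(genes$aa_seq), genes$gene_id)
  genes <- genes[ord, , drop = FALSE]

  k <- 5L
  n <- nrow(genes)
  seqs <- genes$aa_seq
  lens <- nchar(seqs)

  rep_idx <- integer(0)      # gene index of each family representative
  rep_len <- numeric(0)
  assignment <- integer(n)   # family id per gene
  index <- new.env(parent = emptyenv()) # kmer -> integer vector of family ids
  counts <- integer(0)       # scratch: shared-kmer counts per family

  kmers_of <- function(s, L) {
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1), k:L))
  }

  for (g in seq_len(n)) {
    s <- seqs[g]
    L <- lens[g]
    km <- kmers_of(s, L)
    nf <- length(rep_idx)
    fam <- 0L
    if (nf > 0) {
      tab <- integer(nf)
      for (x in km) {
        hit <- get0(x, envir = index, ifnotfound = NULL)
        if (!is.null(hit)) tab[hit] <- tab[hit] + 1L
      }
      lo <- pmin(L, rep_len)
      hi <- pmax(L, rep_len)
      len_ok <- lo / hi >= threshold
      bound <- (lo - k + 1) - k * (ceiling((1 - threshold) / threshold * hi) + 1)
      cand <- which(len_ok & (bound < 1 | tab >= bound))
      for (f in cand) {
        al <- align_global(s, seqs[rep_idx[f]], scheme)
        if (al$identity >= threshold) { fam <- f; break }
      }
    }
    if (fam == 0L) {
      rep_idx <- c(rep_idx, g)
      rep_len <- c(rep_len, L)
      fam <- length(rep_idx)
      for (x in km)
        assign(x, c(get0(x, envir = index, ifnotfound = NULL), fam),
               envir = index)
    }
    assignment[g] <- fam
  }

  fam_ids <- sprintf("fam_%05d", seq_along(rep_idx))
  families <- split(genes$gene_id, factor(assignment, seq_along(rep_idx)))
  names(families) <- fam_ids
  structure(list(
    families = families,
    representative = setNames(genes$gene_id[rep_idx], fam_ids),
    genes = genes,
    identity_threshold = threshold
  ), class = "gene_family_set")
}

#' Rebuild a gene family set from a serialized membership table
#'
#' Inverse of writing `data.frame(family_id, gene_id)` membership: lets a
#' downstream analysis stage reconstruct families from artifacts without
#' re-clustering. The representative is taken as each family's first member
#' in the stored order.
#'
#' @param membership data.frame with `family_id` and `gene_id`.
#' @param genes pooled gene table covering every member gene.
#' @param identity_threshold threshold the membership was built at.
#' @return A `gene_family_set`.
#' @export
as_gene_family_set <- function(membership, genes, identity_threshold = 0.95) {
  stopifnot(all(c("family_id", "gene_id") %in% names(membership)),
            all(membership$gene_id %in% genes$gene_id))
  families <- split(membership$gene_id,
                    factor(membership$family_id,
                           unique(membership$family_id)))
  structure(list(
    families = as.list(families),
    representative = vapply(families, `[`, "", 1),
    genes = genes[genes$gene_id %in% membership$gene_id, , drop = FALSE],
    identity_threshold = identity_threshold
  ), class = "gene_family_set")
}

#' @export
print.gene_family_set <- function(x, ...) {
  sizes <- lengths(x$families)
  cat(sprintf("gene family set: %d genes in %d families (threshold %.2f); largest family %d members\n",
              nrow(x$genes), length(x$families), x$identity_threshold,
              max(sizes)))
  invisible(x)
}

#' Build the gene-family presence/absence matrix
#'
#' Binary families x genomes matrix; a cell is 1 iff at least one member gene
#' of the family comes from that genome (paralogs collapse to a single 1).
#'
#' @param fams a [cluster_gene_families()] result.
#' @param genome_ids ordered genome ids (must cover every genome referenced).
#' @return Integer matrix with family rownames and genome colnames.
#' @export
build_matrix <- function(fams, genome_ids) {
  stopifnot(inherits(fams, "gene_family_set"))
  gmap <- setNames(fams$genes$genome_id, fams$genes$gene_id)
  ref <- unique(unname(gmap))
  if (!all(ref %in% genome_ids))
    stop("genome(s) referenced by families but absent from genome_ids: ",
         paste(setdiff(ref, genome_ids), collapse = ", "))
  m <- matrix(0L, length(fams$families), length(genome_ids),
              dimnames = list(names(fams$families), genome_ids))
  for (f in names(fams$families)) {
    m[f, unique(unname(gmap[fams$families[[f]]]))] <- 1L
  }
  m
}

#' Per-genome paralog report
#'
#' Families contributing two or more genes from the same genome collapse to a
#' single presence in the matrix; this side report surfaces them.
#'
#' @param fams a [cluster_gene_families()] result.
#' @return data.frame `family_id`, `genome_id`, `n_copies` (only rows with
#'   `n_copies >= 2`).
#' @export
paralog_report <- function(fams) {
  gmap <- setNames(fams$genes$genome_id, fams$genes$gene_id)
  out <- do.call(rbind, lapply(names(fams$families), function(f) {
    tab <- table(gmap[fams$families[[f]]])
    tab <- tab[tab >= 2]
    if (!length(tab)) return(NULL)
    data.frame(family_id = f, genome_id = names(tab),
               n_copies = as.integer(tab), stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(family_id = character(0), genome_id = character(0),
                      n_copies = integer(0), stringsAsFactors = FALSE)
  out
}

#' Per-family, per-genome multiple alignments of core families
#'
#' For each requested family present in every genome, picks one member gene
#' per genome (smallest gene id when paralogs exist), aligns the proteins
#' with [center_star_msa()], and names rows by genome id — the shape needed
#' by the group-variant scanner and the core-genome concatenation.
#'
#' @param fams a [cluster_gene_families()] result.
#' @param genome_ids genomes that must all be covered.
#' @param family_ids families to align (default: all families present in
#'   every genome).
#' @param scheme protein [scoring_scheme()].
#' @return Named list family id -> `msa` (rows = genome ids).
#' @export
core_family_msas <- function(fams, genome_ids, family_ids = NULL,
                             scheme = scoring_scheme_protein()) {
  gmap <- setNames(fams$genes$genome_id, fams$genes$gene_id)
  smap <- setNames(fams$genes$aa_seq, fams$genes$gene_id)
  covers <- vapply(fams$families, function(gg)
    all(genome_ids %in% gmap[gg]), logical(1))
  if (is.null(family_ids)) family_ids <- names(fams$families)[covers]
  else if (!all(covers[family_ids]))
    stop("family not present in every genome: ",
         paste(family_ids[!covers[family_ids]], collapse = ", "))
  out <- lapply(family_ids, function(f) {
    gg <- sort(fams$families[[f]])
    gg <- gg[!duplicated(gmap[gg])] # one representative gene per genome
    seqs <- setNames(smap[gg], gmap[gg])[genome_ids]
    center_star_msa(seqs, scheme)
  })
  names(out) <- family_ids
  out
}
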