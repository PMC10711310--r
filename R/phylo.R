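#' Concatenate per-family core alignments into one core-genome alignment
#'
#' Families are concatenated in sorted family-id order; every family
#' alignment must cover every requested genome (strict core only). The
#' result carries a provenance map from global columns back to
#' (family, local column).
#'
#' @param msas named list: family id -> `msa` with genome-id row names.
#' @param genome_ids genomes to include (row order of the result).
#' @return An `msa` with attribute `provenance`
#'   (data.frame `family_id`, `start`, `end` in global columns).
#' @export
concatenate_core_alignment <- function(msas, genome_ids) {
  stopifnot(length(msas) >= 1, !is.null(names(msas)))
  fam_order <- sort(names(msas))
  for (f in fam_order) {
    miss <- setdiff(genome_ids, names(msas[[f]]))
    if (length(miss))
      stop("family ", f, " does not cover genome(s): ",
           paste(miss, collapse = ", "))
  }
  lens <- vapply(fam_order, function(f) nchar(msas[[f]][[1]]), numeric(1))
  pieces <- lapply(fam_order, function(f) unclass(msas[[f]])[genome_ids])
  rows <- do.call(mapply, c(list(FUN = paste0), pieces))
  out <- setNames(as.character(rows), genome_ids)
  ends <- cumsum(lens)
  attr(out, "provenance") <- data.frame(
    family_id = fam_order,
    start = as.integer(ends - lens + 1),
    end = as.integer(ends), stringsAsFactors = FALSE)
  class(out) <- "msa"
  out
}

#' Map a global core-alignment column back to its family
#'
#' @param concat result of [concatenate_core_alignment()].
#' @param column global 1-based column index(es).
#' @return data.frame `column`, `family_id`, `local_column`.
#' @export
column_provenance <- function(concat, column) {
  prov <- attr(concat, "provenance")
  stopifnot(!is.null(prov), all(column >= 1), all(column <= max(prov$end)))
  idx <- findInterval(column, prov$start)
  data.frame(column = column, family_id = prov$family_id[idx],
             local_column = as.integer(column - prov$start[idx] + 1),
             stringsAsFactors = FALSE)
}

#' Reduce an alignment to its variant columns
#'
#' Keeps columns with at least two distinct non-gap residues (SNP-sites-style
#' reduction); original column indices are recorded.
#'
#' @param msa an `msa` with >= 2 rows.
#' @return An `msa` of the retained columns with attribute `columns`
#'   (original indices); zero retained columns yield empty rows.
#' @export
variant_columns <- function(msa) {
  stopifnot(length(msa) >= 2)
  mm <- msa_matrix(msa)
  keep <- which(apply(mm, 2, function(cc) {
    r <- unique(cc[cc != "-"])
    length(r) >= 2
  }))
  out <- setNames(apply(mm[, keep, drop = FALSE], 1, paste, collapse = ""),
                  names(msa))
  attr(out, "columns") <- keep
  class(out) <- "msa"
  out
}

#' Pairwise distances from a multiple alignment
#'
#' p-distance is the mismatch fraction over columns where both rows are
#' non-gap. `model = "jc"` applies the Jukes-Cantor correction
#' `-(3/4) log(1 - 4p/3)` on nucleotide alignments and the Poisson
#' correction `-log(1 - p)` on protein alignments (alphabet auto-detected).
#' Nucleotide p >= 0.75 is saturated and raises an error.
#'
#' @param msa an `msa` with >= 2 rows.
#' @param model `"p"` or `"jc"`.
#' @return Symmetric numeric matrix with genome-id dimnames.
#' @export
distance_matrix <- function(msa, model = c("p", "jc")) {
  model <- match.arg(model)
  stopifnot(length(msa) >= 2)
  mm <- msa_matrix(msa)
  n <- nrow(mm)
  is_nt <- all(mm %in% c("A", "C", "G", "T", "N", "-"))
  d <- matrix(0, n, n, dimnames = list(rownames(mm), rownames(mm)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- mm[i, ] != "-" & mm[j, ] != "-"
      if (!any(ok)) stop("no shared non-gap columns between ",
                         rownames(mm)[i], " and ", rownames(mm)[j])
      p <- sum(mm[i, ok] != mm[j, ok]) / sum(ok)
      if (model == "jc") {
        if (is_nt) {
          if (p >= 0.75)
            stop("saturated pair under nucleotide JC (p >= 0.75): ",
                 rownames(mm)[i], " vs ", rownames(mm)[j])
          p <- -0.75 * log(1 - 4 * p / 3)
        } else {
          if (p >= 1) stop("saturated pair under Poisson correction (p >= 1)")
          p <- -log(1 - p)
        }
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the Studier-Keppler Q-criterion.
#' Deterministic: among tied minimal Q entries the smallest (i, j) index pair
#' is joined. Additive distance matrices are recovered exactly (topology and
#' branch lengths). Negative branch-length estimates are clamped to zero with
#' the deficit shifted to the sibling edge, so output lengths are
#' non-negative. The result is unrooted (trifurcating root).
#'
#' @param d symmetric distance matrix with >= 3 taxa and id dimnames.
#' @return An `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  if (max(abs(d - t(d))) > 1e-12 || any(diag(d) != 0))
    stop("distance matrix must be symmetric with zero diagonal")
  frag <- ids # newick fragment per active node
  act <- d
  while (nrow(act) > 3) {
    r <- nrow(act)
    rs <- rowSums(act)
    q <- (r - 2) * act - outer(rs, rs, `+`)
    diag(q) <- Inf
    # smallest (i, j), i < j, among minimal Q
    best <- which(q == min(q[upper.tri(q)]), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- act[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- act[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- sprintf("(%s:%.15g,%s:%.15g)", frag[i], li, frag[j], lj)
    du <- (act[i, ] + act[j, ] - act[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    act <- rbind(cbind(act[keep, keep, drop = FALSE], du[keep]),
                 c(du[keep], 0))
    frag <- c(frag[keep], newfrag)
  }
  # final trifurcation via three-point formulas
  la <- (act[1, 2] + act[1, 3] - act[2, 3]) / 2
  lb <- (act[1, 2] + act[2, 3] - act[1, 3]) / 2
  lc <- (act[1, 3] + act[2, 3] - act[1, 2]) / 2
  l <- pmax(c(la, lb, lc), 0)
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 frag[1], l[1], frag[2], l[2], frag[3], l[3])
  ape::read.tree(text = nwk)
}

#' Neighbor-joining tree with column-bootstrap supports
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_replicates` times, rebuilds an NJ tree per replicate, and
#' annotates each internal edge of the full tree with the percentage of
#' replicates containing the same bipartition. Seeded and reproducible;
#' supports are invariant to leaf input order.
#'
#' @param msa an `msa` with >= 3 rows.
#' @param n_replicates bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @param model distance model, see [distance_matrix()].
#' @return An `ape::phylo` with `node.label` holding supports in \[0, 100\]
#'   (root label empty).
#' @export
bootstrap_supports <- function(msa, n_replicates = 100, seed = 1,
                               model = c("p", "jc")) {
  model <- match.arg(model)
  stopifnot(n_replicates >= 1, length(msa) >= 3)
  mm <- msa_matrix(msa)
  n <- nrow(mm); L <- ncol(mm)
  full <- neighbor_joining(distance_matrix(msa, model))
  is_nt <- all(mm %in% c("A", "C", "G", "T", "N", "-"))

  # per-pair column incidences, factored so replicates are matrix products:
  # mismatches live only in columns with >= 2 distinct non-gap residues,
  # invalid (gap) comparisons only in columns containing a gap.
  vc <- which(apply(mm, 2, function(cc) length(unique(cc[cc != "-"])) >= 2 ||
                      any(cc == "-")))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  np <- nrow(pairs)
  mism <- matrix(0, np, length(vc))
  inval <- matrix(0, np, length(vc))
  if (length(vc)) {
    sub <- mm[, vc, drop = FALSE]
    for (k in seq_len(np)) {
      ri <- sub[pairs[k, 1], ]; rj <- sub[pairs[k, 2], ]
      bad <- ri == "-" | rj == "-"
      inval[k, ] <- as.numeric(bad)
      mism[k, ] <- as.numeric(!bad & ri != rj)
    }
  }
  jc_fix <- function(p) {
    if (model == "p") return(p)
    if (is_nt) {
      # saturated replicate pairs are clamped just under the JC pole
      -0.75 * log(1 - 4 * pmin(p, 0.7499999) / 3)
    } else -log(1 - pmin(p, 1 - 1e-12))
  }
  bs <- withr_seed(seed, {
    lapply(seq_len(n_replicates), function(rep) {
      w <- tabulate(sample.int(L, L, replace = TRUE), L)
      wv <- w[vc]
      valid <- sum(w) - as.vector(inval %*% wv)
      p <- as.vector(mism %*% wv) / pmax(valid, 1)
      p <- jc_fix(p)
      dm <- matrix(0, n, n, dimnames = list(rownames(mm), rownames(mm)))
      dm[cbind(pairs[, 1], pairs[, 2])] <- p
      dm[cbind(pairs[, 2], pairs[, 1])] <- p
      neighbor_joining(dm)
    })
  })
  counts <- ape::prop.clades(full, bs, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / n_replicates
  lab <- as.character(round(support, 1))
  lab[1] <- "" # root of the unrooted representation carries no bipartition
  full$node.label <- lab
  attr(full, "support") <- support
  full
}

#' Test whether a tree contains a given leaf bipartition
#'
#' @param tree `ape::phylo`.
#' @param ids leaf labels on one side of the candidate split.
#' @return `TRUE` iff some internal edge splits the leaves into
#'   `ids` vs the rest.
#' @export
has_bipartition <- function(tree, ids) {
  !is.na(match_bipartition(tree, ids))
}

#' @rdname has_bipartition
#' @return `bipartition_support()`: the bootstrap support (from
#'   `node.label`) of the internal edge realizing the split, or `NA` if the
#'   split is absent or unlabelled.
#' @export
bipartition_support <- function(tree, ids) {
  idx <- match_bipartition(tree, ids)
  if (is.na(idx) || is.null(tree$node.label)) return(NA_real_)
  suppressWarnings(as.numeric(tree$node.label[idx]))
}

# index (within internal nodes) of the clade realizing the split, else NA
match_bipartition <- function(tree, ids) {
  tips <- tree$tip.label
  stopifnot(all(ids %in% tips))
  target <- sort(match(ids, tips))
  parts <- ape::prop.part(tree)
  for (k in seq_along(parts)) {
    s <- sort(parts[[k]])
    comp <- sort(setdiff(seq_along(tips), s))
    if (identical(s, target) || identical(comp, target)) return(k)
  }
  NA_integer_
}
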