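#' Pairwise sequence alignment with affine gaps
#'
#' `align_global()` computes the optimal Needleman-Wunsch alignment under
#' affine gap penalties (Gotoh); `align_local()` the optimal Smith-Waterman
#' local alignment (an empty alignment with score 0 is allowed). Traceback is
#' deterministic: ties prefer diagonal over up (gap in `b`) over left.
#'
#' Percent identity is defined project-wide as matches divided by alignment
#' columns excluding dual-gap columns, so gap columns count against identity.
#' This pins down the meaning of the 95% gene-family clustering threshold.
#'
#' @param a,b character scalars (sequences over the scheme's alphabet).
#' @param scheme a [scoring_scheme()].
#' @param score_only if `TRUE`, skip traceback and return only the score.
#' @return A `pairwise_alignment`: list with `aligned_a`, `aligned_b`, `score`,
#'   `identity`, `coverage_a`, `coverage_b` (fractions of each input consumed
#'   by the aligned region).
#' @export
align_global <- function(a, b, scheme = scoring_scheme_protein(),
                         score_only = FALSE) {
  align_pair(a, b, scheme, local = FALSE, score_only = score_only)
}

#' @rdname align_global
#' @export
align_local <- function(a, b, scheme = scoring_scheme_protein(),
                        score_only = FALSE) {
  align_pair(a, b, scheme, local = TRUE, score_only = score_only)
}

align_pair <- function(a, b, scheme, local, score_only = FALSE) {
  stopifnot(is.character(a), is.character(b), nzchar(a), nzchar(b))
  ea <- encode_seq(a, scheme)
  eb <- encode_seq(b, scheme)
  res <- .gotoh_align(ea, eb, scheme$substitution,
                      scheme$gap_open, scheme$gap_extend, local, score_only)
  if (score_only) return(res$score)
  ops <- res$ops
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  ia <- res$a_start
  ib <- res$b_start
  aa <- character(length(ops))
  ab <- character(length(ops))
  pa <- ia
  pb <- ib
  for (i in seq_along(ops)) {
    o <- ops[i]
    if (o == 1L) {
      aa[i] <- ca[pa]; ab[i] <- cb[pb]; pa <- pa + 1; pb <- pb + 1
    } else if (o == 2L) {
      aa[i] <- ca[pa]; ab[i] <- "-"; pa <- pa + 1
    } else {
      aa[i] <- "-"; ab[i] <- cb[pb]; pb <- pb + 1
    }
  }
  ncol_eff <- length(ops) # pairwise traceback never emits dual-gap columns
  matches <- sum(aa == ab & aa != "-")
  structure(list(
    aligned_a = paste(aa, collapse = ""),
    aligned_b = paste(ab, collapse = ""),
    score = res$score,
    identity = if (ncol_eff > 0) matches / ncol_eff else 0,
    coverage_a = res$a_len / length(ca),
    coverage_b = res$b_len / length(cb),
    a_start = if (length(ops)) ia else 0L,
    b_start = if (length(ops)) ib else 0L
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise alignment: score %.6g, identity %.4f, coverage %.3f/%.3f\n",
              x$score, x$identity, x$coverage_a, x$coverage_b))
  cat(" a: ", x$aligned_a, "\n b: ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Percent identity between two aligned rows
#'
#' Matches over columns where not both rows are gaps (dual-gap columns are
#' skipped; columns with a single gap count against identity).
#'
#' @param x,y equal-length aligned strings over residues and `-`.
#' @return Fraction in \[0, 1\].
#' @export
aligned_identity <- function(x, y) {
  cx <- strsplit(x, "", fixed = TRUE)[[1]]
  cy <- strsplit(y, "", fixed = TRUE)[[1]]
  stopifnot(length(cx) == length(cy))
  keep <- !(cx == "-" & cy == "-")
  if (!any(keep)) return(0)
  sum(cx[keep] == cy[keep] & cx[keep] != "-") / sum(keep)
}

#' Center-star multiple sequence alignment
#'
#' Aligns a set of protein (or DNA) sequences by the center-star heuristic:
#' the center is the sequence maximizing the summed global pairwise alignment
#' scores to all others (ties broken by lexicographically smallest id); every
#' other sequence is aligned to the center and merged under "once a gap,
#' always a gap". De-gapping any row reproduces its input sequence exactly.
#'
#' @param seqs named character vector of sequences (names are row ids).
#' @param scheme a [scoring_scheme()].
#' @return An `msa`: named character vector of equal-length aligned rows, with
#'   attribute `center` (the center id).
#' @export
center_star_msa <- function(seqs, scheme = scoring_scheme_protein()) {
  if (length(seqs) == 0) stop("center_star_msa() needs at least one sequence")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  ids <- names(seqs)
  if (length(seqs) == 1) {
    out <- seqs
    attr(out, "center") <- ids[1]
    class(out) <- "msa"
    return(out)
  }
  k <- length(seqs)
  # center selection: summed pairwise global scores (score-only DP)
  tot <- numeric(k)
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      s <- align_global(seqs[[i]], seqs[[j]], scheme, score_only = TRUE)
      tot[i] <- tot[i] + s
      tot[j] <- tot[j] + s
    }
  }
  ord <- order(-tot, ids)
  center <- ord[1]

  # master state: center row as vector of chars (with gaps); other rows likewise
  center_chars <- strsplit(seqs[[center]], "", fixed = TRUE)[[1]]
  rows <- list()
  rows[[ids[center]]] <- center_chars
  master <- center_chars # current aligned center row

  for (i in seq_len(k)) {
    if (i == center) next
    al <- align_global(seqs[[center]], seqs[[i]], scheme)
    pc <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]] # center in pairwise
    ps <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
    # merge pairwise columns into master columns ("once a gap, always a gap"):
    # walk both; center-residue columns must pair up; gap-only columns from
    # either side are interleaved, master gaps first.
    mi <- 1; pi <- 1
    nm <- length(master); np <- length(pc)
    src_m <- integer(nm + np) # for each output column, index into master or 0
    src_p <- integer(nm + np) # index into pairwise or 0
    oc <- 0L
    while (mi <= nm || pi <= np) {
      m_gap <- mi <= nm && master[mi] == "-"
      p_gap <- pi <= np && pc[pi] == "-"
      oc <- oc + 1L
      if (m_gap) {
        src_m[oc] <- mi; mi <- mi + 1
      } else if (p_gap) {
        src_p[oc] <- pi; pi <- pi + 1
      } else {
        src_m[oc] <- mi; src_p[oc] <- pi; mi <- mi + 1; pi <- pi + 1
      }
    }
    src_m <- src_m[seq_len(oc)]
    src_p <- src_p[seq_len(oc)]
    master <- ifelse(src_m > 0, master[pmax(src_m, 1L)], "-")
    for (id in names(rows)) {
      r <- rows[[id]]
      rows[[id]] <- ifelse(src_m > 0, r[pmax(src_m, 1L)], "-")
    }
    rows[[ids[i]]] <- ifelse(src_p > 0, ps[pmax(src_p, 1L)], "-")
  }

  out <- vapply(rows[ids], paste, character(1), collapse = "")
  attr(out, "center") <- ids[center]
  class(out) <- "msa"
  out
}

#' Write a multiple alignment as aligned FASTA
#'
#' @param msa named character vector of equal-length aligned rows.
#' @param path output file.
#' @export
write_aligned_fasta <- function(msa, path) {
  writeLines(as.vector(rbind(paste0(">", names(msa)), unclass(msa))), path)
  invisible(path)
}

msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(unclass(msa), "", fixed = TRUE))
  rownames(m) <- names(msa)
  m
}
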