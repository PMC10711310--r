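#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed that of
#' the observed table (ties compared within relative tolerance 1e-7, the
#' usual convention). A table with any zero margin carries no signal and
#' returns p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts
#'   (rows = groups, columns = present/absent).
#' @return p-value in \[0, 1\].
#' @export
fisher_exact_two_sided <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2), all(tab >= 0),
            all(tab == round(tab)))
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1.0)
  k <- max(0, c1 - r2):min(c1, r1) # feasible top-left cells
  probs <- dhyper(k, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Gene-family association with the phenotype group
#'
#' Pan-GWAS-style screen: for every gene family that is neither universally
#' present nor universally absent among the labelled genomes, tests the 2x2
#' presence-by-group table with [fisher_exact_two_sided()], then applies
#' Bonferroni and Benjamini-Hochberg corrections over the tested families.
#' UNKNOWN-group genomes are excluded. Phylogenetic awareness (Scoary's
#' pairwise comparisons) is deliberately out of scope.
#'
#' @param m presence/absence matrix (families x genomes).
#' @param metadata metadata table with `genome_id` and `group`.
#' @param groups length-2 character: group 1 and group 2 labels
#'   (default PTB vs FTB).
#' @return data.frame sorted by ascending p: `family_id`, `g1_present`,
#'   `g1_absent`, `g2_present`, `g2_absent`, `p_value`, `odds_ratio`,
#'   `p_bonferroni`, `q_bh`, `direction` (GROUP1_ENRICHED / GROUP2_ENRICHED /
#'   NONE).
#' @export
associate_families <- function(m, metadata, groups = c("PTB", "FTB")) {
  validate_metadata(metadata)
  stopifnot(length(groups) == 2)
  md <- metadata[metadata$group %in% groups, , drop = FALSE]
  missing <- setdiff(md$genome_id, colnames(m))
  if (length(missing))
    stop("labelled genome(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  g1 <- md$genome_id[md$group == groups[1]]
  g2 <- md$genome_id[md$group == groups[2]]
  if (length(g1) == 0 || length(g2) == 0)
    stop("both groups need at least one genome")
  p1 <- rowSums(m[, g1, drop = FALSE] > 0)
  p2 <- rowSums(m[, g2, drop = FALSE] > 0)
  tot <- p1 + p2
  testable <- tot > 0 & tot < length(g1) + length(g2)
  fams <- rownames(m)[testable]
  if (!length(fams))
    return(data.frame(family_id = character(0), g1_present = integer(0),
                      g1_absent = integer(0), g2_present = integer(0),
                      g2_absent = integer(0), p_value = numeric(0),
                      odds_ratio = numeric(0), p_bonferroni = numeric(0),
                      q_bh = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  a <- p1[testable]; b <- length(g1) - a
  c_ <- p2[testable]; d <- length(g2) - c_
  p <- vapply(seq_along(fams), function(i)
    fisher_exact_two_sided(matrix(c(a[i], c_[i], b[i], d[i]), 2)), numeric(1))
  or <- (a * d) / (b * c_) # sample odds ratio; 0/0 -> NaN reported as NA
  or[is.nan(or)] <- NA_real_
  f1 <- a / length(g1); f2 <- c_ / length(g2)
  direction <- ifelse(f1 > f2, "GROUP1_ENRICHED",
                      ifelse(f2 > f1, "GROUP2_ENRICHED", "NONE"))
  out <- data.frame(family_id = fams, g1_present = as.integer(a),
                    g1_absent = as.integer(b), g2_present = as.integer(c_),
                    g2_absent = as.integer(d), p_value = p,
                    odds_ratio = unname(or),
                    p_bonferroni = p.adjust(p, "bonferroni"),
                    q_bh = p.adjust(p, "BH"), direction = direction,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the association report
#' @param assoc result of [associate_families()].
#' @param path TSV file.
#' @export
write_association <- function(assoc, path) {
  write.table(assoc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
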