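#' Scoring schemes for pairwise alignment
#'
#' A scoring scheme bundles a symmetric substitution matrix with affine gap
#' penalties. A gap of length L costs `gap_open + (L - 1) * gap_extend`,
#' and `gap_open <= gap_extend < 0`. The protein default mirrors BLASTp
#' (BLOSUM62, -11/-1); the DNA default is +1/-1 match/mismatch with -5/-2
#' gaps, with `N` scoring 0 against everything (ambiguity is neutral).
#'
#' @param substitution square numeric matrix with identical row/col names
#'   (the alphabet).
#' @param gap_open,gap_extend negative gap penalties.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(substitution, gap_open, gap_extend) {
  stopifnot(is.matrix(substitution),
            nrow(substitution) == ncol(substitution),
            identical(rownames(substitution), colnames(substitution)),
            gap_open <= gap_extend, gap_extend < 0)
  if (max(abs(substitution - t(substitution))) > 1e-9)
    stop("substitution matrix must be symmetric")
  structure(list(substitution = substitution,
                 alphabet = rownames(substitution),
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' @rdname scoring_scheme
#' @export
scoring_scheme_protein <- function(gap_open = -11, gap_extend = -1) {
  scoring_scheme(blosum62_matrix(), gap_open, gap_extend)
}

#' @rdname scoring_scheme
#' @param match,mismatch DNA match/mismatch scores.
#' @export
scoring_scheme_dna <- function(match = 1, mismatch = -1,
                               gap_open = -5, gap_extend = -2) {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(ab, ab))
  diag(m) <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  scoring_scheme(m, gap_open, gap_extend)
}

# BLOSUM62 from Biostrings, loaded once per session
blosum62_env <- new.env(parent = emptyenv())
blosum62_matrix <- function() {
  if (is.null(blosum62_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_env$m <- e$BLOSUM62
  }
  blosum62_env$m
}

encode_seq <- function(x, scheme) {
  codes <- match(strsplit(x, "", fixed = TRUE)[[1]], scheme$alphabet)
  if (anyNA(codes))
    stop("sequence contains residues absent from the substitution matrix: ",
         paste(unique(strsplit(x, "")[[1]][is.na(codes)]), collapse = ","))
  codes
}
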