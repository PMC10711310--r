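# Independent oracles: brute-force enumerations and naive re-implementations
# used only to check package results, never sharing code with them.

# exhaustive affine-gap global alignment score: enumerate every op sequence
oracle_global_score <- function(a, b, scheme) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, last, sc) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1, j + 1, "M", sc + scheme$substitution[ca[i], cb[j]])
    if (i <= length(ca))
      rec(i + 1, j, "X",
          sc + if (last == "X") scheme$gap_extend else scheme$gap_open)
    if (j <= length(cb))
      rec(i, j + 1, "Y",
          sc + if (last == "Y") scheme$gap_extend else scheme$gap_open)
  }
  rec(1, 1, "none", 0)
  best
}

# exhaustive local score: best global score over all substring pairs, floor 0
oracle_local_score <- function(a, b, scheme) {
  best <- 0
  for (i1 in seq_len(nchar(a))) for (i2 in i1:nchar(a))
    for (j1 in seq_len(nchar(b))) for (j2 in j1:nchar(b)) {
      s <- oracle_global_score(substr(a, i1, i2), substr(b, j1, j2), scheme)
      best <- max(best, s)
    }
  best
}

# two-sided Fisher p by explicit enumeration of all tables with fixed margins,
# probabilities from binomial coefficients (no dhyper)
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  ks <- max(0, c1 - r2):min(c1, r1)
  prob <- function(k) choose(r1, k) * choose(r2, c1 - k) / choose(r1 + r2, c1)
  ps <- vapply(ks, prob, numeric(1))
  pobs <- prob(tab[1, 1])
  min(1, sum(ps[ps <= pobs * (1 + 1e-7)]))
}

# naive per-codon translation, bacterial code (table 11), N-containing -> X
ORACLE_CODONS <- local({
  b <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", # TTT..TGG
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  cods <- unlist(lapply(b, function(f)
    unlist(lapply(b, function(s) paste0(f, s, b)))))
  setNames(aas, cods)
})

oracle_translate <- function(nt) {
  n <- nchar(nt) / 3
  cods <- substring(nt, 3 * (1:n) - 2, 3 * (1:n))
  aa <- ifelse(grepl("N", cods), "X", ORACLE_CODONS[cods])
  paste(aa, collapse = "")
}

# random additive tree: random topology, strictly positive branch lengths
random_additive_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) runif(k, 0.1, 2))
  tr$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  tr
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

mutate_dna <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  i <- which(runif(length(v)) < rate)
  if (length(i)) {
    b <- c("A", "C", "G", "T")
    v[i] <- b[(match(v[i], b) + sample(3, length(i), replace = TRUE) - 1) %% 4 + 1]
  }
  paste(v, collapse = "")
}

single_contig_genome <- function(id, seq, ...) {
  genome_record(id, setNames(seq, paste0(id, "_c1")), ...)
}
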