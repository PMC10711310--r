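test_that("global alignment handles identity, forced gaps and bad residues", {
  al <- align_global("MKV", "MKV")
  expect_equal(al$identity, 1)
  expect_equal(al$aligned_a, "MKV")
  expect_equal(al$score, 14) # BLOSUM62: M5 + K5 + V4

  dna <- scoring_scheme_dna()
  al2 <- align_global("AC", "A", dna)
  expect_equal(al2$aligned_b, "A-")
  expect_equal(al2$identity, 0.5) # gap column counts against identity

  expect_error(align_global("MKB1", "MK"), "absent from the substitution")
})

test_that("global score equals exhaustive enumeration on all short DNA pairs", {
  dna <- scoring_scheme_dna()
  pool <- unlist(lapply(1:4, function(L)
    apply(expand.grid(rep(list(c("A", "C")), L)), 1, paste, collapse = "")))
  for (a in pool) for (b in pool) {
    expect_equal(align_global(a, b, dna, score_only = TRUE),
                 oracle_global_score(a, b, dna),
                 info = paste(a, b))
  }
})

test_that("local alignment finds substrings and allows empty alignments", {
  al <- align_local("XXXMKVXXX", "MKV")
  expect_equal(al$aligned_a, "MKV")
  expect_equal(al$coverage_b, 1.0)
  expect_equal(al$coverage_a, 3 / 9)
  expect_equal(al$b_start, 1L)

  dna <- scoring_scheme_dna()
  al2 <- align_local("AAAA", "CCCC", dna)
  expect_equal(al2$score, 0)
  expect_equal(al2$aligned_a, "")
  expect_equal(al2$coverage_a, 0)
})

test_that("local score equals brute force over substring pairs (short DNA)", {
  dna <- scoring_scheme_dna()
  set.seed(5)
  for (rep in 1:40) {
    a <- paste(sample(c("A", "C", "G"), sample(2:4, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G"), sample(2:4, 1), replace = TRUE),
               collapse = "")
    expect_equal(align_local(a, b, dna, score_only = TRUE),
                 oracle_local_score(a, b, dna), info = paste(a, b))
  }
})

test_that("global score is symmetric under a symmetric scheme", {
  set.seed(11)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:25) {
    a <- paste(sample(aas, sample(3:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(3:12, 1), replace = TRUE), collapse = "")
    expect_equal(align_global(a, b, score_only = TRUE),
                 align_global(b, a, score_only = TRUE))
  }
})

test_that("alignment agrees with Biostrings pairwiseAlignment scores", {
  set.seed(13)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:15) {
    a <- paste(sample(aas, sample(5:30, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(5:30, 1), replace = TRUE), collapse = "")
    ours <- align_global(a, b, score_only = TRUE)
    # Biostrings penalties: gap of length L costs opening + L*extension,
    # so opening = |gap_open| - |gap_extend| maps our convention onto theirs
    ref <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(ours, ref, info = paste(a, b))
  }
})

test_that("center-star MSA merges gaps correctly and de-gaps to inputs", {
  m1 <- center_star_msa(c(s = "MKV"))
  expect_equal(unclass(m1), c(s = "MKV"), ignore_attr = TRUE)

  m2 <- center_star_msa(c(a = "MKV", b = "MKV", c = "MKV"))
  expect_equal(nchar(m2[["a"]]), 3)
  expect_true(all(!grepl("-", unclass(m2), fixed = TRUE)))

  m3 <- center_star_msa(c(s1 = "MKV", s2 = "MRV", s3 = "MV"))
  mm <- do.call(rbind, strsplit(unclass(m3), ""))
  expect_equal(unname(mm[, 1]), c("M", "M", "M"))
  expect_equal(unname(mm[, 3]), c("V", "V", "V"))
  expect_equal(m3[["s3"]], "M-V")

  set.seed(17)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:10) {
    seqs <- setNames(vapply(1:5, function(i)
      paste(sample(aas, sample(4:20, 1), replace = TRUE), collapse = ""),
      ""), paste0("q", 1:5))
    msa <- center_star_msa(seqs)
    expect_equal(length(unique(nchar(unclass(msa)))), 1)
    expect_gte(nchar(msa[[1]]), max(nchar(seqs)))
    degap <- gsub("-", "", unclass(msa), fixed = TRUE)
    expect_equal(degap, seqs, ignore_attr = TRUE)
  }

  expect_error(center_star_msa(character(0)), "at least one")
})
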