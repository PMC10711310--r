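mk_msa <- function(...) {
  x <- c(...)
  class(x) <- "msa"
  x
}

test_that("core alignment concatenation preserves lengths and provenance", {
  m1 <- mk_msa(a = "MKVWMKVWMK", b = "MKVWMKVWMK", c = "MKVWMRVWMK")
  m2 <- mk_msa(a = paste(rep("AC", 10), collapse = ""),
               b = paste(rep("AC", 10), collapse = ""),
               c = paste(rep("AC", 10), collapse = ""))
  cc <- concatenate_core_alignment(list(f2 = m2, f1 = m1), c("a", "b", "c"))
  expect_equal(unique(nchar(unclass(cc))), 30)
  expect_equal(substr(cc[["a"]], 1, 10), "MKVWMKVWMK") # sorted family order
  pv <- column_provenance(cc, c(1, 10, 11, 30))
  expect_equal(pv$family_id, c("f1", "f1", "f2", "f2"))
  expect_equal(pv$local_column, c(1L, 10L, 1L, 20L))

  expect_error(concatenate_core_alignment(list(f1 = m1), c("a", "d")),
               "does not cover")
})

test_that("variant-column reduction matches a naive recount", {
  m <- mk_msa(a = "MKVAW", b = "MKVAW", c = "MKVAW")
  r <- variant_columns(m)
  expect_length(attr(r, "columns"), 0)

  m2 <- mk_msa(a = "MKV", b = "MRV")
  r2 <- variant_columns(m2)
  expect_equal(attr(r2, "columns"), 2L)
  expect_equal(r2[["a"]], "K")

  set.seed(59)
  aas <- c("A", "C", "D", "-", "E")
  rows <- replicate(4, paste(sample(aas, 40, replace = TRUE), collapse = ""))
  m3 <- mk_msa(setNames(rows, paste0("g", 1:4)))
  r3 <- variant_columns(m3)
  chars <- do.call(rbind, strsplit(rows, ""))
  naive <- which(apply(chars, 2, function(cc)
    length(unique(cc[cc != "-"])) >= 2))
  expect_equal(attr(r3, "columns"), naive)
})

test_that("p-distance and corrections match closed forms", {
  m <- mk_msa(a = "ACGT", b = "ACGA")
  expect_equal(distance_matrix(m)["a", "b"], 0.25)
  expect_equal(distance_matrix(m, "jc")["a", "b"], -0.75 * log(1 - 1 / 3))
  expect_equal(distance_matrix(mk_msa(a = "ACGT", b = "ACGT"))["a", "b"], 0)

  # gap columns are excluded pairwise
  m2 <- mk_msa(a = "AC-T", b = "ACG-")
  expect_equal(distance_matrix(m2)["a", "b"], 0)

  # protein rows under model "jc" use the Poisson correction
  mp <- mk_msa(a = "MKVW", b = "MRVW")
  expect_equal(distance_matrix(mp, "jc")["a", "b"], -log(1 - 0.25))

  # nucleotide saturation is an error, not a number
  sat <- mk_msa(a = "ACGTACGTACGT", b = "CATCCATCCATC")
  expect_error(distance_matrix(sat, "jc"), "saturated")
})

test_that("neighbor joining solves the 3-taxon case exactly", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_equal(ape::write.tree(tr), "(a:0.5,b:1.5,c:2.5);")
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining recovers additive trees exactly", {
  tr4 <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):0);")
  d4 <- ape::cophenetic.phylo(tr4)
  nj4 <- neighbor_joining(d4)
  expect_equal(ape::dist.topo(ape::unroot(tr4), nj4), 0, ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(nj4)[rownames(d4), colnames(d4)], d4,
               tolerance = 1e-12)

  set.seed(61)
  for (rep in 1:10) {
    tr <- random_additive_tree(sample(5:10, 1))
    d <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), nj), 0, ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
    # independent implementation agrees on the induced metric
    ref <- ape::nj(d)
    expect_equal(ape::cophenetic.phylo(ref)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
  }
})

test_that("degenerate all-zero distances give a deterministic zero tree", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length == 0))
})

test_that("bootstrap supports behave at the edges and are reproducible", {
  # two perfectly separated clades: the separating edge gets 100
  blockA <- paste(rep("A", 50), collapse = "")
  blockC <- paste(rep("C", 50), collapse = "")
  pad <- function(...) paste0(...)
  msa <- mk_msa(x1 = pad(blockA, blockA), x2 = pad(blockA, blockA),
                y1 = pad(blockC, blockA), y2 = pad(blockC, blockC),
                y3 = pad(blockC, blockC))
  tr <- bootstrap_supports(msa, n_replicates = 20, seed = 3)
  expect_true(has_bipartition(tr, c("x1", "x2")))
  sup <- attr(tr, "support")
  expect_true(any(sup[-1] == 100))

  tr_b <- bootstrap_supports(msa, n_replicates = 20, seed = 3)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr_b))

  # a single replicate can only give 0 or 100
  tr1 <- bootstrap_supports(msa, n_replicates = 1, seed = 5)
  expect_true(all(attr(tr1, "support")[-1] %in% c(0, 100)))

  # supports invariant to leaf input order
  perm <- c("y2", "x1", "y3", "x2", "y1")
  tr_p <- bootstrap_supports(mk_msa(setNames(unclass(msa)[perm], perm)),
                             n_replicates = 20, seed = 3)
  expect_true(has_bipartition(tr_p, c("x1", "x2")))
})
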