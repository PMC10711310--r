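test_that("Fisher two-sided p matches hand-derived exact values", {
  expect_equal(fisher_exact_two_sided(matrix(c(1, 1, 1, 1), 2)), 1.0)
  expect_equal(fisher_exact_two_sided(matrix(c(6, 0, 0, 9), 2)), 1 / 5005)
  expect_equal(fisher_exact_two_sided(matrix(c(3, 1, 1, 3), 2)), 34 / 70)
  # degenerate margins carry no signal
  expect_equal(fisher_exact_two_sided(matrix(c(0, 0, 3, 4), 2)), 1.0)
  expect_equal(fisher_exact_two_sided(matrix(c(2, 0, 3, 0), 2)), 1.0)
})

test_that("Fisher p agrees with enumeration and stats::fisher.test", {
  set.seed(53)
  for (rep in 1:60) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    ours <- fisher_exact_two_sided(tab)
    expect_equal(ours, oracle_fisher(tab), tolerance = 1e-12,
                 info = paste(tab, collapse = ","))
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      expect_equal(ours, stats::fisher.test(tab)$p.value, tolerance = 1e-9,
                   info = paste(tab, collapse = ","))
  }
})

make_matrix <- function(rows) {
  m <- do.call(rbind, rows)
  storage.mode(m) <- "integer"
  m
}

test_that("family association screens, corrects and orients correctly", {
  gids <- c(paste0("P", 1:6), paste0("F", 1:9))
  md <- data.frame(genome_id = gids,
                   group = rep(c("PTB", "FTB"), c(6, 9)),
                   stringsAsFactors = FALSE)
  m <- make_matrix(list(
    everywhere = rep(1, 15),          # invariant -> excluded
    nowhere = rep(0, 15),             # invariant -> excluded
    ptb_only = rep(c(1, 0), c(6, 9)), # perfect separation
    ftb_only = rep(c(0, 1), c(6, 9)),
    noise = c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1)))
  colnames(m) <- gids
  res <- associate_families(m, md)
  expect_equal(nrow(res), 3) # invariant families never tested
  expect_equal(res$family_id[1:2], c("ftb_only", "ptb_only"))
  ptb <- res[res$family_id == "ptb_only", ]
  expect_equal(ptb$p_value, 1 / 5005)
  expect_equal(ptb$direction, "GROUP1_ENRICHED")
  expect_equal(ptb$p_bonferroni, 3 / 5005)
  ftb <- res[res$family_id == "ftb_only", ]
  expect_equal(ftb$direction, "GROUP2_ENRICHED")
  expect_true(all(res$p_bonferroni >= res$p_value))

  # swapping group labels flips direction, keeps p
  swapped <- associate_families(m, md, groups = c("FTB", "PTB"))
  sw <- swapped[swapped$family_id == "ptb_only", ]
  expect_equal(sw$p_value, ptb$p_value)
  expect_equal(sw$direction, "GROUP2_ENRICHED")

  # UNKNOWN genomes are excluded from the table margins
  md2 <- rbind(md, data.frame(genome_id = "U1", group = "UNKNOWN"))
  m2 <- cbind(m, U1 = c(1L, 0L, 1L, 1L, 1L))
  res2 <- associate_families(m2, md2)
  expect_equal(res2[res2$family_id == "ptb_only", "p_value"], 1 / 5005)

  expect_error(associate_families(m, md[md$group == "PTB", ]), "both groups")
})

test_that("tied p-values adjust per textbook Bonferroni and BH", {
  gids <- paste0("g", 1:10)
  md <- data.frame(genome_id = gids, group = rep(c("PTB", "FTB"), each = 5))
  # one family pattern repeated 10 times -> identical p for all
  row <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 1)
  m <- make_matrix(rep(list(row), 10))
  rownames(m) <- paste0("f", 1:10)
  colnames(m) <- gids
  res <- associate_families(m, md)
  p <- unique(res$p_value)
  expect_length(p, 1)
  expect_equal(res$p_bonferroni, rep(min(1, 10 * p), 10))
  expect_equal(res$q_bh, rep(p, 10)) # m identical tests: q = p
})
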