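#' Partition the pangenome into core, shell and cloud
#'
#' With G genomes and family presence count c: core if `c/G >= core_frac`,
#' shell if `shell_min_frac <= c/G < core_frac`, cloud otherwise. The rule is
#' fraction-based (no integer rounding): at G = 15 and `core_frac = 0.95`,
#' 0.95 x 15 = 14.25, so only families in all 15 genomes are core — the
#' ">= 95% of strains" convention.
#'
#' @param m presence/absence matrix (families x genomes).
#' @param core_frac core threshold (default 0.95).
#' @param shell_min_frac lower shell threshold (default 0.15).
#' @return A `pangenome_partition`: list with `core_ids`, `shell_ids`,
#'   `cloud_ids`, `thresholds`, and a per-family `table`
#'   (`family_id`, `presence_count`, `class`).
#' @export
partition_pangenome <- function(m, core_frac = 0.95, shell_min_frac = 0.15) {
  stopifnot(is.matrix(m), ncol(m) >= 1, shell_min_frac < core_frac)
  g <- ncol(m)
  cnt <- rowSums(m > 0)
  frac <- cnt / g
  cls <- ifelse(frac >= core_frac, "core",
                ifelse(frac >= shell_min_frac, "shell", "cloud"))
  tab <- data.frame(family_id = rownames(m), presence_count = as.integer(cnt),
                    class = cls, stringsAsFactors = FALSE)
  structure(list(core_ids = rownames(m)[cls == "core"],
                 shell_ids = rownames(m)[cls == "shell"],
                 cloud_ids = rownames(m)[cls == "cloud"],
                 thresholds = c(core_frac = core_frac,
                                shell_min_frac = shell_min_frac),
                 table = tab),
            class = "pangenome_partition")
}

#' @export
print.pangenome_partition <- function(x, ...) {
  cat(sprintf("pangenome partition: %d core / %d shell / %d cloud (total %d families)\n",
              length(x$core_ids), length(x$shell_ids), length(x$cloud_ids),
              nrow(x$table)))
  invisible(x)
}

#' Gene-accumulation (rarefaction) curve of the pangenome
#'
#' For each of `n_permutations` random genome orderings, counts cumulative
#' distinct families after adding genomes 1..G, and reports per-N means of
#' the pangenome size and of the number of new families contributed by the
#' N-th genome. Seeded and reproducible. When every ordering can be afforded
#' (G! <= n_permutations) all G! orderings are enumerated instead of
#' sampled, so small collections get exact means.
#'
#' @param m presence/absence matrix (families x genomes, G >= 2).
#' @param n_permutations number of random orderings (>= 1).
#' @param seed RNG seed.
#' @return data.frame `N`, `mean_pangenome_size`, `mean_new_genes`.
#' @export
rarefaction_curve <- function(m, n_permutations = 100, seed = 1) {
  stopifnot(is.matrix(m), n_permutations >= 1)
  g <- ncol(m)
  if (g < 2) stop("rarefaction needs at least 2 genomes")
  pres <- m > 0
  exhaustive <- factorial(g) <= n_permutations
  perms <- if (exhaustive) all_permutations(g) else NULL
  n_used <- if (exhaustive) length(perms) else n_permutations
  withr_seed(seed, {
    acc <- matrix(0, n_used, g)
    for (p in seq_len(n_used)) {
      perm <- if (exhaustive) perms[[p]] else sample.int(g)
      po <- pres[, perm, drop = FALSE] + 0
      first <- max.col(po, ties.method = "first")
      first[rowSums(po) == 0] <- NA
      newg <- tabulate(first, g)
      acc[p, ] <- cumsum(newg)
    }
  })
  data.frame(N = seq_len(g),
             mean_pangenome_size = colMeans(acc),
             mean_new_genes = colMeans(cbind(acc[, 1, drop = FALSE],
                                             t(diff(t(acc))))))
}

all_permutations <- function(g) {
  if (g == 1) return(list(1L))
  out <- list()
  for (i in seq_len(g)) {
    rest <- all_permutations(g - 1)
    for (r in rest) out[[length(out) + 1]] <- c(i, setdiff(seq_len(g), i)[r])
  }
  out
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Fit Heaps' law to a rarefaction curve and classify openness
#'
#' Fits the total-pangenome-size power law P(N) = kappa * N^gamma by least
#' squares on log P vs log N. The pangenome is OPEN if gamma > 0 (new
#' families keep accruing as genomes are added) and CLOSED otherwise;
#' |gamma| <= 1e-6 is treated as 0 (CLOSED).
#'
#' @param curve data.frame from [rarefaction_curve()] (needs columns `N` and
#'   `mean_pangenome_size`; >= 3 points with positive sizes).
#' @return A `heaps_fit`: list with `kappa`, `gamma`, `openness`
#'   ("OPEN"/"CLOSED"), and the input `curve`.
#' @export
fit_heaps <- function(curve) {
  stopifnot(is.data.frame(curve),
            all(c("N", "mean_pangenome_size") %in% names(curve)))
  if (nrow(curve) < 3) stop("fit_heaps() needs at least 3 curve points")
  if (any(curve$mean_pangenome_size <= 0)) stop("curve sizes must be positive")
  fit <- lm(log(mean_pangenome_size) ~ log(N), data = curve)
  kappa <- exp(unname(coef(fit)[1]))
  gamma <- unname(coef(fit)[2])
  structure(list(kappa = kappa, gamma = gamma,
                 openness = if (gamma > 1e-6) "OPEN" else "CLOSED",
                 n_points = nrow(curve), curve = curve),
            class = "heaps_fit")
}

#' @export
print.heaps_fit <- function(x, ...) {
  cat(sprintf("Heaps' law fit: P(N) = %.4g * N^%.4g -> %s pangenome\n",
              x$kappa, x$gamma, x$openness))
  invisible(x)
}
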