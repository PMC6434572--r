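# Jost's D differentiation with locus bootstrap.

# Nei & Chesser style unbiased Hs / Ht for one locus and two (or more)
# populations, from individual counts and frequency matrix (rows = pops).
jost_locus_components <- function(freqs, n_ind) {
  npop <- nrow(freqs)
  n_harm <- npop / sum(1 / n_ind)
  hs_hat <- mean(1 - rowSums(freqs^2))
  hs <- (2 * n_harm / (2 * n_harm - 1)) * hs_hat
  pbar <- colMeans(freqs)
  ht <- 1 - sum(pbar^2) + hs / (2 * n_harm * npop)
  c(hs = hs, ht = ht)
}

# Multi-locus D_est: components averaged across loci before the ratio
# (Ht - Hs two-locus means), times N/(N-1).
jost_d_from_components <- function(comp, npop) {
  num <- mean(comp["ht", ] - comp["hs", ])
  den <- mean(1 - comp["hs", ])
  if (den == 0) return(NA_real_)
  (npop / (npop - 1)) * num / den
}

#' Pairwise Jost's D matrix
#'
#' D_est per population pair with Nei-Chesser sample-size corrected Hs and
#' Ht per locus; the multi-locus value averages the (Ht - Hs) and (1 - Hs)
#' components across loci before taking the ratio. Significance (D > 0)
#' comes from bootstrapping over loci; single-locus datasets return point
#' estimates only. The harmonic-number FDR threshold at `alpha` flags the
#' significant pairs.
#'
#' @param dataset a diploid `genotype_dataset`.
#' @param n_boot bootstrap-over-loci replicates.
#' @param alpha family-wise level for the FDR flags.
#' @param seed RNG seed.
#' @return a `pairwise_matrix` with elements `d`, `p`, `significant` and
#'   `cpv`.
#' @export
jost_d <- function(dataset, n_boot = 1000, alpha = 0.05, seed = NULL) {
  stopifnot(dataset$variant == "diploid")
  pops <- unique(dataset$samples$population)
  if (length(pops) < 2) stop("need >= 2 populations")
  counts <- gd_count_matrices(dataset, weighted = FALSE)
  d <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  p <- matrix(NA_real_, length(pops), length(pops),
              dimnames = list(pops, pops))
  with_seed(seed, {
    for (i in seq_len(length(pops) - 1)) for (j in (i + 1):length(pops)) {
      comp <- vapply(counts, function(m) {
        sub <- m[pops[c(i, j)], , drop = FALSE]
        tot <- rowSums(sub)
        if (any(tot < 2)) return(c(hs = NA_real_, ht = NA_real_))
        jost_locus_components(sub / tot, tot / 2)
      }, numeric(2))
      comp <- comp[, !is.na(comp["hs", ]), drop = FALSE]
      if (ncol(comp) == 0) next
      d[i, j] <- d[j, i] <- jost_d_from_components(comp, 2)
      if (n_boot > 0 && ncol(comp) > 1) {
        hits <- 0
        for (b in seq_len(n_boot)) {
          idx <- sample.int(ncol(comp), replace = TRUE)
          if (jost_d_from_components(comp[, idx, drop = FALSE], 2) <= 0)
            hits <- hits + 1
        }
        p[i, j] <- p[j, i] <- perm_pvalue(hits, n_boot)
      }
    }
  })
  pv <- p[upper.tri(p)]
  fam <- fdr_correct_by(pv, alpha = alpha)
  sig <- matrix(NA, length(pops), length(pops), dimnames = list(pops, pops))
  sig[upper.tri(sig)] <- fam$significant
  sig[lower.tri(sig)] <- t(sig)[lower.tri(sig)]
  structure(list(d = d, p = p, significant = sig, cpv = fam$cpv,
                 estimator = "jost-d-est", n_boot = n_boot),
            class = "pairwise_matrix")
}
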