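# Independent brute-force oracles. These deliberately avoid the package's
# count-based shortcuts: sums of squares come from explicit pairwise
# distance loops over gene copies, rarefaction from exhaustive subset
# enumeration, components from matrix-power transitive closure.

# Three-level AMOVA from explicit gene-copy distance sums. `copies` is a
# data frame with columns allele, pop, group (one row per gene copy).
bf_amova <- function(copies) {
  ss_set <- function(rows) {
    n <- length(rows)
    if (n < 2) return(0)
    s <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      s <- s + as.numeric(copies$allele[rows[i]] != copies$allele[rows[j]])
    s / n
  }
  n <- nrow(copies)
  pops <- unique(copies$pop)
  groups <- unique(copies$group)
  ss_t <- ss_set(seq_len(n))
  ss_wp <- sum(sapply(pops, function(p) ss_set(which(copies$pop == p))))
  ss_wg <- sum(sapply(groups, function(g) ss_set(which(copies$group == g))))
  p_tot <- length(pops); g_tot <- length(groups)
  df_ag <- g_tot - 1; df_ap <- p_tot - g_tot; df_wp <- n - p_tot
  n_p <- sapply(pops, function(p) sum(copies$pop == p))
  grp_of_pop <- sapply(pops, function(p)
    copies$group[which(copies$pop == p)[1]])
  t_g <- sapply(groups, function(g) sum(n_p[grp_of_pop == g]))
  s2_g <- sapply(groups, function(g) sum(n_p[grp_of_pop == g]^2))
  n1 <- (n - sum(s2_g / t_g)) / df_ap
  n2 <- (sum(s2_g / t_g) - sum(n_p^2) / n) / df_ag
  n3 <- (n - sum(t_g^2) / n) / df_ag
  sigma_c <- ss_wp / df_wp
  sigma_b <- ((ss_wg - ss_wp) / df_ap - sigma_c) / n1
  sigma_a <- ((ss_t - ss_wg) / df_ag - sigma_c - n2 * sigma_b) / n3
  c(a = sigma_a, b = sigma_b, c = sigma_c)
}

# Weir-Cockerham two-population theta written out allele by allele with
# scalar loops (no tabulation shortcuts).
bf_wc_theta <- function(a1, a2, pop) {
  pops <- unique(pop)
  r <- length(pops)
  n_i <- sapply(pops, function(p) sum(pop == p))
  nsum <- sum(n_i); nbar <- nsum / r
  n_c <- (nsum - sum(n_i^2) / nsum) / (r - 1)
  alleles <- unique(c(a1, a2))
  A <- 0; B <- 0; C <- 0
  for (al in alleles) {
    p_i <- sapply(pops, function(p) {
      rows <- pop == p
      (sum(a1[rows] == al) + sum(a2[rows] == al)) / (2 * sum(rows))
    })
    h_i <- sapply(pops, function(p) {
      rows <- pop == p
      mean((a1[rows] == al) != (a2[rows] == al))
    })
    pbar <- sum(n_i * p_i) / nsum
    hbar <- sum(n_i * h_i) / nsum
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    A <- A + (nbar / n_c) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    B <- B + (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    C <- C + hbar / 2
  }
  A / (A + B + C)
}

# Expected distinct alleles in subsamples of size m, by exhaustive
# enumeration over all subsets of gene copies.
bf_rarefaction <- function(counts, m) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(copies), m)
  mean(apply(subs, 2, function(idx) length(unique(copies[idx]))))
}

# Exact two-allele HWE p-value by direct enumeration over heterozygote
# counts (Levene distribution).
bf_hwe_2allele <- function(n11, n12, n22) {
  n <- n11 + n12 + n22
  c1 <- 2 * n11 + n12
  c2 <- 2 * n22 + n12
  lp <- function(h) {
    if ((c1 - h) %% 2 != 0 || h > min(c1, c2)) return(-Inf)
    hom1 <- (c1 - h) / 2; hom2 <- (c2 - h) / 2
    if (hom1 < 0 || hom2 < 0) return(-Inf)
    lfactorial(n) + lfactorial(c1) + lfactorial(c2) + h * log(2) -
      lfactorial(2 * n) - lfactorial(h) - lfactorial(hom1) - lfactorial(hom2)
  }
  hs <- 0:min(c1, c2)
  lps <- sapply(hs, lp)
  probs <- exp(lps[is.finite(lps)])
  obs <- exp(lp(n12))
  sum(probs[probs <= obs * (1 + 1e-9)]) / sum(probs)
}

# Connected components by boolean matrix-power transitive closure.
bf_components <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (all(nxt == reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  cid <- 0
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      cid <- cid + 1
      comp[reach[i, ]] <- cid
    }
  }
  comp
}
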