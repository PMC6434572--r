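# Weir-Cockerham theta and Nei-style G_ST pairwise differentiation.

# Per-locus individual-level structure reused by estimators and
# permutation tests: one data frame per locus with sample_id, a1, a2
# (allele indices into that locus's allele set).
gd_locus_structure <- function(dataset) {
  out <- lapply(dataset$loci, function(loc) {
    pr <- gd_diploid_pairs(dataset, loc)
    alleles <- sort(unique(c(pr$a1, pr$a2)))
    list(sample_id = pr$sample_id,
         a1 = match(pr$a1, alleles), a2 = match(pr$a2, alleles),
         n_alleles = length(alleles))
  })
  names(out) <- dataset$loci
  out
}

# Weir-Cockerham variance components for one locus from integer allele
# indices (a1, a2 in 1..k) and an integer population vector (1..npop).
# Returns c(a, b, c) summed over alleles; zeros when fewer than two
# populations carry data or the locus is monomorphic.
wc_components_int <- function(a1, a2, pop, npop, k) {
  if (k < 2) return(c(a = 0, b = 0, c = 0))
  sz <- npop * k
  cnt <- tabulate((a1 - 1L) * npop + pop, sz) +
         tabulate((a2 - 1L) * npop + pop, sz)
  cnt <- matrix(cnt, npop, k)
  het <- a1 != a2
  hcnt <- matrix(tabulate((a1[het] - 1L) * npop + pop[het], sz) +
                 tabulate((a2[het] - 1L) * npop + pop[het], sz), npop, k)
  n_i <- tabulate(pop, npop)
  keep <- n_i > 0
  r <- sum(keep)
  if (r < 2) return(c(a = 0, b = 0, c = 0))
  n_i <- n_i[keep]
  cnt <- cnt[keep, , drop = FALSE]
  hcnt <- hcnt[keep, , drop = FALSE]
  nsum <- sum(n_i)
  nbar <- nsum / r
  n_c <- (nsum - sum(n_i^2) / nsum) / (r - 1)
  p_ia <- cnt / (2 * n_i)
  h_ia <- hcnt / n_i
  pbar <- colSums(n_i * p_ia) / nsum
  hbar <- colSums(n_i * h_ia) / nsum
  s2 <- colSums(n_i * (p_ia - matrix(pbar, r, k, byrow = TRUE))^2) /
    ((r - 1) * nbar)
  a <- (nbar / n_c) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = sum(a), b = sum(b), c = sum(cc))
}

# Components for one locus given a population assignment named by sample
# id (general path; the pairwise permutation loop uses integer vectors).
wc_locus_components <- function(ld, assign) {
  pop <- assign[ld$sample_id]
  ok <- !is.na(pop)
  pop <- factor(pop[ok])
  wc_components_int(ld$a1[ok], ld$a2[ok], as.integer(pop), nlevels(pop),
                    ld$n_alleles)
}

# Multi-locus theta from summed components.
wc_theta <- function(locus_data, assign) {
  comp <- vapply(locus_data, wc_locus_components, numeric(3), assign = assign)
  s <- rowSums(comp)
  tot <- s["a"] + s["b"] + s["c"]
  if (tot == 0) return(0)
  unname(s["a"] / tot)
}

#' Pairwise F_ST matrix (Weir-Cockerham theta)
#'
#' Multi-locus theta for every population pair, with significance by
#' permuting individuals between the two populations.
#'
#' @param dataset a diploid `genotype_dataset` with >= 2 populations.
#' @param n_perm permutations per pair (0 skips testing).
#' @param seed RNG seed.
#' @return an object of class `pairwise_matrix`: list with `fst` and `p`
#'   (symmetric matrices, zero/NA diagonal), `estimator` and `n_perm`.
#' @export
pairwise_fst <- function(dataset, n_perm = 10000, seed = NULL) {
  stopifnot(dataset$variant == "diploid")
  pops <- unique(dataset$samples$population)
  if (length(pops) < 2) stop("need >= 2 populations")
  locus_data <- gd_locus_structure(dataset)
  assign_all <- stats::setNames(dataset$samples$population,
                                dataset$samples$sample_id)
  fst <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  p <- matrix(NA_real_, length(pops), length(pops),
              dimnames = list(pops, pops))
  with_seed(seed, {
    for (i in seq_len(length(pops) - 1)) for (j in (i + 1):length(pops)) {
      ids <- names(assign_all)[assign_all %in% pops[c(i, j)]]
      popvec <- ifelse(assign_all[ids] == pops[i], 1L, 2L)
      # per-locus rows restricted to the pair, indexed into `ids`
      sub <- lapply(locus_data, function(ld) {
        sel <- which(ld$sample_id %in% ids)
        list(idx = match(ld$sample_id[sel], ids),
             a1 = ld$a1[sel], a2 = ld$a2[sel], k = ld$n_alleles)
      })
      theta_of <- function(pv) {
        s <- c(0, 0, 0)
        for (ldp in sub)
          s <- s + wc_components_int(ldp$a1, ldp$a2, pv[ldp$idx], 2L, ldp$k)
        if (sum(s) == 0) 0 else s[1] / sum(s)
      }
      th <- theta_of(popvec)
      fst[i, j] <- fst[j, i] <- th
      if (n_perm > 0) {
        hits <- 0
        for (b in seq_len(n_perm))
          if (theta_of(sample(popvec)) >= th - 1e-12) hits <- hits + 1
        p[i, j] <- p[j, i] <- perm_pvalue(hits, n_perm)
      }
    }
  })
  structure(list(fst = fst, p = p, estimator = "weir-cockerham",
                 n_perm = n_perm), class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  nm <- intersect(c("fst", "d"), names(x))[1]
  cat(sprintf("<pairwise_matrix> %s, %d populations (%s)\n", nm,
              nrow(x[[nm]]), x$estimator))
  print(round(x[[nm]], 4))
  invisible(x)
}

# Nei-style G_ST between two populations from frequency matrices (rows =
# the two pops), averaged across loci as sum(Ht - Hs) / sum(Ht).
nei_gst_pair <- function(freq_list) {
  num <- 0; den <- 0
  for (f in freq_list) {
    if (is.null(f)) next
    hs <- mean(1 - rowSums(f^2))
    pbar <- colMeans(f)
    ht <- 1 - sum(pbar^2)
    num <- num + (ht - hs)
    den <- den + ht
  }
  if (den == 0) return(0)
  num / den
}

#' Pairwise F_ST for polyploid (chimeric) data
#'
#' Allele frequencies are estimated by equal-dosage weighting (every
#' individual contributes total weight 1 split over its distinct alleles);
#' differentiation per pair is a Nei-style gene-diversity partition
#' `(H_T - H_S) / H_T` accumulated across loci. Without chimeras this
#' equals the same partition computed from diploid frequencies.
#'
#' @param dataset a polyploid `genotype_dataset` (ploidy cap 4).
#' @param n_perm permutations (individuals shuffled between the pair).
#' @param seed RNG seed.
#' @return a `pairwise_matrix` with elements `fst` and `p`.
#' @export
polyploid_fst <- function(dataset, n_perm = 0, seed = NULL) {
  pops <- unique(dataset$samples$population)
  if (length(pops) < 2) stop("need >= 2 populations")
  pair_freqs <- function(dat, two) {
    cm <- gd_count_matrices(dat, weighted = TRUE)
    lapply(cm, function(m) {
      f <- m[two, , drop = FALSE]
      rs <- rowSums(f)
      if (any(rs == 0)) return(NULL)
      f / rs
    })
  }
  fst <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  p <- matrix(NA_real_, length(pops), length(pops),
              dimnames = list(pops, pops))
  with_seed(seed, {
    for (i in seq_len(length(pops) - 1)) for (j in (i + 1):length(pops)) {
      two <- pops[c(i, j)]
      sub <- gd_filter(dataset, populations = two)
      g <- nei_gst_pair(pair_freqs(sub, two))
      fst[i, j] <- fst[j, i] <- g
      if (n_perm > 0) {
        ids <- sub$samples$sample_id
        hits <- 0
        for (b in seq_len(n_perm)) {
          perm <- sub
          perm$samples$population <- sample(perm$samples$population)
          if (nei_gst_pair(pair_freqs(perm, two)) >= g - 1e-12)
            hits <- hits + 1
        }
        p[i, j] <- p[j, i] <- perm_pvalue(hits, n_perm)
      }
    }
  })
  structure(list(fst = fst, p = p, estimator = "nei-gst-equal-dosage",
                 n_perm = n_perm), class = "pairwise_matrix")
}

#' Linearize an F_ST matrix for distance-based analyses
#'
#' `F_ST / (1 - F_ST)` with negative estimates truncated at 0.
#'
#' @param m symmetric F_ST matrix.
#' @return symmetric matrix of linearized values.
#' @export
linearized_fst <- function(m) {
  m <- pmax(m, 0)
  out <- m / (1 - m)
  diag(out) <- 0
  out
}
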