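# Per-locus and per-population diversity statistics: heterozygosity,
# Weir-Cockerham inbreeding, and rarefied (private) allelic richness.

#' Expected heterozygosity from allele counts
#'
#' `1 - sum(p_i^2)`, with Nei's small-sample correction `T / (T - 1)`
#' (T gene copies) when `unbiased = TRUE`.
#'
#' @param allele_counts non-negative counts of gene copies per allele.
#' @param unbiased apply the small-sample correction.
#' @return numeric in `[0, 1]`.
#' @export
expected_heterozygosity <- function(allele_counts, unbiased = TRUE) {
  t <- sum(allele_counts)
  if (t < 2) stop("need at least 2 gene copies")
  p <- allele_counts / t
  he <- 1 - sum(p^2)
  if (unbiased) he <- he * t / (t - 1)
  he
}

#' Observed heterozygosity from diploid genotypes
#'
#' @param a1,a2 allele vectors (one entry per non-missing genotype).
#' @return fraction of genotypes with two distinct alleles.
#' @export
observed_heterozygosity <- function(a1, a2) {
  stopifnot(length(a1) == length(a2))
  if (length(a1) == 0) return(NA_real_)
  mean(a1 != a2)
}

# Weir-Cockerham within-population variance components (b = among
# individuals, c = within individuals) for one population at one locus.
# Returns per-allele sums; f = 1 - sum(c) / sum(b + c).
wc_within_components <- function(a1, a2) {
  n <- length(a1)
  if (n < 2) return(c(b = 0, c = 0))
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2) return(c(b = 0, c = 0))
  b_tot <- 0; c_tot <- 0
  for (al in alleles) {
    p <- (sum(a1 == al) + sum(a2 == al)) / (2 * n)
    hbar <- mean((a1 == al) != (a2 == al))
    b <- (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * hbar)
    b_tot <- b_tot + b
    c_tot <- c_tot + hbar / 2
  }
  c(b = b_tot, c = c_tot)
}

#' Multi-locus inbreeding coefficient per population
#'
#' Weir-Cockerham within-population f summed over loci, with a permutation
#' p-value obtained by shuffling allele copies among individuals within
#' the population (which enforces the Hardy-Weinberg null). The simple
#' ratio `1 - Ho/He` is reported alongside for transparency.
#'
#' @param dataset a diploid `genotype_dataset`.
#' @param population population label; `NULL` computes all populations.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return data frame with `population`, `fis` (Weir-Cockerham f),
#'   `fis_ratio`, `p_value` (two-sided) and `n_loci_used`; monomorphic
#'   populations yield `NA`.
#' @export
inbreeding_coefficient <- function(dataset, population = NULL,
                                   n_perm = 10000, seed = NULL) {
  stopifnot(dataset$variant == "diploid")
  pops <- population %||% unique(dataset$samples$population)
  pairs <- lapply(dataset$loci, function(loc) gd_diploid_pairs(dataset, loc))
  names(pairs) <- dataset$loci
  with_seed(seed, {
    out <- lapply(pops, function(pop) {
      per_locus <- lapply(dataset$loci, function(loc) {
        pr <- pairs[[loc]]
        pr[pr$population == pop, c("a1", "a2")]
      })
      comp <- vapply(per_locus, function(g) wc_within_components(g$a1, g$a2),
                     numeric(2))
      used <- colSums(abs(comp)) > 0
      if (!any(used))
        return(data.frame(population = pop, fis = NA_real_,
                          fis_ratio = NA_real_, p_value = NA_real_,
                          n_loci_used = 0L))
      f_of <- function(genos) {
        comp <- vapply(genos, function(g) wc_within_components(g$a1, g$a2),
                       numeric(2))
        s <- rowSums(comp)
        if (s["b"] + s["c"] == 0) return(NA_real_)
        1 - s["c"] / (s["b"] + s["c"])
      }
      f_obs <- f_of(per_locus)
      ho <- vapply(per_locus, function(g) {
        if (nrow(g) == 0) NA_real_ else observed_heterozygosity(g$a1, g$a2)
      }, numeric(1))
      he <- vapply(per_locus, function(g) {
        cnt <- table(c(g$a1, g$a2))
        if (sum(cnt) < 2) NA_real_ else expected_heterozygosity(cnt)
      }, numeric(1))
      fr <- 1 - mean(ho, na.rm = TRUE) / mean(he, na.rm = TRUE)
      hits <- 0
      for (b in seq_len(n_perm)) {
        perm <- lapply(per_locus, function(g) {
          if (nrow(g) < 2) return(g)
          copies <- sample(c(g$a1, g$a2))
          data.frame(a1 = copies[seq_len(nrow(g))],
                     a2 = copies[nrow(g) + seq_len(nrow(g))])
        })
        fp <- f_of(perm)
        if (!is.na(fp) && abs(fp) >= abs(f_obs)) hits <- hits + 1
      }
      data.frame(population = pop, fis = f_obs, fis_ratio = fr,
                 p_value = perm_pvalue(hits, n_perm),
                 n_loci_used = sum(used), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a hypergeometric subsample of
#' `2 g` gene copies: `sum_a (1 - choose(T - N_a, 2g) / choose(T, 2g))`.
#'
#' @param allele_counts gene-copy counts per allele.
#' @param g rarefaction size in diploid individuals (2g gene copies).
#' @return expected allele count (numeric).
#' @export
rarefied_allelic_richness <- function(allele_counts, g = 19) {
  t <- sum(allele_counts)
  m <- 2 * g
  if (m > t) stop("rarefaction size 2g = ", m, " exceeds ", t, " gene copies")
  sum(1 - hyper_absent_prob(allele_counts, t, m))
}

#' Rarefied private allelic richness
#'
#' Expected number of alleles present in a rarefied sample (2g copies) of
#' the focal population and simultaneously absent from independent rarefied
#' samples of every other population (product-form closed expression).
#'
#' @param count_matrix populations x alleles matrix of gene-copy counts.
#' @param g rarefaction size in diploid individuals.
#' @return named numeric vector, one value per population.
#' @export
rarefied_private_richness <- function(count_matrix, g = 19) {
  stopifnot(is.matrix(count_matrix), nrow(count_matrix) >= 2)
  m <- 2 * g
  tot <- rowSums(count_matrix)
  if (any(m > tot))
    stop("rarefaction size 2g = ", m, " exceeds gene copies in population ",
         rownames(count_matrix)[which(m > tot)[1]])
  res <- vapply(seq_len(nrow(count_matrix)), function(focal) {
    pres <- 1 - hyper_absent_prob(count_matrix[focal, ], tot[focal], m)
    absent <- rep(1, ncol(count_matrix))
    for (o in setdiff(seq_len(nrow(count_matrix)), focal))
      absent <- absent * hyper_absent_prob(count_matrix[o, ], tot[o], m)
    sum(pres * absent)
  }, numeric(1))
  stats::setNames(res, rownames(count_matrix))
}

#' Per-population diversity table
#'
#' One row per population with sample size, mean alleles per locus for the
#' diploid and (optionally) polyploid variants, rarefied allelic and
#' private allelic richness at reference size `g`, observed and expected
#' heterozygosity, the multi-locus inbreeding coefficient, and the chimera
#' proportion. Means are across loci, with standard errors (`n - 1`
#' denominator).
#'
#' @param diploid a diploid `genotype_dataset`.
#' @param polyploid optional matched polyploid `genotype_dataset`.
#' @param g rarefaction reference size in individuals; capped automatically
#'   at the smallest per-locus sample.
#' @param n_perm permutations for the F_IS test.
#' @param seed RNG seed.
#' @return data frame, one row per population plus an `Overall` row.
#' @export
diversity_table <- function(diploid, polyploid = NULL, g = 19,
                            n_perm = 1000, seed = NULL) {
  stopifnot(diploid$variant == "diploid")
  pops <- unique(diploid$samples$population)
  counts <- gd_count_matrices(diploid, weighted = FALSE)
  g_eff <- min(g, floor(min(vapply(counts, function(m) min(rowSums(m)),
                                   numeric(1))) / 2))
  fis <- inbreeding_coefficient(diploid, n_perm = n_perm, seed = seed)
  cc <- if (!is.null(polyploid)) flag_chimeras(polyploid)$cc else NULL

  se <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  rows <- lapply(pops, function(pop) {
    an_dip <- vapply(counts, function(m) sum(m[pop, ] > 0), numeric(1))
    arn <- vapply(counts, function(m)
      rarefied_allelic_richness(m[pop, ], g_eff), numeric(1))
    arp <- vapply(counts, function(m)
      rarefied_private_richness(m, g_eff)[pop], numeric(1))
    ho <- vapply(diploid$loci, function(loc) {
      pr <- gd_diploid_pairs(diploid, loc)
      pr <- pr[pr$population == pop, ]
      if (nrow(pr) == 0) NA_real_ else observed_heterozygosity(pr$a1, pr$a2)
    }, numeric(1))
    he <- vapply(counts, function(m) {
      if (sum(m[pop, ]) < 2) NA_real_ else expected_heterozygosity(m[pop, ])
    }, numeric(1))
    an_poly <- if (!is.null(polyploid)) {
      pc <- gd_count_matrices(polyploid, weighted = FALSE)
      vapply(pc, function(m) if (pop %in% rownames(m)) sum(m[pop, ] > 0)
             else NA_real_, numeric(1))
    } else rep(NA_real_, length(counts))
    data.frame(
      population = pop,
      n = sum(diploid$samples$population == pop),
      a_n_dip = mean(an_dip), a_n_dip_se = se(an_dip),
      a_n_poly = mean(an_poly), a_n_poly_se = se(an_poly),
      a_rn = mean(arn), a_rn_se = se(arn),
      a_rp = mean(arp), a_rp_se = se(arp),
      h_o = mean(ho, na.rm = TRUE), h_o_se = se(ho),
      h_e = mean(he, na.rm = TRUE), h_e_se = se(he),
      f_is = fis$fis[fis$population == pop],
      f_is_p = fis$p_value[fis$population == pop],
      cc = if (is.null(cc) || !pop %in% cc$population) NA_real_
           else cc$cc[cc$population == pop],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "g_rarefaction") <- g_eff
  out
}
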