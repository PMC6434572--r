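# Marker screening: Hardy-Weinberg exact tests, linkage disequilibrium,
# null-allele estimation, the harmonic-number FDR correction, and the
# diploid-vs-polyploid allele-frequency shift.

# Log-probability of a genotype table under the Levene/Haldane conditional
# distribution given allele counts: n! * prod(c_a!) * 2^het / ((2n)! *
# prod(n_ab!)).
hwe_log_prob <- function(het_counts, hom_counts, n, copies) {
  lfactorial(n) + sum(lfactorial(copies)) + sum(het_counts) * log(2) -
    lfactorial(2 * n) - sum(lfactorial(het_counts)) -
    sum(lfactorial(hom_counts))
}

# Enumerate all genotype tables compatible with the observed allele counts;
# returns the exact p-value (sum of probabilities of tables no more
# probable than the observed one).
hwe_enumerate <- function(het_obs, hom_obs, n, copies) {
  k <- length(copies)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  logp_obs <- hwe_log_prob(het_obs, hom_obs, n, copies)
  total <- 0; at_most <- 0
  rec <- function(i, rem, het) {
    if (i > nrow(pairs)) {
      if (any(rem %% 2 != 0)) return()
      hom <- rem / 2
      lp <- hwe_log_prob(het, hom, n, copies)
      p <- exp(lp)
      total <<- total + p
      if (lp <= logp_obs + 1e-9) at_most <<- at_most + p
      return()
    }
    a <- pairs[i, 1]; b <- pairs[i, 2]
    for (h in 0:min(rem[a], rem[b])) {
      het[i] <- h
      rem2 <- rem
      rem2[a] <- rem2[a] - h; rem2[b] <- rem2[b] - h
      rec(i + 1, rem2, het)
    }
  }
  rec(1, copies, numeric(nrow(pairs)))
  at_most / total
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Complete enumeration of genotype tables conditional on allele counts for
#' up to `max_enumerate` alleles; a seeded Markov chain (pairwise allele
#' swaps with Metropolis acceptance) beyond that. Rejection is
#' probability-based (tables no more probable than the observed one count
#' toward p), the standard two-sided exact test.
#'
#' @param a1,a2 allele vectors of the non-missing diploid genotypes.
#' @param max_enumerate largest allele number handled by full enumeration.
#' @param n_mcmc Monte Carlo iterations after burn-in.
#' @param burn_in discarded initial iterations.
#' @param seed RNG seed for the chain.
#' @return list with `p_value`, `method` ("enumeration", "mcmc" or
#'   "monomorphic") and `n_alleles`.
#' @export
hwe_exact_test <- function(a1, a2, max_enumerate = 4, n_mcmc = 20000,
                           burn_in = 2000, seed = NULL) {
  stopifnot(length(a1) == length(a2))
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k < 2)
    return(list(p_value = 1, method = "monomorphic", n_alleles = k))
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  lo <- pmin(i1, i2); hi <- pmax(i1, i2)
  n <- length(lo)
  copies <- tabulate(c(i1, i2), k)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  het_obs <- vapply(seq_len(nrow(pairs)), function(r)
    sum(lo == pairs[r, 1] & hi == pairs[r, 2]), numeric(1))
  hom_obs <- vapply(seq_len(k), function(a) sum(lo == a & hi == a),
                    numeric(1))
  if (k <= max_enumerate) {
    p <- hwe_enumerate(het_obs, hom_obs, n, copies)
    return(list(p_value = p, method = "enumeration", n_alleles = k))
  }
  # Monte Carlo chain: random transpositions of allele copies between
  # individuals. A uniform walk over copy arrangements induces exactly the
  # Levene conditional distribution over genotype tables, so every move is
  # accepted and no Metropolis correction is needed; the p-value
  # accumulates the probability-ordering indicator against the observed
  # table's (unnormalised) log-probability 2^het / prod(n_ab!).
  with_seed(seed, {
    g <- cbind(lo, hi)
    logp <- function(g) {
      het <- g[, 1] != g[, 2]
      cnt <- table(paste(g[, 1], g[, 2]))
      sum(het) * log(2) - sum(lfactorial(cnt))
    }
    obs <- logp(g)
    hits <- 0
    for (it in seq_len(burn_in + n_mcmc)) {
      ij <- sample.int(n, 2)
      ci <- sample.int(2, 1); cj <- sample.int(2, 1)
      tmp <- g[ij[1], ci]
      g[ij[1], ci] <- g[ij[2], cj]
      g[ij[2], cj] <- tmp
      g[ij, ] <- cbind(pmin(g[ij, 1], g[ij, 2]),
                       pmax(g[ij, 1], g[ij, 2]))
      if (it > burn_in && logp(g) <= obs + 1e-9) hits <- hits + 1
    }
    list(p_value = (hits + 1) / (n_mcmc + 1), method = "mcmc",
         n_alleles = k)
  })
}

# G-like statistic on a two-way contingency table of genotype classes.
g_statistic <- function(x, y) {
  tab <- table(x, y)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  o <- as.numeric(tab); e <- as.numeric(e)
  pos <- o > 0
  2 * sum(o[pos] * log(o[pos] / e[pos]))
}

#' Permutation test of linkage disequilibrium between locus pairs
#'
#' Genotypic association test per population and locus pair: the statistic
#' is a G-like score on the two-locus genotype contingency table, and the
#' null is built by permuting single-locus genotypes among individuals,
#' which breaks inter-locus association while preserving single-locus
#' genotype frequencies. One row is emitted for every population by locus
#' pair, so the family size is always `choose(L, 2) * P`.
#'
#' @param dataset a diploid `genotype_dataset`.
#' @param n_perm permutations; 0 skips the test and reports statistics only.
#' @param min_n minimum individuals with both loci called.
#' @param seed RNG seed.
#' @return data frame with `population`, `locus1`, `locus2`, `n`,
#'   `statistic`, `p_value` (`NA` when `n < min_n` or `n_perm = 0`).
#' @export
ld_test <- function(dataset, n_perm = 10000, min_n = 5, seed = NULL) {
  stopifnot(dataset$variant == "diploid")
  loci <- dataset$loci
  pops <- unique(dataset$samples$population)
  geno <- lapply(loci, function(loc) {
    pr <- gd_diploid_pairs(dataset, loc)
    stats::setNames(paste(pr$a1, pr$a2, sep = "/"), pr$sample_id)
  })
  names(geno) <- loci
  with_seed(seed, {
    rows <- list()
    for (pop in pops) {
      ids_pop <- dataset$samples$sample_id[dataset$samples$population == pop]
      for (i in seq_len(length(loci) - 1)) for (j in (i + 1):length(loci)) {
        gi <- geno[[i]][ids_pop]; gj <- geno[[j]][ids_pop]
        ok <- !is.na(gi) & !is.na(gj)
        n <- sum(ok)
        stat <- NA_real_; p <- NA_real_
        if (n >= min_n) {
          x <- gi[ok]; y <- gj[ok]
          stat <- g_statistic(x, y)
          if (n_perm > 0) {
            hits <- 0
            for (b in seq_len(n_perm))
              if (g_statistic(x, sample(y)) >= stat - 1e-12) hits <- hits + 1
            p <- perm_pvalue(hits, n_perm)
          }
        }
        rows[[length(rows) + 1]] <- data.frame(
          population = pop, locus1 = loci[i], locus2 = loci[j], n = n,
          statistic = stat, p_value = p, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Null-allele frequency estimate with bootstrap flag
#'
#' Chakraborty-style estimator `r = (He - Ho) / (He + Ho)` from the
#' heterozygote deficit at one locus, with a bootstrap (over individuals)
#' confidence interval; the locus is flagged when the interval excludes 0.
#'
#' @param a1,a2 allele vectors of the non-missing diploid genotypes.
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed RNG seed.
#' @return list with `r`, `ci` (length 2), `flagged`, `h_o`, `h_e`.
#' @export
null_allele_estimate <- function(a1, a2, n_boot = 1000, conf = 0.95,
                                 seed = NULL) {
  stopifnot(length(a1) == length(a2), length(a1) >= 2)
  r_of <- function(x1, x2) {
    ho <- observed_heterozygosity(x1, x2)
    he <- expected_heterozygosity(table(c(x1, x2)))
    if (he + ho == 0) stop("He + Ho = 0: locus carries no information")
    (he - ho) / (he + ho)
  }
  r <- r_of(a1, a2)
  with_seed(seed, {
    n <- length(a1)
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(r_of(a1[idx], a2[idx]), error = function(e) NA_real_)
    }, numeric(1))
    a <- (1 - conf) / 2
    ci <- stats::quantile(boots, c(a, 1 - a), na.rm = TRUE, names = FALSE)
    list(r = r, ci = ci, flagged = ci[1] > 0 || ci[2] < 0,
         h_o = observed_heterozygosity(a1, a2),
         h_e = expected_heterozygosity(table(c(a1, a2))))
  })
}

#' Harmonic-number false discovery rate correction
#'
#' Corrected p-value threshold `CPV = alpha / sum_{i=1..k}(1/i)` for a
#' family of k tests (Benjamini-Yekutieli control under arbitrary
#' dependence); tests with `p < CPV` are flagged significant.
#'
#' @param p_values numeric vector of p-values (may contain `NA`, which
#'   still count toward the family size but are never significant).
#' @param alpha family-wise level.
#' @param k family size; defaults to `length(p_values)`.
#' @return an object of class `fdr_family`: list with `p_values`, `k`,
#'   `alpha`, `cpv` (full precision), `cpv_rounded` (3 decimals),
#'   `significant` (logical vector), `n_significant`, `prop_significant`.
#' @export
fdr_correct_by <- function(p_values, alpha = 0.05, k = length(p_values)) {
  if (k < 1) stop("empty test family")
  cpv <- alpha / harmonic_number(k)
  sig <- !is.na(p_values) & p_values < cpv
  structure(list(p_values = p_values, k = k, alpha = alpha, cpv = cpv,
                 cpv_rounded = round(cpv, 3), significant = sig,
                 n_significant = sum(sig),
                 prop_significant = if (k > 0) sum(sig) / k else NA_real_),
            class = "fdr_family")
}

#' @export
print.fdr_family <- function(x, ...) {
  cat(sprintf("<fdr_family> k = %d, alpha = %g, CPV = %.3f (%.6g)\n",
              x$k, x$alpha, x$cpv_rounded, x$cpv))
  cat(sprintf("  significant: %d / %d (%.1f%%)\n", x$n_significant, x$k,
              100 * x$prop_significant))
  invisible(x)
}

#' Allele-frequency shift between the diploid and polyploid variants
#'
#' Compares per-population, per-locus allele frequency spectra of the two
#' dataset variants (polyploid frequencies use equal-dosage weighting, each
#' individual contributing total weight 1 over its distinct alleles).
#' Chimeric scoring typically lowers the modal allele's frequency, raises
#' minor allele frequencies, and introduces alleles absent from the
#' diploid spectrum.
#'
#' @param diploid,polyploid matched `genotype_dataset`s from the same
#'   samples.
#' @return list with `deltas` (population, locus, allele, freq_dip,
#'   freq_poly, delta, novel), `modal` (delta of the diploid-modal allele
#'   per population by locus), and `summary` (mean modal delta, number of
#'   novel alleles).
#' @export
chimera_frequency_shift <- function(diploid, polyploid) {
  stopifnot(diploid$variant == "diploid", polyploid$variant == "polyploid")
  if (!setequal(diploid$loci, polyploid$loci))
    stop("locus sets differ between variants")
  cd <- gd_count_matrices(diploid, weighted = TRUE)
  cp <- gd_count_matrices(polyploid, weighted = TRUE)
  rows <- list(); modal <- list()
  for (loc in diploid$loci) {
    alleles <- sort(unique(c(as.integer(colnames(cd[[loc]])),
                             as.integer(colnames(cp[[loc]])))))
    for (pop in rownames(cd[[loc]])) {
      fd <- stats::setNames(rep(0, length(alleles)), alleles)
      fp <- fd
      d <- cd[[loc]][pop, ]; p <- cp[[loc]][pop, ]
      if (sum(d) > 0) fd[names(d)] <- d / sum(d)
      if (sum(p) > 0) fp[names(p)] <- p / sum(p)
      rows[[length(rows) + 1]] <- data.frame(
        population = pop, locus = loc, allele = alleles,
        freq_dip = unname(fd), freq_poly = unname(fp),
        delta = unname(fp - fd),
        novel = unname(fd == 0 & fp > 0), stringsAsFactors = FALSE)
      if (sum(d) > 0) {
        top <- alleles[which.max(fd)]
        modal[[length(modal) + 1]] <- data.frame(
          population = pop, locus = loc, allele = top,
          delta = unname(fp[as.character(top)] - fd[as.character(top)]),
          stringsAsFactors = FALSE)
      }
    }
  }
  deltas <- do.call(rbind, rows)
  modal <- do.call(rbind, modal)
  list(deltas = deltas, modal = modal,
       summary = list(mean_modal_delta = mean(modal$delta),
                      n_novel = sum(deltas$novel)))
}
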