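# Hierarchical analysis of molecular variance on gene copies, with the
# three standard permutation schemes and locus-bootstrap confidence
# intervals.

#' Define a population-to-group hierarchy
#'
#' @param mapping named character vector (`population = group`) or a data
#'   frame with columns `population` and `group`.
#' @return an object of class `hierarchy_spec` (named character vector).
#' @export
hierarchy_spec <- function(mapping) {
  if (is.data.frame(mapping)) {
    stopifnot(all(c("population", "group") %in% names(mapping)))
    mapping <- stats::setNames(as.character(mapping$group),
                               mapping$population)
  }
  if (is.null(names(mapping)) || anyDuplicated(names(mapping)) > 0)
    stop("every population must be assigned to exactly one group")
  structure(mapping, class = "hierarchy_spec")
}

# Sum over unequal pairs within a set, from gene-copy allele counts:
# SS = (choose(n, 2) - sum_a choose(c_a, 2)) / n with 0/1 allele distance.
ss_from_counts <- function(counts) {
  n <- sum(counts)
  if (n < 2) return(0)
  (choose(n, 2) - sum(choose(counts, 2))) / n
}

# Variance components for one locus from a population x allele gene-copy
# count matrix and the group of each population row. Returns sigma
# components, degrees of freedom and SSDs; NA sigma_a when only one group
# carries data.
amova_locus <- function(pop_counts, group_of_pop) {
  n_p <- rowSums(pop_counts)
  use <- n_p > 0
  pop_counts <- pop_counts[use, , drop = FALSE]
  group_of_pop <- group_of_pop[use]
  n_p <- n_p[use]
  p_tot <- nrow(pop_counts)
  groups <- unique(group_of_pop)
  g_tot <- length(groups)
  n <- sum(n_p)
  if (p_tot < 2) return(NULL)

  ss_wp <- sum(apply(pop_counts, 1, ss_from_counts))
  grp_counts <- rowsum(pop_counts, group = group_of_pop)
  ss_wg <- sum(apply(grp_counts, 1, ss_from_counts))
  ss_t <- ss_from_counts(colSums(pop_counts))

  if (g_tot < 2) {
    # two-level design: among populations / within populations
    df_ap <- p_tot - 1; df_wp <- n - p_tot
    ms_wp <- ss_wp / df_wp
    n_prime <- (n - sum(n_p^2) / n) / df_ap
    sigma_c <- ms_wp
    sigma_b <- ((ss_t - ss_wp) / df_ap - sigma_c) / n_prime
    return(list(sigma = c(a = NA_real_, b = sigma_b, c = sigma_c),
                ss = c(ag = NA_real_, ap = ss_t - ss_wp, wp = ss_wp),
                df = c(ag = NA_real_, ap = df_ap, wp = df_wp)))
  }

  df_ag <- g_tot - 1; df_ap <- p_tot - g_tot; df_wp <- n - p_tot
  t_g <- tapply(n_p, group_of_pop, sum)[groups]
  s2_g <- tapply(n_p^2, group_of_pop, sum)[groups]
  n1 <- (n - sum(s2_g / t_g)) / df_ap
  n2 <- (sum(s2_g / t_g) - sum(n_p^2) / n) / df_ag
  n3 <- (n - sum(t_g^2) / n) / df_ag

  ms_wp <- ss_wp / df_wp
  ms_ap <- (ss_wg - ss_wp) / df_ap
  ms_ag <- (ss_t - ss_wg) / df_ag
  sigma_c <- ms_wp
  sigma_b <- (ms_ap - sigma_c) / n1
  sigma_a <- (ms_ag - sigma_c - n2 * sigma_b) / n3
  list(sigma = c(a = sigma_a, b = sigma_b, c = sigma_c),
       ss = c(ag = ss_t - ss_wg, ap = ss_wg - ss_wp, wp = ss_wp),
       df = c(ag = df_ag, ap = df_ap, wp = df_wp))
}

# F-statistics from summed sigma components.
amova_f <- function(sigma) {
  tot <- sum(sigma, na.rm = TRUE)
  if (tot == 0) return(c(f_ct = NA_real_, f_sc = NA_real_, f_st = NA_real_))
  if (is.na(sigma["a"])) {
    f <- sigma["b"] / (sigma["b"] + sigma["c"])
    return(c(f_ct = NA_real_, f_sc = unname(f), f_st = unname(f)))
  }
  c(f_ct = unname(sigma["a"] / tot),
    f_sc = unname(sigma["b"] / (sigma["b"] + sigma["c"])),
    f_st = unname((sigma["a"] + sigma["b"]) / tot))
}

# Per-locus pop x allele gene-copy count matrices plus individual-level
# data for permutation schemes that move individuals.
amova_prepare <- function(dataset) {
  pops <- unique(dataset$samples$population)
  locus_data <- gd_locus_structure(dataset)
  assign_all <- stats::setNames(dataset$samples$population,
                                dataset$samples$sample_id)
  np <- length(pops)
  per_locus <- lapply(locus_data, function(ld) {
    pop <- match(assign_all[ld$sample_id], pops)
    k <- ld$n_alleles
    cnt <- matrix(tabulate((ld$a1 - 1L) * np + pop, np * k) +
                  tabulate((ld$a2 - 1L) * np + pop, np * k), np, k,
                  dimnames = list(pops, NULL))
    list(counts = cnt, pop = pop, a1 = ld$a1, a2 = ld$a2,
         sample_id = ld$sample_id)
  })
  list(pops = pops, per_locus = per_locus, assign_all = assign_all)
}

amova_sigma_from_counts <- function(per_locus, group_of_pop,
                                    counts_override = NULL) {
  sig <- matrix(NA_real_, 3, length(per_locus),
                dimnames = list(c("a", "b", "c"), names(per_locus)))
  for (l in seq_along(per_locus)) {
    cnt <- if (is.null(counts_override)) per_locus[[l]]$counts
           else counts_override[[l]]
    res <- amova_locus(cnt, group_of_pop)
    if (!is.null(res)) sig[, l] <- res$sigma
  }
  sig
}

# Rebuild per-locus count matrices after permuting the population label of
# each individual (new_pop: named by sample id, values = pop index).
amova_counts_for_assignment <- function(per_locus, n_pops, new_pop) {
  lapply(per_locus, function(pl) {
    pi <- new_pop[pl$sample_id]
    k <- max(c(pl$a1, pl$a2))
    matrix(tabulate((pl$a1 - 1L) * n_pops + pi, n_pops * k) +
           tabulate((pl$a2 - 1L) * n_pops + pi, n_pops * k), n_pops, k)
  })
}

#' Hierarchical analysis of molecular variance
#'
#' Three-level AMOVA on gene copies (among groups, among populations within
#' groups, within populations) with 0/1 allele distance, variance
#' components summed across loci. F_CT, F_SC and F_ST are tested with the
#' standard permutation schemes (whole populations among groups;
#' individuals among populations within groups; individuals among all
#' populations), and 95% confidence intervals come from bootstrapping over
#' loci. With a single group the design degenerates to two levels
#' (F_CT undefined, F_SC = F_ST).
#'
#' @param dataset a diploid `genotype_dataset`.
#' @param hierarchy a [hierarchy_spec()] (or coercible mapping) assigning
#'   each population to a group.
#' @param n_perm permutations per F-statistic (0 skips testing).
#' @param schemes which F-statistics to test by permutation; restricting
#'   the schemes saves the individual-level permutations when only F_CT is
#'   of interest.
#' @param n_boot_loci locus bootstrap replicates for the CIs.
#' @param seed RNG seed.
#' @return an object of class `amova_result`: `sigma` (variance
#'   components), `percent` (percentages of variation, summing to 100),
#'   `f` (F_CT, F_SC, F_ST), `p` (permutation p-values), `ci` (2x3 matrix),
#'   `df`, `ss`.
#' @export
amova <- function(dataset, hierarchy, n_perm = 10000, n_boot_loci = 20000,
                  seed = NULL,
                  schemes = c("f_ct", "f_sc", "f_st")) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  stopifnot(dataset$variant == "diploid")
  if (!inherits(hierarchy, "hierarchy_spec"))
    hierarchy <- hierarchy_spec(hierarchy)
  prep <- amova_prepare(dataset)
  pops <- prep$pops
  if (!all(pops %in% names(hierarchy)))
    stop("hierarchy is missing populations: ",
         paste(setdiff(pops, names(hierarchy)), collapse = ", "))
  group_of_pop <- unname(unclass(hierarchy)[pops])
  n_groups <- length(unique(group_of_pop))

  sig <- amova_sigma_from_counts(prep$per_locus, group_of_pop)
  sigma <- rowSums(sig, na.rm = TRUE)
  if (n_groups < 2) sigma["a"] <- NA_real_
  f_obs <- amova_f(sigma)

  # aggregate SS / df for the report
  ss <- c(ag = 0, ap = 0, wp = 0); df <- c(ag = 0, ap = 0, wp = 0)
  for (l in seq_along(prep$per_locus)) {
    res <- amova_locus(prep$per_locus[[l]]$counts, group_of_pop)
    if (is.null(res)) next
    ss <- ss + ifelse(is.na(res$ss), 0, res$ss)
    df <- df + ifelse(is.na(res$df), 0, res$df)
  }

  tot <- sum(sigma, na.rm = TRUE)
  percent <- 100 * c(sigma, recursive = TRUE) / tot
  names(percent) <- c("among_groups", "among_pops_within_groups",
                      "within_pops")

  p <- c(f_ct = NA_real_, f_sc = NA_real_, f_st = NA_real_)
  ci <- NULL
  with_seed(seed, {
    if (n_perm > 0) {
      # F_CT: permute populations among groups (labels only; counts fixed)
      if ("f_ct" %in% schemes && n_groups >= 2 && !is.na(f_obs["f_ct"])) {
        hits <- 0
        for (b in seq_len(n_perm)) {
          gp <- sample(group_of_pop)
          fp <- amova_f(rowSums(amova_sigma_from_counts(prep$per_locus, gp),
                                na.rm = TRUE))
          if (!is.na(fp["f_ct"]) && fp["f_ct"] >= f_obs["f_ct"] - 1e-12)
            hits <- hits + 1
        }
        p["f_ct"] <- perm_pvalue(hits, n_perm)
      }
      # F_SC: permute individuals among populations within groups
      # F_ST: permute individuals among all populations
      ids <- dataset$samples$sample_id
      pop_idx <- stats::setNames(match(dataset$samples$population, pops), ids)
      grp_of_ind <- group_of_pop[pop_idx]
      hits_sc <- 0; hits_st <- 0
      if (any(c("f_sc", "f_st") %in% schemes)) {
        for (b in seq_len(n_perm)) {
          if ("f_sc" %in% schemes) {
            new_pop <- pop_idx
            for (g in unique(grp_of_ind)) {
              sel <- which(grp_of_ind == g)
              new_pop[sel] <- sample(pop_idx[sel])
            }
            cnts <- amova_counts_for_assignment(prep$per_locus, length(pops),
                                                new_pop)
            fp <- amova_f(rowSums(
              amova_sigma_from_counts(prep$per_locus, group_of_pop, cnts),
              na.rm = TRUE))
            if (!is.na(fp["f_sc"]) && fp["f_sc"] >= f_obs["f_sc"] - 1e-12)
              hits_sc <- hits_sc + 1
          }
          if ("f_st" %in% schemes) {
            new_pop_all <- stats::setNames(sample(pop_idx), ids)
            cnts <- amova_counts_for_assignment(prep$per_locus, length(pops),
                                                new_pop_all)
            fp <- amova_f(rowSums(
              amova_sigma_from_counts(prep$per_locus, group_of_pop, cnts),
              na.rm = TRUE))
            if (!is.na(fp["f_st"]) && fp["f_st"] >= f_obs["f_st"] - 1e-12)
              hits_st <- hits_st + 1
          }
        }
        if ("f_sc" %in% schemes) p["f_sc"] <- perm_pvalue(hits_sc, n_perm)
        if ("f_st" %in% schemes) p["f_st"] <- perm_pvalue(hits_st, n_perm)
      }
    }
    n_loci <- ncol(sig)
    if (n_boot_loci > 0 && n_loci > 1) {
      w <- stats::rmultinom(n_boot_loci, n_loci, rep(1 / n_loci, n_loci))
      s0 <- ifelse(is.na(sig), 0, sig)
      sboot <- s0 %*% w
      fb <- apply(sboot, 2, function(s) {
        names(s) <- c("a", "b", "c")
        if (n_groups < 2) s["a"] <- NA_real_
        amova_f(s)
      })
      ci <- apply(fb, 1, stats::quantile, probs = c(0.025, 0.975),
                  na.rm = TRUE)
    }
  })

  structure(list(sigma = sigma, percent = percent, f = f_obs, p = p,
                 ci = ci, ss = ss, df = df, n_perm = n_perm,
                 hierarchy = hierarchy),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result>\n")
  tab <- data.frame(
    level = c("Among groups (F_CT)", "Among pops within groups (F_SC)",
              "Within pops (F_ST)"),
    F = unname(x$f), p = unname(x$p),
    percent_variation = unname(x$percent))
  if (!is.null(x$ci)) {
    tab$ci_low <- x$ci[1, ]; tab$ci_high <- x$ci[2, ]
  }
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}
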