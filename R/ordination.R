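# Isolation by distance, principal coordinates, and likelihood assignment.

#' Mantel test of isolation by distance
#'
#' Pearson correlation between the off-diagonal elements of a genetic and
#' a geographic distance matrix, with significance by row/column
#' permutation (delegated to vegan's Mantel machinery).
#'
#' @param genetic_matrix,geographic_matrix matched square symmetric
#'   matrices (n >= 4).
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return list with `rxy`, `p_value`, `n_perm`.
#' @export
mantel_ibd <- function(genetic_matrix, geographic_matrix, n_perm = 9999,
                       seed = NULL) {
  check_square_symmetric(genetic_matrix, "genetic matrix")
  check_square_symmetric(geographic_matrix, "geographic matrix")
  if (nrow(genetic_matrix) != nrow(geographic_matrix))
    stop("matrices must have matching dimensions")
  if (nrow(genetic_matrix) < 4) stop("need at least 4 populations")
  off <- function(m) m[lower.tri(m)]
  if (stats::sd(off(genetic_matrix)) == 0 ||
      stats::sd(off(geographic_matrix)) == 0)
    stop("constant distance matrix: correlation undefined")
  with_seed(seed, {
    res <- vegan::mantel(stats::as.dist(genetic_matrix),
                         stats::as.dist(geographic_matrix),
                         method = "pearson", permutations = n_perm)
    list(rxy = unname(res$statistic), p_value = res$signif, n_perm = n_perm)
  })
}

#' Principal coordinates analysis of a population distance matrix
#'
#' Gower double-centering and eigendecomposition (classical scaling); axes
#' are ordered by eigenvalue and signed so the largest-magnitude loading
#' on each axis is positive, making output deterministic across platforms.
#'
#' @param distance_matrix symmetric matrix with zero diagonal (for genetic
#'   input, typically linearized F_ST; see [linearized_fst()]).
#' @param eig_tol eigenvalues below `eig_tol * max(eig)` are treated as
#'   null axes.
#' @return list with `coords` (populations x axes), `eigenvalues` (all of
#'   them, possibly negative), `percent` (percent of positive variation
#'   per retained axis).
#' @export
pcoa_ordination <- function(distance_matrix, eig_tol = 1e-9) {
  check_square_symmetric(distance_matrix, "distance matrix")
  if (any(abs(diag(distance_matrix)) > 1e-12))
    stop("distance matrix must have a zero diagonal")
  n <- nrow(distance_matrix)
  d2 <- distance_matrix^2
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% d2 %*% j
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  pos <- e$values > eig_tol * max(abs(e$values), 1e-300)
  if (!any(pos)) {
    coords <- matrix(0, n, 1, dimnames = list(rownames(distance_matrix), "Axis1"))
    return(list(coords = coords, eigenvalues = e$values, percent = 100))
  }
  vec <- e$vectors[, pos, drop = FALSE]
  val <- e$values[pos]
  coords <- vec %*% diag(sqrt(val), nrow = length(val))
  for (a in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, a]))
    if (coords[i, a] < 0) coords[, a] <- -coords[, a]
  }
  dimnames(coords) <- list(rownames(distance_matrix),
                           paste0("Axis", seq_len(ncol(coords))))
  list(coords = coords, eigenvalues = e$values,
       percent = 100 * val / sum(val))
}

#' Frequency-based likelihood assignment to preset founder populations
#'
#' Every individual's diploid genotype is scored against each founder
#' population's allele frequencies (product over loci of Hardy-Weinberg
#' genotype probabilities on a log scale). Individuals belonging to a
#' founder are scored leave-one-out (their own alleles removed from the
#' reference counts). Alleles unseen in a reference pool receive frequency
#' `1 / (2n + 2)`. Each individual is assigned to the founder with the
#' highest log-likelihood (ties to the first founder in the supplied
#' order).
#'
#' @param dataset a diploid `genotype_dataset`.
#' @param founder_pops character vector of founder population labels
#'   (subset of the dataset's populations; each needs >= 5 individuals).
#' @return an object of class `assignment_result`: `individuals`
#'   (log-likelihood per founder plus `assigned`), `proportions`
#'   (population x founder matrix, rows summing to 1).
#' @export
likelihood_assignment <- function(dataset, founder_pops) {
  stopifnot(dataset$variant == "diploid")
  pops <- unique(dataset$samples$population)
  if (!all(founder_pops %in% pops))
    stop("founder populations not in dataset: ",
         paste(setdiff(founder_pops, pops), collapse = ", "))
  for (fp in founder_pops)
    if (sum(dataset$samples$population == fp) < 5)
      stop("founder ", fp, " has fewer than 5 individuals")

  pairs <- lapply(dataset$loci, function(loc) gd_diploid_pairs(dataset, loc))
  names(pairs) <- dataset$loci
  # reference gene-copy counts per founder x locus
  ref <- lapply(founder_pops, function(fp) {
    lapply(pairs, function(pr) {
      sub <- pr[pr$population == fp, ]
      table(c(sub$a1, sub$a2))
    })
  })
  names(ref) <- founder_pops

  geno_ll <- function(cnt, a1, a2) {
    tot <- sum(cnt)
    fl <- 1 / (2 * (tot / 2) + 2)  # unseen-allele frequency floor
    p1 <- cnt[as.character(a1)]; p1 <- if (is.na(p1)) 0 else p1
    p2 <- cnt[as.character(a2)]; p2 <- if (is.na(p2)) 0 else p2
    f1 <- max(p1 / tot, fl); f2 <- max(p2 / tot, fl)
    if (a1 == a2) log(f1^2) else log(2 * f1 * f2)
  }

  ids <- dataset$samples$sample_id
  ll <- matrix(NA_real_, length(ids), length(founder_pops),
               dimnames = list(ids, founder_pops))
  own_pop <- stats::setNames(dataset$samples$population, ids)
  for (id in ids) {
    for (fp in founder_pops) {
      tot_ll <- 0; used <- 0
      for (loc in dataset$loci) {
        pr <- pairs[[loc]]
        row <- pr[pr$sample_id == id, ]
        if (nrow(row) == 0) next
        cnt <- ref[[fp]][[loc]]
        if (own_pop[id] == fp) {
          # leave-one-out: remove the individual's own gene copies
          for (al in c(row$a1, row$a2)) {
            key <- as.character(al)
            if (!is.na(cnt[key])) cnt[key] <- cnt[key] - 1
          }
        }
        if (sum(cnt) < 2) next
        tot_ll <- tot_ll + geno_ll(cnt, row$a1, row$a2)
        used <- used + 1
      }
      ll[id, fp] <- if (used > 0) tot_ll else NA_real_
    }
  }
  assigned <- founder_pops[apply(ll, 1, function(v) {
    v[is.na(v)] <- -Inf
    which.max(v)
  })]
  individuals <- data.frame(sample_id = ids, population = own_pop[ids],
                            ll, assigned = assigned,
                            stringsAsFactors = FALSE, row.names = NULL)
  prop <- t(vapply(pops, function(pop) {
    sel <- individuals$assigned[individuals$population == pop]
    vapply(founder_pops, function(fp) mean(sel == fp), numeric(1))
  }, numeric(length(founder_pops))))
  dimnames(prop) <- list(pops, founder_pops)
  structure(list(individuals = individuals, proportions = prop,
                 founders = founder_pops),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("<assignment_result> founders:", paste(x$founders, collapse = ", "),
      "\n")
  print(round(x$proportions, 3))
  invisible(x)
}
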