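#' Simulate hierarchical allele frequencies
#'
#' Draws global, group and population allele frequencies per locus under a
#' Balding-Nichols style hierarchical model: group frequencies are
#' Dirichlet-distributed around the global vector with concentration
#' `(1 - theta_ct) / theta_ct`, and population frequencies around their
#' group vector with `(1 - theta_sc) / theta_sc`. Each conditional marginal
#' is then Beta with mean p and variance `p (1 - p) theta`, so the theta
#' parameters map directly onto the expected F_CT and F_SC.
#'
#' @param config a [simulation_config()].
#' @return a `truth_record`: list with `loci` (locus table with allele
#'   sizes), `freq_global`, `freq_group`, `freq_pop` (per-locus frequency
#'   vectors/matrices) and `pop_table` (population and site-group labels).
#' @export
simulate_allele_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, "freqs"), {
    n_pops <- sum(config$pops_per_group)
    pop_ids <- sprintf("P%02d", seq_len(n_pops))
    group_ids <- sprintf("G%d", seq_len(config$n_site_groups))
    pop_group <- rep(group_ids, config$pops_per_group)
    loci <- sprintf("L%d", seq_len(config$n_loci))

    k_per_locus <- sample(seq(config$allele_range[1], config$allele_range[2]),
                          config$n_loci, replace = TRUE)
    # Dinucleotide-style ladders in disjoint size windows per locus.
    sizes <- lapply(seq_len(config$n_loci), function(l) {
      as.integer(100 + (l - 1) * 40 + 2 * (seq_len(k_per_locus[l]) - 1))
    })

    draw_children <- function(p, n, theta) {
      if (theta == 0) {
        matrix(p, nrow = n, ncol = length(p), byrow = TRUE)
      } else {
        rdirichlet(n, p * (1 - theta) / theta)
      }
    }

    freq_global <- vector("list", config$n_loci)
    freq_group <- vector("list", config$n_loci)
    freq_pop <- vector("list", config$n_loci)
    for (l in seq_len(config$n_loci)) {
      k <- k_per_locus[l]
      p <- drop(rdirichlet(1, rep(config$global_alpha, k)))
      # Keep loci genuinely polymorphic: no allele may exceed 0.95.
      tries <- 0
      while (max(p) > 0.95 && tries < 50) {
        p <- drop(rdirichlet(1, rep(config$global_alpha, k)))
        tries <- tries + 1
      }
      g <- draw_children(p, config$n_site_groups, config$theta_ct)
      pops <- matrix(NA_real_, n_pops, k)
      for (gi in seq_len(config$n_site_groups)) {
        rows <- which(pop_group == group_ids[gi])
        pops[rows, ] <- draw_children(g[gi, ], length(rows), config$theta_sc)
      }
      names(p) <- as.character(sizes[[l]])
      colnames(g) <- colnames(pops) <- as.character(sizes[[l]])
      rownames(g) <- group_ids
      rownames(pops) <- pop_ids
      freq_global[[l]] <- p
      freq_group[[l]] <- g
      freq_pop[[l]] <- pops
    }
    names(freq_global) <- names(freq_group) <- names(freq_pop) <- loci

    out <- list(
      config = config,
      loci = data.frame(locus = loci, n_alleles = k_per_locus,
                        stringsAsFactors = FALSE),
      allele_sizes = stats::setNames(sizes, loci),
      freq_global = freq_global,
      freq_group = freq_group,
      freq_pop = freq_pop,
      pop_table = data.frame(population = pop_ids, site_group = pop_group,
                             stringsAsFactors = FALSE)
    )
    class(out) <- "truth_record"
    out
  })
}

#' @export
print.truth_record <- function(x, ...) {
  cat("<truth_record>",
      sprintf("  %d populations in %d groups; %d loci (%d-%d alleles)",
              nrow(x$pop_table), length(unique(x$pop_table$site_group)),
              nrow(x$loci), min(x$loci$n_alleles), max(x$loci$n_alleles)),
      sep = "\n")
  if (!is.null(x$colonies))
    cat(sprintf("  %d colonies (%d chimeric)\n", nrow(x$colonies),
                sum(x$colonies$is_chimera)))
  invisible(x)
}
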