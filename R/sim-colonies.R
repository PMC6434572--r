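# Colony-level simulation: random-mating genotypes with an outcrossing
# excess, chimeric fusion, and the winter dieback bottleneck.

# Draw n two-allele genotypes from a frequency vector. With probability
# `avoidance`, an identical second allele is redrawn from the remaining
# spectrum, producing heterozygote excess: E[F_IS] = -v * sum(p^2) / (1 - sum(p^2)).
draw_genotypes <- function(sizes, p, n, avoidance) {
  a1 <- sample(sizes, n, replace = TRUE, prob = p)
  a2 <- sample(sizes, n, replace = TRUE, prob = p)
  if (avoidance > 0) {
    redo <- which(a1 == a2 & stats::runif(n) < avoidance)
    for (i in redo) {
      keep <- sizes != a1[i] & p > 0
      if (any(keep))
        a2[i] <- sample(rep(sizes[keep], 2), 1, prob = rep(p[keep], 2))
    }
  }
  cbind(a1, a2)
}

new_colony_set <- function(colonies, genotypes) {
  structure(list(colonies = colonies, genotypes = genotypes),
            class = "colony_set")
}

#' @export
print.colony_set <- function(x, ...) {
  cat(sprintf("<colony_set> %d colonies, %d populations, season %s, %d chimeric\n",
              nrow(x$colonies), length(unique(x$colonies$population)),
              paste(unique(x$colonies$season), collapse = "/"),
              sum(x$colonies$is_chimera)))
  invisible(x)
}

#' Simulate colony genotypes
#'
#' Each colony receives two alleles per locus drawn from its population's
#' frequency vector under random mating, optionally with an outcrossing
#' (self-avoidance) excess of heterozygotes.
#'
#' @param truth a `truth_record` from [simulate_allele_frequencies()].
#' @param config the [simulation_config()]; defaults to the one stored in
#'   `truth`.
#' @param season label attached to the colonies.
#' @param freq_pop optional per-locus list of population-by-allele frequency
#'   matrices overriding `truth$freq_pop` (used for winter regrowth).
#' @param n_per_pop optional named vector of colony counts per population;
#'   defaults to `config$colonies_per_pop` for every population.
#' @param id_prefix prefix for colony ids.
#' @param seed_label internal RNG stream label.
#' @return a `colony_set`: `colonies` (colony_id, population, site_group,
#'   season, is_chimera) and `genotypes` (colony_id, locus, genome, a1, a2).
#' @export
simulate_colonies <- function(truth, config = truth$config,
                              season = "summer", freq_pop = NULL,
                              n_per_pop = NULL, id_prefix = "S",
                              seed_label = "colonies") {
  stopifnot(inherits(truth, "truth_record"))
  freq_pop <- freq_pop %||% truth$freq_pop
  pops <- rownames(freq_pop[[1]])
  if (is.null(n_per_pop))
    n_per_pop <- stats::setNames(rep(config$colonies_per_pop, length(pops)), pops)
  with_seed(child_seed(config$seed, paste0(seed_label, "-", season)), {
    col_rows <- list(); gen_rows <- list()
    for (pi in seq_along(pops)) {
      pop <- pops[pi]
      n <- n_per_pop[[pop]]
      ids <- sprintf("%s_%s_%03d", id_prefix, pop, seq_len(n))
      sg <- truth$pop_table$site_group[match(pop, truth$pop_table$population)]
      col_rows[[pi]] <- data.frame(
        colony_id = ids, population = pop, site_group = sg, season = season,
        is_chimera = FALSE, stringsAsFactors = FALSE)
      per_locus <- lapply(names(freq_pop), function(loc) {
        sizes <- as.integer(colnames(freq_pop[[loc]]))
        g <- draw_genotypes(sizes, freq_pop[[loc]][pop, ], n, config$avoidance)
        data.frame(colony_id = ids, locus = loc, genome = 1L,
                   a1 = pmin(g[, 1], g[, 2]), a2 = pmax(g[, 1], g[, 2]),
                   stringsAsFactors = FALSE)
      })
      gen_rows[[pi]] <- do.call(rbind, per_locus)
    }
    new_colony_set(do.call(rbind, col_rows), do.call(rbind, gen_rows))
  })
}

#' Turn colonies chimeric by fusing second genotypes
#'
#' Each colony independently becomes chimeric with probability
#' `config$chimera_rate`; the fusion partner genotype is drawn fresh from
#' the same population's allele frequencies (or, with
#' `config$cross_pop_fusion`, from a random population of the same site
#' group). Truth flags are recorded on the colony table.
#'
#' @inheritParams simulate_colonies
#' @param colonies a `colony_set`.
#' @return the `colony_set` with `is_chimera` flags set and genome-2 rows
#'   appended for chimeric colonies.
#' @export
apply_chimerism <- function(colonies, truth, config = truth$config,
                            freq_pop = NULL, seed_label = "chimera") {
  stopifnot(inherits(colonies, "colony_set"))
  freq_pop <- freq_pop %||% truth$freq_pop
  season <- colonies$colonies$season[1] %||% "summer"
  with_seed(child_seed(config$seed, paste0(seed_label, "-", season)), {
    tab <- colonies$colonies
    tab$is_chimera <- stats::runif(nrow(tab)) < config$chimera_rate
    extra <- list()
    if (any(tab$is_chimera)) {
      idx <- which(tab$is_chimera)
      for (i in idx) {
        pop <- tab$population[i]
        if (config$cross_pop_fusion) {
          mates <- truth$pop_table$population[
            truth$pop_table$site_group == tab$site_group[i]]
          pop <- sample(rep(mates, 2), 1)
        }
        rows <- lapply(names(freq_pop), function(loc) {
          sizes <- as.integer(colnames(freq_pop[[loc]]))
          g <- draw_genotypes(sizes, freq_pop[[loc]][pop, ], 1, config$avoidance)
          data.frame(colony_id = tab$colony_id[i], locus = loc, genome = 2L,
                     a1 = min(g), a2 = max(g), stringsAsFactors = FALSE)
        })
        extra[[length(extra) + 1]] <- do.call(rbind, rows)
      }
    }
    new_colony_set(tab, rbind(colonies$genotypes, do.call(rbind, extra)))
  })
}

#' Apply winter dieback to a summer colony set
#'
#' Retains a `dieback_survival` fraction of colonies per population (the
#' bottleneck), then either returns the survivors themselves
#' (`winter_mode = "survivors"`) or draws fresh recruit colonies from the
#' survivors' empirical allele frequencies, optionally perturbed by
#' Balding-Nichols drift of strength `drift_strength`
#' (`winter_mode = "recruits"`). Only populations listed in
#' `config$winter_pops` are resampled.
#'
#' @inheritParams apply_chimerism
#' @param summer a summer `colony_set` (chimeric genome-2 rows, if present,
#'   are ignored when computing survivor frequencies).
#' @return a list: `winter` (a `colony_set`, season "winter"),
#'   `survivor_ids` (colony ids retained by the bottleneck) and
#'   `winter_freq_pop` (frequency pool used for regrowth; `NULL` in
#'   survivors mode).
#' @export
apply_winter_dieback <- function(summer, truth, config = truth$config,
                                 seed_label = "winter") {
  stopifnot(inherits(summer, "colony_set"))
  pops <- truth$pop_table$population[config$winter_pops]
  with_seed(child_seed(config$seed, seed_label), {
    surv <- list()
    for (pop in pops) {
      ids <- summer$colonies$colony_id[summer$colonies$population == pop]
      n_keep <- round(config$dieback_survival * length(ids))
      if (n_keep < 2)
        stop("dieback_survival leaves fewer than 2 colonies in ", pop)
      surv[[pop]] <- sample(ids, n_keep)
    }
    survivor_ids <- unlist(surv, use.names = FALSE)

    if (config$winter_mode == "survivors") {
      keep_col <- summer$colonies[summer$colonies$colony_id %in% survivor_ids, ]
      keep_col$season <- "winter"
      keep_col$colony_id <- sub("^S_", "W_", keep_col$colony_id)
      keep_gen <- summer$genotypes[summer$genotypes$colony_id %in% survivor_ids, ]
      keep_gen$colony_id <- sub("^S_", "W_", keep_gen$colony_id)
      return(list(winter = new_colony_set(keep_col, keep_gen),
                  survivor_ids = survivor_ids, winter_freq_pop = NULL))
    }

    # Recruits mode: empirical survivor frequencies (primary genomes only),
    # optionally drifted, feed a fresh draw of colonies.
    winter_freq <- lapply(names(truth$freq_pop), function(loc) {
      m <- truth$freq_pop[[loc]][pops, , drop = FALSE]
      sizes <- as.integer(colnames(m))
      for (pop in pops) {
        g <- summer$genotypes
        g <- g[g$colony_id %in% surv[[pop]] & g$locus == loc & g$genome == 1L, ]
        cnt <- tabulate(match(c(g$a1, g$a2), sizes), length(sizes))
        p <- if (sum(cnt) > 0) cnt / sum(cnt) else m[pop, ]
        if (config$drift_strength > 0) {
          pos <- p > 0
          d <- config$drift_strength
          p[pos] <- drop(rdirichlet(1, p[pos] * (1 - d) / d))
        }
        m[pop, ] <- p
      }
      m
    })
    names(winter_freq) <- names(truth$freq_pop)
    n_per_pop <- vapply(surv, length, integer(1))
    winter <- simulate_colonies(truth, config, season = "winter",
                                freq_pop = winter_freq,
                                n_per_pop = n_per_pop, id_prefix = "W",
                                seed_label = "winter-colonies")
    list(winter = winter, survivor_ids = survivor_ids,
         winter_freq_pop = winter_freq)
  })
}
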