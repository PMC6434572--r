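# End-to-end orchestration: simulate (or ingest) peaks, call both dataset
# variants, run every analysis for summer and winter, sweep the PLDs, and
# emit a report bundle with a run manifest.

#' Validate pipeline input files
#'
#' Schema checks for every reader: peak-table CSV columns, GenePop dialect
#' (exactly two alleles per cell), polyploid CSV columns, site table and
#' distance-matrix symmetry. Returns diagnostics instead of stopping, so a
#' caller can report all problems at once.
#'
#' @param paths named list; recognised names: `peaks`, `genepop`,
#'   `polyploid`, `sites`, `distances`.
#' @return character vector of diagnostics (empty when all inputs are
#'   clean), with names identifying the offending input.
#' @export
validate_inputs <- function(paths) {
  diags <- character(0)
  note <- function(input, msg) {
    diags[length(diags) + 1] <<- msg
    names(diags)[length(diags)] <<- input
  }
  for (input in names(paths)) {
    path <- paths[[input]]
    if (!file.exists(path)) {
      note(input, paste0("file not found: ", path))
      next
    }
    res <- tryCatch({
      switch(input,
        peaks = {
          df <- utils::read.csv(path, nrows = 50)
          need <- c("sample_id", "population", "locus", "allele_size_bp",
                    "peak_height")
          miss <- setdiff(need, names(df))
          if (length(miss) > 0)
            stop("missing columns: ", paste(miss, collapse = ", "))
          if (any(df$peak_height <= 0)) stop("non-positive peak heights")
          NULL
        },
        genepop = { read_genepop(path); NULL },
        polyploid = { read_polyploid_csv(path); NULL },
        sites = {
          df <- utils::read.csv(path)
          miss <- setdiff(c("site_id", "x", "y"), names(df))
          if (length(miss) > 0)
            stop("missing columns: ", paste(miss, collapse = ", "))
          NULL
        },
        distances = {
          m <- as.matrix(utils::read.csv(path, row.names = 1,
                                         check.names = FALSE))
          check_square_symmetric(m, "distance matrix")
          if (any(abs(diag(m)) > 1e-9)) stop("non-zero diagonal")
          NULL
        },
        stop("unknown input kind"))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) note(input, res)
  }
  diags
}

pipeline_manifest <- function(config, seed, steps, inputs = NULL) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  list(config_hash = unname(tools::md5sum(tf)),
       seed = seed,
       inputs = inputs,
       steps = steps,
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       package_version = as.character(utils::packageVersion("chimerapop")))
}

#' Run the full two-season, two-variant study pipeline
#'
#' Simulates a study (or ingests a peak table), calls the diploid and
#' polyploid dataset variants for both seasons, filters by missingness,
#' and produces: the per-population diversity table, marker screening
#' (HWE, LD with the harmonic-number FDR, null alleles), hierarchical
#' AMOVAs (site hierarchy, summer-vs-winter season hierarchy, and the
#' 12/24-hr dispersal-cluster hierarchies), pairwise F_ST and Jost's D
#' with their Pearson cross-check, Mantel isolation by distance, PCoA
#' coordinates for the four variant-by-season combinations, likelihood
#' assignment to three founder populations, and a run manifest.
#'
#' @param config a [simulation_config()]; its seed drives all randomness.
#' @param peaks optional externally supplied peak table (data frame or CSV
#'   path); when given, the simulation step is skipped and `map` inputs
#'   must be supplied too.
#' @param map optional list with `distances` (matrix) and `velocity`; and
#'   `pop_sites` data frame mapping populations to site ids and
#'   coordinates.
#' @param out_dir optional directory; when given, CSV outputs and the
#'   manifest are written there.
#' @param n_perm permutations for every permutation test.
#' @param n_boot bootstrap replicates (Jost's D, AMOVA loci CIs).
#' @param founders founder populations for assignment; defaults to the
#'   populations of the second site group, falling back to the first
#'   three populations.
#' @param g rarefaction reference size (individuals).
#' @param pld_hours PLD sweep values.
#' @param hwe_mcmc Monte Carlo iterations for exact HWE tests at loci with
#'   more than four alleles.
#' @return a `pipeline_report` list; see details in the package vignette.
#' @export
run_pipeline <- function(config = simulation_config(), peaks = NULL,
                         map = NULL, out_dir = NULL, n_perm = 999,
                         n_boot = 200, founders = NULL, g = 19,
                         pld_hours = c(2, 12, 24, 36), hwe_mcmc = 20000) {
  steps <- character(0)
  stage <- function(name, expr) {
    steps <<- c(steps, name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  if (is.null(peaks)) {
    study <- stage("simulate", simulate_study(config))
    peaks <- study$peaks
    map <- list(distances = study$map$distances,
                velocity = study$map$velocity,
                pop_sites = study$pop_sites)
    truth <- study$truth
  } else if (is.character(peaks)) {
    peaks <- stage("ingest", utils::read.csv(peaks, stringsAsFactors = FALSE))
  }
  if (!"season" %in% names(peaks)) peaks$season <- "summer"
  seasons <- intersect(c("summer", "winter"), unique(peaks$season))

  # --- calling and filtering -------------------------------------------
  datasets <- stage("call", {
    out <- list()
    for (season in seasons) {
      pk <- peaks[peaks$season == season, ]
      for (variant in c("diploid", "polyploid")) {
        d <- call_dataset(pk, variant)
        out[[paste(variant, season, sep = "_")]] <- filter_dataset(d)
      }
    }
    out
  })

  seed_of <- function(label) child_seed(config$seed, label)

  # --- diversity and screening -----------------------------------------
  diversity <- stage("diversity", {
    lapply(stats::setNames(seasons, seasons), function(season) {
      diversity_table(datasets[[paste0("diploid_", season)]],
                      datasets[[paste0("polyploid_", season)]],
                      g = g, n_perm = min(n_perm, 500),
                      seed = seed_of(paste0("fis-", season)))
    })
  })

  screening <- stage("screening", {
    lapply(stats::setNames(seasons, seasons), function(season) {
      dd <- datasets[[paste0("diploid_", season)]]
      ld <- ld_test(dd, n_perm = n_perm, seed = seed_of(paste0("ld-", season)))
      ld_fam <- fdr_correct_by(ld$p_value, k = nrow(ld))
      hwe <- do.call(rbind, lapply(unique(dd$samples$population), function(pop) {
        sub <- gd_filter(dd, populations = pop)
        do.call(rbind, lapply(dd$loci, function(loc) {
          pr <- gd_diploid_pairs(sub, loc)
          res <- hwe_exact_test(pr$a1, pr$a2, n_mcmc = hwe_mcmc,
                                burn_in = ceiling(hwe_mcmc / 10),
                                seed = seed_of(paste(season, pop, loc)))
          data.frame(population = pop, locus = loc, p_value = res$p_value,
                     method = res$method, stringsAsFactors = FALSE)
        }))
      }))
      hwe_fam <- fdr_correct_by(hwe$p_value, k = nrow(hwe))
      nulls <- do.call(rbind, lapply(dd$loci, function(loc) {
        pr <- gd_diploid_pairs(dd, loc)
        res <- null_allele_estimate(pr$a1, pr$a2, n_boot = n_boot,
                                    seed = seed_of(paste("null", season, loc)))
        data.frame(locus = loc, r = res$r, flagged = res$flagged,
                   stringsAsFactors = FALSE)
      }))
      list(ld = ld, ld_family = ld_fam, hwe = hwe, hwe_family = hwe_fam,
           null_alleles = nulls)
    })
  })

  # --- differentiation --------------------------------------------------
  differentiation <- stage("differentiate", {
    out <- list()
    for (season in seasons) {
      dd <- datasets[[paste0("diploid_", season)]]
      fst <- pairwise_fst(dd, n_perm = n_perm,
                          seed = seed_of(paste0("fst-", season)))
      d <- jost_d(dd, n_boot = n_boot, seed = seed_of(paste0("jost-", season)))
      lo <- lower.tri(fst$fst)
      cor_fd <- stats::cor.test(fst$fst[lo], d$d[lo])
      pfst <- polyploid_fst(datasets[[paste0("polyploid_", season)]])
      out[[season]] <- list(fst = fst, jost_d = d,
                            fst_d_pearson = list(r = unname(cor_fd$estimate),
                                                 p = cor_fd$p.value),
                            polyploid_fst = pfst)
    }
    out
  })

  pcoa <- stage("pcoa", {
    out <- list()
    for (season in seasons) {
      out[[paste0("diploid_", season)]] <- pcoa_ordination(
        linearized_fst(differentiation[[season]]$fst$fst))
      out[[paste0("polyploid_", season)]] <- pcoa_ordination(
        linearized_fst(differentiation[[season]]$polyploid_fst$fst))
    }
    out
  })

  # --- hierarchies ------------------------------------------------------
  summer_dip <- datasets[["diploid_summer"]]
  site_hier <- hierarchy_spec(stats::setNames(
    summer_dip$samples$site_group[!duplicated(summer_dip$samples$population)],
    unique(summer_dip$samples$population)))
  amovas <- stage("amova", {
    out <- list(site = amova(summer_dip, site_hier, n_perm = n_perm,
                             n_boot_loci = n_boot,
                             seed = seed_of("amova-site")))
    if ("winter" %in% seasons) {
      winter_dip <- datasets[["diploid_winter"]]
      shared <- intersect(unique(summer_dip$samples$population),
                          unique(winter_dip$samples$population))
      both <- genotype_dataset(
        rbind(gd_filter(summer_dip, populations = shared)$calls,
              gd_filter(winter_dip, populations = shared)$calls),
        rbind(
          transform(gd_filter(summer_dip, populations = shared)$samples,
                    population = paste0(population, "_S")),
          transform(gd_filter(winter_dip, populations = shared)$samples,
                    population = paste0(population, "_W"))),
        "diploid")
      # the calls above still use original ids; remap sample->population
      season_hier <- hierarchy_spec(stats::setNames(
        both$samples$season[!duplicated(both$samples$population)],
        unique(both$samples$population)))
      out$season <- amova(both, season_hier, n_perm = n_perm,
                          n_boot_loci = n_boot,
                          seed = seed_of("amova-season"))
    }
    out
  })

  # --- connectivity -----------------------------------------------------
  connectivity <- NULL
  if (!is.null(map)) {
    connectivity <- stage("connect", {
      parts <- withCallingHandlers(
        pld_sweep(map$distances, map$velocity, pld_hours,
                  sampled_sites = map$pop_sites$site_id),
        warning = function(w) invokeRestart("muffleWarning"))
      singleton <- attr(parts, "all_singleton")
      cluster_amovas <- list()
      for (h in intersect(c(12, 24), pld_hours)) {
        key <- paste0("pld", h)
        if (isTRUE(singleton[[key]])) {
          cluster_amovas[[key]] <- "skipped: all sampled populations are singleton clusters"
          next
        }
        cluster_amovas[[key]] <- tryCatch(
          amova_by_cluster(summer_dip, parts[[key]], map$pop_sites,
                           n_perm = n_perm, n_boot_loci = n_boot,
                           seed = seed_of(paste0("amova-", key))),
          error = function(e) paste("skipped:", conditionMessage(e)))
      }
      list(partitions = parts, cluster_amovas = cluster_amovas,
           all_singleton = singleton,
           coincident_pairs = attr(parts, "coincident_pairs"))
    })
  }

  ibd <- NULL
  if (!is.null(map)) {
    ibd <- stage("ibd", {
      ps <- map$pop_sites
      pops <- intersect(unique(summer_dip$samples$population), ps$population)
      if (length(pops) >= 4) {
        geo <- map$distances[ps$site_id[match(pops, ps$population)],
                             ps$site_id[match(pops, ps$population)]]
        dimnames(geo) <- list(pops, pops)
        gen <- linearized_fst(
          differentiation$summer$fst$fst[pops, pops])
        tryCatch(mantel_ibd(gen, geo / 1000, n_perm = n_perm,
                            seed = seed_of("mantel")),
                 error = function(e) paste("skipped:", conditionMessage(e)))
      } else "skipped: fewer than 4 mapped populations"
    })
  }

  assignment <- stage("assign", {
    pops <- unique(summer_dip$samples$population)
    if (is.null(founders)) {
      sg <- summer_dip$samples$site_group[
        match(pops, summer_dip$samples$population)]
      grp2 <- unique(sg)[min(2, length(unique(sg)))]
      founders <- utils::head(pops[sg == grp2], 3)
      if (length(founders) < 2) founders <- utils::head(pops, 3)
    }
    tryCatch(likelihood_assignment(summer_dip, founders),
             error = function(e) paste("skipped:", conditionMessage(e)))
  })

  comparisons <- stage("compare", {
    out <- list()
    if ("winter" %in% seasons)
      out$summer_vs_winter <- compare_diversity(diversity$summer,
                                                diversity$winter)
    out
  })

  report <- list(
    config = config,
    datasets = datasets,
    diversity = diversity,
    screening = screening,
    differentiation = differentiation,
    pcoa = pcoa,
    amova = amovas,
    connectivity = connectivity,
    ibd = ibd,
    assignment = assignment,
    comparisons = comparisons,
    truth = truth,
    manifest = pipeline_manifest(config, config$seed, steps))
  class(report) <- "pipeline_report"

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n  steps:", paste(x$manifest$steps, collapse = ", "),
      "\n  datasets:", paste(names(x$datasets), collapse = ", "), "\n")
  invisible(x)
}

#' Write a pipeline report bundle to CSV
#'
#' @param report a `pipeline_report`.
#' @param out_dir output directory.
#' @return invisibly, the directory.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (season in names(report$diversity))
    utils::write.csv(report$diversity[[season]],
                     file.path(out_dir, paste0("diversity_", season, ".csv")),
                     row.names = FALSE)
  for (season in names(report$differentiation)) {
    utils::write.csv(report$differentiation[[season]]$fst$fst,
                     file.path(out_dir, paste0("fst_", season, ".csv")))
    utils::write.csv(report$differentiation[[season]]$jost_d$d,
                     file.path(out_dir, paste0("jost_d_", season, ".csv")))
  }
  amova_row <- function(a, label) {
    if (!inherits(a, "amova_result")) return(NULL)
    data.frame(hierarchy = label, statistic = names(a$f), value = unname(a$f),
               p = unname(a$p),
               ci_low = if (is.null(a$ci)) NA else a$ci[1, ],
               ci_high = if (is.null(a$ci)) NA else a$ci[2, ],
               stringsAsFactors = FALSE)
  }
  am <- do.call(rbind, c(
    lapply(names(report$amova), function(nm)
      amova_row(report$amova[[nm]], nm)),
    if (!is.null(report$connectivity))
      lapply(names(report$connectivity$cluster_amovas), function(nm)
        amova_row(report$connectivity$cluster_amovas[[nm]], nm))))
  if (!is.null(am))
    utils::write.csv(am, file.path(out_dir, "amova.csv"), row.names = FALSE)
  for (nm in names(report$pcoa))
    utils::write.csv(report$pcoa[[nm]]$coords,
                     file.path(out_dir, paste0("pcoa_", nm, ".csv")))
  if (inherits(report$assignment, "assignment_result"))
    utils::write.csv(report$assignment$proportions,
                     file.path(out_dir, "assignment_proportions.csv"))
  if (!is.null(report$connectivity)) {
    mem <- do.call(cbind, lapply(report$connectivity$partitions,
                                 function(p) p$membership))
    utils::write.csv(data.frame(site_id = rownames(mem), mem),
                     file.path(out_dir, "clusters.csv"), row.names = FALSE)
  }
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
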