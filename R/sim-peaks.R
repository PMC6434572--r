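# Electropherogram emulation and the study-level simulation wrapper.

#' Simulate peak tables from colony genotypes
#'
#' Every allele copy of the primary genotype emits a lognormal fluorescence
#' contribution around half of `peak_mean`; copies of a fused secondary
#' genotype are scaled by `fusion_fraction`. Contributions to the same
#' fragment size sum into one peak. Whole sample-by-locus records drop out
#' with probability `missing_rate` (amplification failure), and peaks below
#' `detection_floor` are not reported.
#'
#' @param colonies a `colony_set`.
#' @param truth the `truth_record` the colonies came from.
#' @param config a [simulation_config()].
#' @param seed_label internal RNG stream label.
#' @return a peak table: data frame with columns `sample_id`, `population`,
#'   `site_group`, `season`, `locus`, `allele_size_bp`, `peak_height`.
#' @export
simulate_peaks <- function(colonies, truth, config = truth$config,
                           seed_label = "peaks") {
  stopifnot(inherits(colonies, "colony_set"))
  season <- colonies$colonies$season[1] %||% "summer"
  with_seed(child_seed(config$seed, paste0(seed_label, "-", season)), {
    g <- colonies$genotypes
    copies <- data.frame(
      colony_id = rep(g$colony_id, 2),
      locus = rep(g$locus, 2),
      size = c(g$a1, g$a2),
      scale = rep(ifelse(g$genome == 2L, config$fusion_fraction, 1), 2),
      stringsAsFactors = FALSE)
    copies$height <- stats::rlnorm(nrow(copies),
                                   meanlog = log(config$peak_mean / 2),
                                   sdlog = config$peak_sigma) * copies$scale
    agg <- stats::aggregate(height ~ colony_id + locus + size, copies, sum)

    # Amplification failure hits the whole sample x locus record.
    units <- unique(g[, c("colony_id", "locus")])
    fail <- units[stats::runif(nrow(units)) < config$missing_rate, ,
                  drop = FALSE]
    if (nrow(fail) > 0) {
      key <- paste(agg$colony_id, agg$locus)
      agg <- agg[!(key %in% paste(fail$colony_id, fail$locus)), ]
    }
    agg <- agg[agg$height >= config$detection_floor, ]

    meta <- colonies$colonies
    m <- match(agg$colony_id, meta$colony_id)
    out <- data.frame(
      sample_id = agg$colony_id,
      population = meta$population[m],
      site_group = meta$site_group[m],
      season = meta$season[m],
      locus = agg$locus,
      allele_size_bp = as.integer(agg$size),
      peak_height = agg$height,
      stringsAsFactors = FALSE)
    out[order(out$sample_id, out$locus, out$allele_size_bp), ]
  })
}

#' Simulate a planar site map with pairwise distances
#'
#' Sites are placed in a bounded planar region, optionally around supplied
#' cluster centers (emulating farms strung through branched sounds), and
#' pairwise Euclidean distances are returned in meters.
#'
#' @param n_sites number of sites (>= 2).
#' @param extent length-2 numeric, region width and height in meters.
#' @param velocity representative current velocity (m/s), carried along for
#'   connectivity modelling.
#' @param centers optional matrix of cluster centers (one row per center).
#' @param spread standard deviation of site scatter around centers.
#' @param seed integer seed.
#' @return list with `sites` (site_id, x, y), `distances` (symmetric matrix,
#'   zero diagonal) and `velocity`.
#' @export
simulate_site_map <- function(n_sites, extent = c(40000, 30000),
                              velocity = 0.1, centers = NULL,
                              spread = NULL, seed = NULL) {
  stopifnot(n_sites >= 2, length(extent) == 2, all(extent > 0), velocity > 0)
  with_seed(seed, {
    if (is.null(centers)) {
      xy <- cbind(stats::runif(n_sites, 0, extent[1]),
                  stats::runif(n_sites, 0, extent[2]))
    } else {
      spread <- spread %||% (min(extent) / 12)
      pick <- sample(nrow(centers), n_sites, replace = TRUE)
      xy <- centers[pick, , drop = FALSE] +
        matrix(stats::rnorm(2 * n_sites, 0, spread), ncol = 2)
      xy[, 1] <- pmin(pmax(xy[, 1], 0), extent[1])
      xy[, 2] <- pmin(pmax(xy[, 2], 0), extent[2])
    }
    ids <- sprintf("site%03d", seq_len(n_sites))
    d <- as.matrix(stats::dist(xy))
    dimnames(d) <- list(ids, ids)
    list(sites = data.frame(site_id = ids, x = xy[, 1], y = xy[, 2],
                            stringsAsFactors = FALSE),
         distances = d, velocity = velocity)
  })
}

#' Simulate a complete two-season study with known truth
#'
#' Orchestrates the generator: hierarchical allele frequencies, summer
#' colonies with chimerism, winter dieback and regrowth with its own
#' chimerism, electropherogram peaks for both seasons, and a site map whose
#' first sites host the sampled populations (grouped spatially by site
#' group).
#'
#' @param config a [simulation_config()].
#' @param n_sites total number of sites on the map (sampled populations
#'   occupy a subset); defaults to four times the number of populations.
#' @param extent map extent in meters.
#' @param velocity current velocity in m/s.
#' @return list with `truth` (including colony tables and chimera flags),
#'   `peaks` (both seasons), `map` (sites, distances, velocity) and
#'   `pop_sites` (population to site assignment).
#' @export
simulate_study <- function(config = simulation_config(), n_sites = NULL,
                           extent = c(40000, 30000), velocity = 0.1) {
  truth <- simulate_allele_frequencies(config)
  summer <- simulate_colonies(truth, config)
  summer <- apply_chimerism(summer, truth, config)
  wb <- apply_winter_dieback(summer, truth, config)
  winter <- wb$winter
  if (config$winter_mode == "recruits")
    winter <- apply_chimerism(winter, truth, config,
                              freq_pop = wb$winter_freq_pop,
                              seed_label = "chimera-w")
  peaks <- rbind(simulate_peaks(summer, truth, config),
                 simulate_peaks(winter, truth, config))

  n_pops <- nrow(truth$pop_table)
  n_sites <- n_sites %||% (4L * n_pops)
  ng <- config$n_site_groups
  centers <- cbind(extent[1] * (seq_len(ng) - 0.5) / ng,
                   extent[2] * (0.5 + 0.25 * (-1)^seq_len(ng)))
  map <- simulate_site_map(n_sites, extent, velocity, centers = centers,
                           seed = child_seed(config$seed, "sites"))
  # Assign each population a site near its group's center: order sites by
  # distance to the center and hand them out group by group.
  pop_sites <- truth$pop_table
  taken <- character(0)
  site_of <- character(n_pops)
  for (gi in seq_len(ng)) {
    rows <- which(truth$pop_table$site_group == sprintf("G%d", gi))
    d2 <- (map$sites$x - centers[gi, 1])^2 + (map$sites$y - centers[gi, 2])^2
    avail <- map$sites$site_id[order(d2)]
    avail <- setdiff(avail, taken)
    site_of[rows] <- avail[seq_along(rows)]
    taken <- c(taken, site_of[rows])
  }
  pop_sites$site_id <- site_of
  m <- match(site_of, map$sites$site_id)
  pop_sites$x <- map$sites$x[m]
  pop_sites$y <- map$sites$y[m]

  truth$colonies <- rbind(summer$colonies, winter$colonies)
  truth$survivor_ids <- wb$survivor_ids
  truth$winter_freq_pop <- wb$winter_freq_pop
  list(truth = truth, peaks = peaks, map = map, pop_sites = pop_sites,
       colony_sets = list(summer = summer, winter = winter))
}

#' Write the synthetic-study artefacts to CSV
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study_csv <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(peaks = file.path(dir, "peaks.csv"),
             sites = file.path(dir, "sites.csv"),
             distances = file.path(dir, "distances.csv"),
             pop_sites = file.path(dir, "population_sites.csv"))
  utils::write.csv(study$peaks, paths["peaks"], row.names = FALSE)
  utils::write.csv(study$map$sites, paths["sites"], row.names = FALSE)
  utils::write.csv(as.data.frame(study$map$distances), paths["distances"])
  utils::write.csv(study$pop_sites, paths["pop_sites"], row.names = FALSE)
  invisible(paths)
}
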