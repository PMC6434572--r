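#' Simulation configuration for a chimeric-colony microsatellite study
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the sampling design of a multi-sound aquaculture survey: three site
#' groups holding 9, 5 and 1 populations, thirty colonies sampled per
#' population, eight polymorphic loci with 3-13 alleles each, weak
#' hierarchical structure, strong outcrossing (negative F_IS), roughly a
#' third of colonies chimeric, and a winter resampling of six populations
#' after seasonal dieback.
#'
#' @param n_site_groups number of site groups (regions).
#' @param pops_per_group integer vector, populations per site group.
#' @param colonies_per_pop colonies sampled per population.
#' @param n_loci number of microsatellite loci.
#' @param allele_range length-2 integer range for the number of alleles per
#'   locus (inclusive).
#' @param global_alpha symmetric Dirichlet concentration for global allele
#'   frequencies; smaller values give more skewed spectra with rare alleles.
#' @param theta_ct among-group divergence in `[0, 1)` (Balding-Nichols
#'   style); maps directly onto the expected F_CT.
#' @param theta_sc among-population-within-group divergence in `[0, 1)`;
#'   maps onto the expected F_SC.
#' @param avoidance probability that a selfed (identical) second allele is
#'   redrawn, producing the heterozygote excess typical of obligate
#'   outcrossers; 0 gives Hardy-Weinberg proportions.
#' @param chimera_rate per-colony probability of carrying a fused second
#'   genotype.
#' @param fusion_fraction relative tissue contribution of the second
#'   genotype in `(0, 1]`; scales its peak heights.
#' @param cross_pop_fusion if `TRUE` the fusion partner may come from any
#'   population in the same site group; default is fusion within the
#'   population, reflecting intra-site sampling.
#' @param dieback_survival fraction of colonies surviving the winter
#'   bottleneck.
#' @param drift_strength Balding-Nichols theta applied to survivor allele
#'   frequencies before winter regrowth; 0 disables drift.
#' @param winter_mode `"recruits"` draws fresh colonies from the (possibly
#'   drifted) survivor frequency pool; `"survivors"` keeps the surviving
#'   summer colonies themselves.
#' @param winter_pops populations resampled in winter, as indices into the
#'   population list; default: up to six populations of the largest group.
#' @param missing_rate per sample-by-locus amplification failure rate.
#' @param peak_mean expected total fluorescence of a homozygous peak; each
#'   allele copy contributes about half of this.
#' @param peak_sigma lognormal sdlog of per-copy peak height noise.
#' @param detection_floor minimum height (fluorescence units) for a peak to
#'   be reported at all.
#' @param seed integer seed; fully determines the generated study.
#' @return an object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(n_site_groups = 3,
                              pops_per_group = c(9, 5, 1),
                              colonies_per_pop = 30,
                              n_loci = 8,
                              allele_range = c(3, 13),
                              global_alpha = 0.3,
                              theta_ct = 0.015,
                              theta_sc = 0.035,
                              avoidance = 0.3,
                              chimera_rate = 0.35,
                              fusion_fraction = 1,
                              cross_pop_fusion = FALSE,
                              dieback_survival = 0.8,
                              drift_strength = 0.03,
                              winter_mode = c("recruits", "survivors"),
                              winter_pops = NULL,
                              missing_rate = 0.02,
                              peak_mean = 1000,
                              peak_sigma = 0.25,
                              detection_floor = 100,
                              seed = 1L) {
  winter_mode <- match.arg(winter_mode)
  pops_per_group <- as.integer(pops_per_group)
  if (length(pops_per_group) != n_site_groups)
    stop("pops_per_group must have length n_site_groups")
  if (any(pops_per_group < 1)) stop("each site group needs >= 1 population")
  stopifnot(colonies_per_pop >= 2, n_loci >= 1)
  allele_range <- as.integer(allele_range)
  if (length(allele_range) != 2 || allele_range[1] < 2 ||
      allele_range[2] < allele_range[1])
    stop("allele_range must be an increasing pair with minimum >= 2 (loci must be polymorphic)")
  for (nm in c("theta_ct", "theta_sc", "drift_strength")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v >= 1)
      stop(nm, " must lie in [0, 1)")
  }
  for (nm in c("avoidance", "chimera_rate", "dieback_survival",
               "missing_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1) stop(nm, " must lie in [0, 1]")
  }
  if (fusion_fraction <= 0 || fusion_fraction > 1)
    stop("fusion_fraction must lie in (0, 1]")
  stopifnot(peak_mean > 0, peak_sigma >= 0, detection_floor >= 0)

  n_pops <- sum(pops_per_group)
  if (is.null(winter_pops)) {
    g <- which.max(pops_per_group)
    first <- if (g == 1) 0L else sum(pops_per_group[seq_len(g - 1)])
    winter_pops <- first + seq_len(min(6L, pops_per_group[g]))
  }
  winter_pops <- as.integer(winter_pops)
  if (any(winter_pops < 1 | winter_pops > n_pops))
    stop("winter_pops out of range")

  cfg <- list(
    n_site_groups = as.integer(n_site_groups),
    pops_per_group = pops_per_group,
    colonies_per_pop = as.integer(colonies_per_pop),
    n_loci = as.integer(n_loci),
    allele_range = allele_range,
    global_alpha = global_alpha,
    theta_ct = theta_ct,
    theta_sc = theta_sc,
    avoidance = avoidance,
    chimera_rate = chimera_rate,
    fusion_fraction = fusion_fraction,
    cross_pop_fusion = cross_pop_fusion,
    dieback_survival = dieback_survival,
    drift_strength = drift_strength,
    winter_mode = winter_mode,
    winter_pops = winter_pops,
    missing_rate = missing_rate,
    peak_mean = peak_mean,
    peak_sigma = peak_sigma,
    detection_floor = detection_floor,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>",
      sprintf("  %d site groups, pops per group: %s, %d colonies/pop",
              x$n_site_groups, paste(x$pops_per_group, collapse = "/"),
              x$colonies_per_pop),
      sprintf("  %d loci, %d-%d alleles; theta_ct %.3f, theta_sc %.3f",
              x$n_loci, x$allele_range[1], x$allele_range[2],
              x$theta_ct, x$theta_sc),
      sprintf("  chimera_rate %.2f (fusion %.2f), avoidance %.2f",
              x$chimera_rate, x$fusion_fraction, x$avoidance),
      sprintf("  winter: survival %.2f, drift %.3f, mode %s, %d pops",
              x$dieback_survival, x$drift_strength, x$winter_mode,
              length(x$winter_pops)),
      sprintf("  seed %s", x$seed %||% "<none>"),
      sep = "\n")
  invisible(x)
}

# Read a simulation config from YAML; unknown keys are rejected so typos
# fail loudly.
#' Read a simulation config from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [simulation_config()].
#' @return a `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(simulation_config, vals)
}
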