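# Dispersal connectivity: threshold graphs over pelagic larval duration
# (PLD), their connected-component cluster partitions, and
# cluster-stratified AMOVA.

#' Build a PLD connectivity graph over sites
#'
#' Two sites are connected when a larva can cover the distance between
#' them within one PLD at the modelled current velocity:
#' `distance <= velocity * pld_hours * 3600`. Alternatively a pairwise
#' travel-time matrix (hours) may be supplied, in which case the edge
#' criterion is `travel_time <= pld_hours`; asymmetric travel times are
#' treated as connected when either direction meets the criterion (weak
#' connectivity).
#'
#' @param distances symmetric site distance matrix in meters (ignored when
#'   `travel_time` is given).
#' @param velocity scalar current velocity in m/s.
#' @param pld_hours pelagic larval duration in hours.
#' @param travel_time optional pairwise travel-time matrix in hours.
#' @return an object of class `connectivity_graph`: `adjacency` (logical,
#'   symmetric, `TRUE` diagonal), `pld_hours`, `velocity`, `reach_m`.
#' @export
build_connectivity <- function(distances = NULL, velocity = NULL, pld_hours,
                               travel_time = NULL) {
  stopifnot(pld_hours > 0)
  if (is.null(travel_time)) {
    if (is.null(distances) || is.null(velocity))
      stop("supply distances + velocity, or a travel_time matrix")
    if (velocity <= 0) stop("velocity must be positive")
    if (any(distances < 0)) stop("distances must be non-negative")
    check_square_symmetric(distances, "distance matrix")
    reach <- velocity * pld_hours * 3600
    adj <- distances <= reach
  } else {
    if (any(travel_time < 0)) stop("travel times must be non-negative")
    adj <- travel_time <= pld_hours
    adj <- adj | t(adj)  # weak connectivity for asymmetric currents
    reach <- NA_real_
  }
  diag(adj) <- TRUE
  structure(list(adjacency = adj, pld_hours = pld_hours,
                 velocity = velocity %||% NA_real_, reach_m = reach),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("<connectivity_graph> %d sites, PLD %g hr, reach %s m, %d edges\n",
              nrow(x$adjacency), x$pld_hours,
              format(x$reach_m, big.mark = ","),
              (sum(x$adjacency) - nrow(x$adjacency)) / 2))
  invisible(x)
}

#' Cluster partition from a connectivity graph
#'
#' Connected components of the adjacency, with cluster ids assigned
#' deterministically in order of each component's smallest member site
#' index.
#'
#' @param graph a `connectivity_graph`.
#' @return an object of class `cluster_partition`: `membership` (named
#'   integer vector site -> cluster id), `n_clusters`, `pld_hours`.
#' @export
connectivity_clusters <- function(graph) {
  stopifnot(inherits(graph, "connectivity_graph"))
  g <- igraph::graph_from_adjacency_matrix(graph$adjacency,
                                           mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  first <- tapply(seq_along(comp), comp, min)
  relabel <- match(comp, as.integer(names(sort(first))))
  names(relabel) <- rownames(graph$adjacency)
  structure(list(membership = relabel, n_clusters = max(relabel),
                 pld_hours = graph$pld_hours),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("<cluster_partition> PLD %g hr: %d clusters over %d sites\n",
              x$pld_hours, x$n_clusters, length(x$membership)))
  invisible(x)
}

#' Cluster partitions across the PLD sweep
#'
#' Builds the connectivity graph and its cluster partition for each PLD,
#' and raises the two situations that block or duplicate downstream
#' AMOVAs: a partition placing every sampled population in its own cluster
#' (AMOVA impossible: each population is a unique cluster), and two PLDs
#' whose partitions coincide on the sampled populations (one model
#' suffices).
#'
#' @param distances symmetric distance matrix in meters.
#' @param velocity scalar current velocity in m/s.
#' @param pld_hours PLDs swept, in hours.
#' @param sampled_sites optional site ids hosting sampled populations;
#'   warnings are evaluated on these (all sites if omitted).
#' @return list of `cluster_partition`s (named by PLD) with attributes
#'   `all_singleton` (logical per PLD) and `coincident_pairs` (data frame
#'   of PLD pairs agreeing on sampled sites).
#' @export
pld_sweep <- function(distances, velocity, pld_hours = c(2, 12, 24, 36),
                      sampled_sites = NULL) {
  parts <- lapply(pld_hours, function(h)
    connectivity_clusters(build_connectivity(distances, velocity, h)))
  names(parts) <- paste0("pld", pld_hours)
  sampled_sites <- sampled_sites %||% rownames(distances)
  singleton <- vapply(parts, function(p) {
    m <- p$membership[sampled_sites]
    length(unique(m)) == length(m)
  }, logical(1))
  for (h in which(singleton))
    warning("PLD ", pld_hours[h], " hr: every sampled population is its ",
            "own cluster; cluster-stratified AMOVA is not possible",
            call. = FALSE)
  coincident <- list()
  if (length(parts) > 1) {
    for (i in seq_len(length(parts) - 1)) for (j in (i + 1):length(parts)) {
      mi <- parts[[i]]$membership[sampled_sites]
      mj <- parts[[j]]$membership[sampled_sites]
      if (length(unique(paste(mi, mj))) == length(unique(mi)) &&
          length(unique(mi)) == length(unique(mj))) {
        coincident[[length(coincident) + 1]] <-
          data.frame(pld_a = pld_hours[i], pld_b = pld_hours[j])
        warning("PLD ", pld_hours[i], " hr and ", pld_hours[j],
                " hr partitions coincide on the sampled populations",
                call. = FALSE)
      }
    }
  }
  attr(parts, "all_singleton") <- singleton
  attr(parts, "coincident_pairs") <- do.call(rbind, coincident)
  parts
}

#' AMOVA stratified by dispersal cluster
#'
#' Maps each sampled population to the cluster of its site and delegates
#' to [amova()] with the cluster partition as the grouping hierarchy.
#'
#' @param dataset a diploid `genotype_dataset`.
#' @param partition a `cluster_partition`.
#' @param pop_sites data frame mapping `population` to `site_id`.
#' @param ... passed to [amova()] (`n_perm`, `n_boot_loci`, `seed`).
#' @return an `amova_result`.
#' @export
amova_by_cluster <- function(dataset, partition, pop_sites, ...) {
  stopifnot(inherits(partition, "cluster_partition"),
            all(c("population", "site_id") %in% names(pop_sites)))
  pops <- unique(dataset$samples$population)
  m <- match(pops, pop_sites$population)
  if (anyNA(m)) stop("populations without a site: ",
                     paste(pops[is.na(m)], collapse = ", "))
  cl <- partition$membership[pop_sites$site_id[m]]
  if (anyNA(cl)) stop("sites missing from the cluster partition")
  if (length(unique(cl)) < 2)
    stop("only one usable cluster: cluster-stratified AMOVA undefined")
  hier <- hierarchy_spec(stats::setNames(paste0("cluster", cl), pops))
  amova(dataset, hier, ...)
}
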