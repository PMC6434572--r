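# Fixture builders shared across test files.

# Build a diploid genotype_dataset from a named list of n x (2*L) integer
# matrices (one per population; columns a1,a2 per locus).
make_diploid <- function(pop_genotypes, loci = NULL,
                         site_group = NULL, season = "summer") {
  n_loci <- ncol(pop_genotypes[[1]]) / 2
  loci <- loci %||% sprintf("L%d", seq_len(n_loci))
  calls <- list(); samples <- list()
  for (pop in names(pop_genotypes)) {
    m <- pop_genotypes[[pop]]
    ids <- sprintf("%s_i%02d", pop, seq_len(nrow(m)))
    samples[[pop]] <- data.frame(
      sample_id = ids, population = pop,
      site_group = if (is.null(site_group)) pop else site_group[[pop]],
      season = season, stringsAsFactors = FALSE)
    for (l in seq_len(n_loci)) {
      a1 <- m[, 2 * l - 1]; a2 <- m[, 2 * l]
      ok <- !is.na(a1) & !is.na(a2)
      if (!any(ok)) next
      calls[[length(calls) + 1]] <- data.frame(
        sample_id = rep(ids[ok], 2), locus = loci[l],
        allele = c(pmin(a1[ok], a2[ok]), pmax(a1[ok], a2[ok])),
        weight = 0.5, stringsAsFactors = FALSE)
    }
  }
  genotype_dataset(do.call(rbind, calls), do.call(rbind, samples),
                   "diploid", loci = loci)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Simulate a clean one-group diploid dataset straight from the generator
# (bypassing peaks) -- used where calling noise is irrelevant.
sim_diploid_direct <- function(cfg) {
  tr <- simulate_allele_frequencies(cfg)
  col <- simulate_colonies(tr, cfg)
  g <- col$genotypes
  samples <- col$colonies
  samples$sample_id <- samples$colony_id
  genotype_dataset(
    data.frame(sample_id = rep(g$colony_id, 2), locus = rep(g$locus, 2),
               allele = c(g$a1, g$a2), weight = 0.5,
               stringsAsFactors = FALSE),
    samples[, c("sample_id", "population", "site_group", "season")],
    "diploid")
}

# A small complete peak table with known calls.
toy_peaks <- function() {
  data.frame(
    sample_id = rep(c("s1", "s2"), each = 4),
    population = "P1", site_group = "G1", season = "summer",
    locus = rep(c("L1", "L1", "L2", "L2"), 2),
    allele_size_bp = c(180L, 184L, 220L, 224L, 180L, 188L, 220L, 226L),
    peak_height = c(1000, 900, 800, 700, 950, 850, 820, 640),
    stringsAsFactors = FALSE)
}
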