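# The synthetic-data generator: determinism, frequency conservation, the
# Balding-Nichols variance mapping, chimerism, dieback and the site map.

test_that("config validation rejects degenerate parameter values", {
  expect_error(simulation_config(theta_sc = 1), "theta_sc")
  expect_error(simulation_config(allele_range = c(1, 5)), "polymorphic")
  expect_error(simulation_config(fusion_fraction = 0), "fusion_fraction")
  expect_error(simulation_config(pops_per_group = c(2, 2)), "length")
})

test_that("identical seeds give identical studies; frequencies sum to 1", {
  cfg <- simulation_config(n_site_groups = 2, pops_per_group = c(2, 2),
                           colonies_per_pop = 8, n_loci = 3, seed = 42)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(s1$truth$freq_pop, s2$truth$freq_pop)
  for (f in s1$truth$freq_pop)
    expect_true(all(abs(rowSums(f) - 1) < 1e-9))
  expect_true(all(abs(sapply(s1$truth$freq_global, sum) - 1) < 1e-9))
})

test_that("zero theta collapses every population onto the global vector", {
  cfg <- simulation_config(n_site_groups = 2, pops_per_group = c(3, 2),
                           n_loci = 4, theta_ct = 0, theta_sc = 0, seed = 5)
  tr <- simulate_allele_frequencies(cfg)
  for (loc in names(tr$freq_pop)) {
    expected <- matrix(tr$freq_global[[loc]], nrow(tr$freq_pop[[loc]]),
                       length(tr$freq_global[[loc]]), byrow = TRUE)
    expect_equal(unname(tr$freq_pop[[loc]]), unname(expected))
  }
})

test_that("Balding-Nichols marginal variance is p(1-p)*theta", {
  # two alleles at (0.5, 0.5), theta = 0.5 -> Beta variance 0.125
  set.seed(1)
  draws <- chimerapop:::rdirichlet(20000, c(0.5, 0.5) * (1 - 0.5) / 0.5)
  expect_equal(stats::var(draws[, 1]), 0.125, tolerance = 0.02)
})

test_that("generating theta_sc is recovered by multi-locus F_ST", {
  # the design-size parameter-recovery property (theta_sc = 0.05,
  # 8 pops x 30 diploids x 8 loci, averaged over seeds)
  est <- vapply(1:8, function(s) {
    cfg <- simulation_config(n_site_groups = 1, pops_per_group = 8,
                             colonies_per_pop = 30, n_loci = 8,
                             theta_ct = 0, theta_sc = 0.05, avoidance = 0,
                             chimera_rate = 0, missing_rate = 0, seed = s)
    dd <- sim_diploid_direct(cfg)
    chimerapop:::wc_theta(
      chimerapop:::gd_locus_structure(dd),
      stats::setNames(dd$samples$population, dd$samples$sample_id))
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.05), 0.02)
})

test_that("avoidance produces the intended heterozygote excess", {
  fis <- vapply(1:6, function(s) {
    cfg <- simulation_config(n_site_groups = 1, pops_per_group = 2,
                             colonies_per_pop = 30, n_loci = 8,
                             theta_ct = 0, theta_sc = 0.02,
                             chimera_rate = 0, missing_rate = 0, seed = s)
    dd <- sim_diploid_direct(cfg)
    mean(inbreeding_coefficient(dd, n_perm = 0)$fis, na.rm = TRUE)
  }, numeric(1))
  # default avoidance lands inside the observed field range of F_IS
  expect_gt(mean(fis), -0.36)
  expect_lt(mean(fis), -0.04)
  # avoidance off: Hardy-Weinberg proportions, F_IS near zero
  fis0 <- vapply(1:6, function(s) {
    cfg <- simulation_config(n_site_groups = 1, pops_per_group = 2,
                             colonies_per_pop = 30, n_loci = 8,
                             theta_ct = 0, theta_sc = 0.02, avoidance = 0,
                             chimera_rate = 0, missing_rate = 0, seed = s)
    dd <- sim_diploid_direct(cfg)
    mean(inbreeding_coefficient(dd, n_perm = 0)$fis, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(fis0)), 0.05)
})

test_that("chimerism flags follow the configured rate", {
  base <- function(rate, seed) {
    cfg <- simulation_config(n_site_groups = 1, pops_per_group = 1,
                             colonies_per_pop = 30, n_loci = 4,
                             chimera_rate = rate, missing_rate = 0,
                             seed = seed)
    tr <- simulate_allele_frequencies(cfg)
    col <- apply_chimerism(simulate_colonies(tr, cfg), tr, cfg)
    col
  }
  none <- base(0, 1)
  expect_false(any(none$colonies$is_chimera))
  expect_true(all(none$genotypes$genome == 1L))
  all_ch <- base(1, 2)
  expect_true(all(all_ch$colonies$is_chimera))
  # realised count within the central 99% binomial interval at rate 0.35
  counts <- vapply(1:20, function(s) sum(base(0.35, s)$colonies$is_chimera),
                   numeric(1))
  bounds <- qbinom(c(0.005, 0.995), 30, 0.35)
  expect_true(mean(counts >= bounds[1] & counts <= bounds[2]) >= 0.9)
})

test_that("fixed allele gives homozygous colonies; secondary flag bookkeeping", {
  cfg <- simulation_config(n_site_groups = 1, pops_per_group = 1,
                           colonies_per_pop = 10, n_loci = 1,
                           allele_range = c(2, 2), theta_ct = 0,
                           theta_sc = 0, chimera_rate = 0, seed = 3)
  tr <- simulate_allele_frequencies(cfg)
  tr$freq_pop[[1]][] <- c(1, 0)  # degenerate: allele 1 fixed
  col <- simulate_colonies(tr, cfg)
  expect_true(all(col$genotypes$a1 == col$genotypes$a2))
})

test_that("secondary peaks vanish below the calling threshold at low fusion", {
  cfg <- simulation_config(n_site_groups = 1, pops_per_group = 1,
                           colonies_per_pop = 40, n_loci = 6,
                           chimera_rate = 1, fusion_fraction = 0.1,
                           missing_rate = 0, seed = 9)
  tr <- simulate_allele_frequencies(cfg)
  col <- apply_chimerism(simulate_colonies(tr, cfg), tr, cfg)
  pk <- simulate_peaks(col, tr, cfg)
  poly <- call_dataset(pk, "polyploid")
  # secondary-only alleles per colony x locus that survived into the call
  g <- col$genotypes
  surv <- 0; tot <- 0
  for (id in unique(g$colony_id)) for (loc in unique(g$locus)) {
    prim <- g[g$colony_id == id & g$locus == loc & g$genome == 1, ]
    sec <- g[g$colony_id == id & g$locus == loc & g$genome == 2, ]
    extra <- setdiff(c(sec$a1, sec$a2), c(prim$a1, prim$a2))
    if (length(extra) == 0) next
    tot <- tot + 1
    called <- poly$calls$allele[poly$calls$sample_id == id &
                                  poly$calls$locus == loc]
    if (any(extra %in% called)) surv <- surv + 1
  }
  expect_gt(tot, 20)
  expect_lt(surv / tot, 0.5)
})

test_that("winter dieback: identity case, rare-allele loss, and guards", {
  cfg <- simulation_config(n_site_groups = 1, pops_per_group = 2,
                           colonies_per_pop = 20, n_loci = 4,
                           chimera_rate = 0, missing_rate = 0,
                           dieback_survival = 1, drift_strength = 0,
                           winter_mode = "survivors",
                           winter_pops = 1:2, seed = 4)
  tr <- simulate_allele_frequencies(cfg)
  summer <- simulate_colonies(tr, cfg)
  wb <- apply_winter_dieback(summer, tr, cfg)
  # survival 1 + no drift in survivors mode: the same colonies come back
  expect_equal(nrow(wb$winter$colonies), nrow(summer$colonies))
  expect_equal(sort(sub("^W_", "S_", wb$winter$colonies$colony_id)),
               sort(summer$colonies$colony_id))

  expect_error({
    cfg_bad <- simulation_config(n_site_groups = 1, pops_per_group = 1,
                                 colonies_per_pop = 4,
                                 dieback_survival = 0.1, winter_pops = 1,
                                 seed = 1)
    tr2 <- simulate_allele_frequencies(cfg_bad)
    apply_winter_dieback(simulate_colonies(tr2, cfg_bad), tr2, cfg_bad)
  }, "fewer than 2")

  # rare alleles are lost at a higher rate than common alleles under a
  # strong bottleneck (sampling without replacement)
  rare_lost <- 0; rare_tot <- 0; common_lost <- 0; common_tot <- 0
  for (s in 1:40) {
    cfg3 <- simulation_config(n_site_groups = 1, pops_per_group = 1,
                              colonies_per_pop = 30, n_loci = 4,
                              chimera_rate = 0, missing_rate = 0,
                              dieback_survival = 0.3,
                              winter_mode = "survivors", winter_pops = 1,
                              seed = s)
    tr3 <- simulate_allele_frequencies(cfg3)
    summer3 <- simulate_colonies(tr3, cfg3)
    wb3 <- apply_winter_dieback(summer3, tr3, cfg3)
    for (loc in unique(summer3$genotypes$locus)) {
      gs <- summer3$genotypes[summer3$genotypes$locus == loc, ]
      gw <- wb3$winter$genotypes[wb3$winter$genotypes$locus == loc, ]
      tab <- table(c(gs$a1, gs$a2))
      freq <- tab / sum(tab)
      for (al in names(tab)) {
        present <- al %in% c(gw$a1, gw$a2)
        if (freq[al] <= 0.05) {
          rare_tot <- rare_tot + 1
          if (!present) rare_lost <- rare_lost + 1
        } else if (freq[al] >= 0.2) {
          common_tot <- common_tot + 1
          if (!present) common_lost <- common_lost + 1
        }
      }
    }
  }
  expect_gt(rare_lost / rare_tot, common_lost / max(common_tot, 1) + 0.05)
})

test_that("site maps have exact Euclidean geometry", {
  map <- simulate_site_map(5, seed = 1)
  # distances recomputed by hand
  d <- map$distances
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  i <- 2; j <- 4
  expect_equal(d[i, j],
               sqrt((map$sites$x[i] - map$sites$x[j])^2 +
                      (map$sites$y[i] - map$sites$y[j])^2))
  # 2 sites at (0,0) and (3000,4000): distance 5000
  m <- simulate_site_map(2, seed = 1)
  m$sites$x <- c(0, 3000); m$sites$y <- c(0, 4000)
  d2 <- as.matrix(stats::dist(m$sites[, c("x", "y")]))
  expect_equal(unname(d2[1, 2]), 5000)
  # collinear equally spaced sites give a Toeplitz matrix
  xy <- cbind(seq(0, 4000, by = 1000), 0)
  dt <- as.matrix(stats::dist(xy))
  for (k in 0:3)
    expect_true(all(abs(dt[cbind(1:(5 - k), (1 + k):5)] - 1000 * k) < 1e-9))
  expect_error(simulate_site_map(1), "n_sites")
})
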