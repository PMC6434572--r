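# Pairwise F_ST, Jost's D, AMOVA, Mantel, PCoA, assignment, and the
# variant comparison.

two_pop_fixture <- function(seed = 1, theta = 0.1, n = 20, loci = 5) {
  cfg <- simulation_config(n_site_groups = 1, pops_per_group = 2,
                           colonies_per_pop = n, n_loci = loci,
                           theta_ct = 0, theta_sc = theta, avoidance = 0,
                           chimera_rate = 0, missing_rate = 0, seed = seed)
  sim_diploid_direct(cfg)
}

test_that("pairwise F_ST: identical pools near 0, fixed difference = 1, oracle", {
  # identical frequency pools
  ds0 <- two_pop_fixture(seed = 2, theta = 0, n = 60, loci = 6)
  f0 <- pairwise_fst(ds0, n_perm = 0)
  expect_lt(abs(f0$fst[1, 2]), 0.03)
  expect_equal(f0$fst, t(f0$fst))
  expect_true(all(diag(f0$fst) == 0))

  # fixed for different alleles
  fixA <- matrix(rep(c(1L, 1L), 10), ncol = 2, byrow = TRUE)
  fixB <- matrix(rep(c(2L, 2L), 10), ncol = 2, byrow = TRUE)
  dsf <- make_diploid(list(A = fixA, B = fixB))
  expect_equal(pairwise_fst(dsf, n_perm = 49, seed = 1)$fst[1, 2], 1)

  # 2-pop, 1-locus, 6-individual toy matches the scalar-loop oracle
  gA <- matrix(c(1L, 1L, 1L, 2L, 2L, 2L), ncol = 2, byrow = TRUE)
  gB <- matrix(c(2L, 3L, 3L, 3L, 1L, 3L), ncol = 2, byrow = TRUE)
  ds <- make_diploid(list(A = gA, B = gB))
  f <- pairwise_fst(ds, n_perm = 0)$fst[1, 2]
  pop <- rep(c("A", "B"), each = 3)
  a1 <- c(gA[, 1], gB[, 1]); a2 <- c(gA[, 2], gB[, 2])
  expect_equal(f, bf_wc_theta(a1, a2, pop), tolerance = 1e-10)

  # monomorphic pair: 0 with p = 1
  mono <- make_diploid(list(A = fixA, B = fixA))
  fm <- pairwise_fst(mono, n_perm = 49, seed = 1)
  expect_equal(fm$fst[1, 2], 0)
  expect_equal(fm$p[1, 2], 1)

  # permutation p is small for genuinely differentiated pools
  dsd <- two_pop_fixture(seed = 3, theta = 0.2, n = 30, loci = 6)
  fd <- pairwise_fst(dsd, n_perm = 199, seed = 9)
  expect_lt(fd$p[1, 2], 0.05)
})

test_that("Jost's D: identical pools near 0, disjoint fixation = 1", {
  ds0 <- two_pop_fixture(seed = 4, theta = 0, n = 60, loci = 6)
  d0 <- jost_d(ds0, n_boot = 0)
  expect_lt(abs(d0$d[1, 2]), 0.05)

  fixA <- matrix(rep(c(1L, 1L), 12), ncol = 2, byrow = TRUE)
  fixB <- matrix(rep(c(2L, 2L), 12), ncol = 2, byrow = TRUE)
  dsf <- make_diploid(list(A = fixA, B = fixB))
  expect_equal(jost_d(dsf, n_boot = 0)$d[1, 2], 1, tolerance = 1e-12)
})

test_that("F_ST and Jost's D matrices correlate strongly under structure", {
  cfg <- simulation_config(n_site_groups = 1, pops_per_group = 6,
                           colonies_per_pop = 25, n_loci = 8,
                           theta_ct = 0, theta_sc = 0.08, avoidance = 0,
                           chimera_rate = 0, missing_rate = 0, seed = 17)
  ds <- sim_diploid_direct(cfg)
  f <- pairwise_fst(ds, n_perm = 0)
  d <- jost_d(ds, n_boot = 0)
  lo <- lower.tri(f$fst)
  expect_gt(stats::cor(f$fst[lo], d$d[lo]), 0.9)
})

test_that("AMOVA equals the explicit pairwise-distance oracle on toys", {
  set.seed(5)
  # 2 groups x 2 pops x 4 individuals, 1 locus
  pops <- list(
    A1 = matrix(sample(1:3, 8, TRUE), ncol = 2),
    A2 = matrix(sample(1:3, 8, TRUE), ncol = 2),
    B1 = matrix(sample(2:4, 8, TRUE), ncol = 2),
    B2 = matrix(sample(2:4, 8, TRUE), ncol = 2))
  ds <- make_diploid(pops)
  hier <- hierarchy_spec(c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
  am <- amova(ds, hier, n_perm = 0, n_boot_loci = 0)
  copies <- do.call(rbind, lapply(names(pops), function(p)
    data.frame(allele = as.vector(pops[[p]]), pop = p,
               group = substr(p, 1, 1))))
  oracle <- bf_amova(copies)
  expect_equal(unname(am$sigma), unname(oracle), tolerance = 1e-8)
  expect_equal(sum(am$percent), 100, tolerance = 1e-8)

  # multi-locus: components sum per locus; check against per-locus oracles
  pops2 <- lapply(pops, function(m) cbind(m, matrix(sample(1:4, 8, TRUE),
                                                    ncol = 2)))
  ds2 <- make_diploid(pops2)
  am2 <- amova(ds2, hier, n_perm = 0, n_boot_loci = 0)
  or2 <- oracle + bf_amova(do.call(rbind, lapply(names(pops2), function(p)
    data.frame(allele = as.vector(pops2[[p]][, 3:4]), pop = p,
               group = substr(p, 1, 1)))))
  expect_equal(unname(am2$sigma), unname(or2), tolerance = 1e-8)
})

test_that("AMOVA degenerate designs behave as documented", {
  set.seed(6)
  pops <- list(P1 = matrix(sample(1:3, 12, TRUE), ncol = 2),
               P2 = matrix(sample(1:3, 12, TRUE), ncol = 2),
               P3 = matrix(sample(1:3, 12, TRUE), ncol = 2))
  ds <- make_diploid(pops)
  one <- amova(ds, hierarchy_spec(c(P1 = "G", P2 = "G", P3 = "G")),
               n_perm = 0, n_boot_loci = 0)
  expect_true(is.na(one$f["f_ct"]))
  expect_equal(unname(one$f["f_sc"]), unname(one$f["f_st"]))

  # all populations drawn from one pool: F near 0, ~100% within pops
  big <- two_pop_fixture(seed = 7, theta = 0, n = 60, loci = 6)
  hier <- hierarchy_spec(stats::setNames(c("X", "Y"),
                                         unique(big$samples$population)))
  flat <- amova(big, hier, n_perm = 0, n_boot_loci = 0)
  expect_lt(abs(flat$f["f_st"]), 0.05)
  expect_gt(flat$percent["within_pops"], 95)
})

test_that("AMOVA permutation and bootstrap machinery are sane", {
  cfg <- simulation_config(n_site_groups = 2, pops_per_group = c(3, 3),
                           colonies_per_pop = 15, n_loci = 5,
                           theta_ct = 0.08, theta_sc = 0.02, avoidance = 0,
                           chimera_rate = 0, missing_rate = 0, seed = 23)
  ds <- sim_diploid_direct(cfg)
  hier <- hierarchy_spec(stats::setNames(
    ds$samples$site_group[!duplicated(ds$samples$population)],
    unique(ds$samples$population)))
  am <- amova(ds, hier, n_perm = 199, n_boot_loci = 500, seed = 3)
  expect_true(all(am$p > 0 & am$p <= 1, na.rm = TRUE))
  expect_lt(am$p["f_st"], 0.05)      # strong overall structure detected
  expect_true(!is.null(am$ci))
  expect_true(am$ci[1, "f_st"] <= am$f["f_st"] &&
                am$f["f_st"] <= am$ci[2, "f_st"])
  # permutation p-values are never exactly zero
  expect_gte(min(am$p, na.rm = TRUE), 1 / 200)
})

test_that("Mantel test: identity, anti-ordering and input guards", {
  set.seed(11)
  xy <- matrix(runif(12), ncol = 2)
  d <- as.matrix(dist(xy))
  m <- mantel_ibd(d, d, n_perm = 99, seed = 1)
  expect_equal(m$rxy, 1, tolerance = 1e-12)
  expect_lt(m$p_value, 0.05)
  anti <- max(d) - d; diag(anti) <- 0
  expect_lt(mantel_ibd(anti, d, n_perm = 99, seed = 1)$rxy, 0)
  expect_error(mantel_ibd(d * 0, d, n_perm = 99), "constant")
  expect_error(mantel_ibd(d[1:3, 1:3], d[1:3, 1:3], n_perm = 99), "4")
  dd <- d; dd[1, 2] <- 99
  expect_error(mantel_ibd(dd, d), "symmetric")
})

test_that("PCoA: symmetry, line recovery, reconstruction and sign rule", {
  # three equidistant populations: first two eigenvalues equal
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  p3 <- pcoa_ordination(d3)
  ev <- p3$eigenvalues[p3$eigenvalues > 1e-9]
  expect_equal(ev[1], ev[2], tolerance = 1e-9)

  # points on a line: one positive eigenvalue, coordinates recover spacing
  x <- c(0, 1, 3, 6)
  dl <- abs(outer(x, x, "-"))
  pl <- pcoa_ordination(dl)
  expect_equal(sum(pl$eigenvalues > 1e-6), 1)
  rec <- as.matrix(dist(pl$coords[, 1]))
  expect_equal(unname(rec), unname(dl), tolerance = 1e-8)

  # zero matrix: all coordinates zero
  pz <- pcoa_ordination(matrix(0, 4, 4))
  expect_true(all(pz$coords == 0))

  # Euclidean-embeddable input is reconstructed from all positive axes
  set.seed(12)
  pts <- matrix(rnorm(10), ncol = 2)
  de <- as.matrix(dist(pts))
  pe <- pcoa_ordination(de)
  expect_equal(unname(as.matrix(dist(pe$coords))), unname(de),
               tolerance = 1e-8)
  # deterministic sign: largest-magnitude loading positive on each axis
  for (a in seq_len(ncol(pe$coords)))
    expect_gte(pe$coords[which.max(abs(pe$coords[, a])), a], 0)
})

test_that("likelihood assignment: private alleles, symmetry, self-assignment", {
  # an individual carrying alleles private to founder A goes to A
  set.seed(13)
  A <- matrix(sample(1:2, 24, TRUE), ncol = 2)
  B <- matrix(sample(5:6, 24, TRUE), ncol = 2)
  q <- rbind(c(1L, 2L))  # carries A-private alleles
  ds <- make_diploid(list(A = A, B = B, Q = rbind(q, q, q, q, q)))
  res <- likelihood_assignment(ds, c("A", "B"))
  expect_true(all(res$individuals$assigned[
    res$individuals$population == "Q"] == "A"))
  expect_true(all(abs(rowSums(res$proportions) - 1) < 1e-12))

  # founders with identical frequency pools split roughly evenly
  set.seed(14)
  base <- function() matrix(sample(1:4, 60, TRUE, prob = c(.4, .3, .2, .1)),
                            ncol = 2)
  ds2 <- make_diploid(list(F1 = base(), F2 = base(), X = base()))
  res2 <- likelihood_assignment(ds2, c("F1", "F2"))
  px <- res2$proportions["X", ]
  expect_gt(min(px), 0.2)

  # simulated founders at theta = 0.1: majority self-assignment
  cfg <- simulation_config(n_site_groups = 1, pops_per_group = 3,
                           colonies_per_pop = 30, n_loci = 8,
                           theta_ct = 0, theta_sc = 0.1, avoidance = 0,
                           chimera_rate = 0, missing_rate = 0, seed = 19)
  ds3 <- sim_diploid_direct(cfg)
  founders <- unique(ds3$samples$population)
  res3 <- likelihood_assignment(ds3, founders)
  self <- diag(res3$proportions[founders, founders])
  expect_gte(mean(self >= 0.5), 2 / 3)
  expect_error(likelihood_assignment(ds3, "nope"), "not in dataset")
})

test_that("polyploid F_ST: diploid identity without chimeras, fixation = 1", {
  # same samples, no chimeras: polyploid equals the diploid-frequency
  # partition to machine precision
  cfg <- simulation_config(n_site_groups = 1, pops_per_group = 3,
                           colonies_per_pop = 15, n_loci = 4,
                           chimera_rate = 0, missing_rate = 0, seed = 29)
  st <- simulate_study(cfg)
  pk <- st$peaks[st$peaks$season == "summer", ]
  dd <- call_dataset(pk, "diploid")
  pp <- call_dataset(pk, "polyploid")
  dd_as_poly <- dd; dd_as_poly$variant <- "polyploid"
  fp <- polyploid_fst(pp)
  fd <- polyploid_fst(dd_as_poly)
  expect_equal(fp$fst, fd$fst, tolerance = 1e-12)

  fixA <- matrix(rep(c(1L, 1L), 8), ncol = 2, byrow = TRUE)
  fixB <- matrix(rep(c(2L, 2L), 8), ncol = 2, byrow = TRUE)
  dsf <- make_diploid(list(A = fixA, B = fixB))
  dsf$variant <- "polyploid"
  expect_equal(polyploid_fst(dsf)$fst[1, 2], 1)

  # a shared chimera-introduced allele pulls differentiation down
  addA <- dsf
  extra <- data.frame(sample_id = c("A_i01", "B_i01"), locus = "L1",
                      allele = 9L, weight = NA)
  addA$calls$weight <- 0.5
  calls <- rbind(addA$calls,
                 data.frame(sample_id = c("A_i01", "B_i01"), locus = "L1",
                            allele = 9L, weight = 0.5))
  # renormalise A_i01 / B_i01 to equal-dosage over 2 distinct alleles
  calls$weight[calls$sample_id %in% c("A_i01", "B_i01")] <- 0.5
  mixed <- genotype_dataset(calls[!duplicated(paste(calls$sample_id,
                                                    calls$locus,
                                                    calls$allele)), ],
                            addA$samples, "polyploid")
  expect_lt(polyploid_fst(mixed)$fst[1, 2], 1)
})

test_that("diversity comparison: identity gives zero deltas and p = 1", {
  cfg <- simulation_config(n_site_groups = 1, pops_per_group = 3,
                           colonies_per_pop = 12, n_loci = 4,
                           chimera_rate = 0.3, missing_rate = 0, seed = 37)
  st <- simulate_study(cfg)
  pk <- st$peaks[st$peaks$season == "summer", ]
  dd <- call_dataset(pk, "diploid")
  pp <- call_dataset(pk, "polyploid")
  div <- diversity_table(dd, pp, g = 8, n_perm = 20, seed = 1)
  same <- compare_diversity(div, div)
  expect_true(all(unlist(same$deltas[, -1]) == 0))
  expect_true(all(abs(same$tests$anova_p - 1) < 1e-8 |
                    is.na(same$tests$anova_p)))
  expect_error(compare_diversity(div[0, ], div[0, ]), "shared")
})
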