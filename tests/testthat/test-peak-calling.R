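# Scoring rules, chimera flagging, missingness filtering and replicate
# concordance.

test_that("diploid calls follow the two-tallest-peaks rule", {
  expect_equal(call_diploid(c(180L, 184L, 188L), c(1000, 900, 600)),
               c(180L, 184L))
  expect_equal(call_diploid(200L, 500), c(200L, 200L))
  expect_null(call_diploid(integer(0), numeric(0)))
  # height ties resolved toward the smaller fragment
  expect_equal(call_diploid(c(190L, 186L, 182L), c(800, 800, 800)),
               c(182L, 186L))
  expect_error(call_diploid(c(180L, 184L), c(100, -5)), "positive")
})

test_that("polyploid calls apply the 50%-height rule with a tetraploid cap", {
  expect_equal(call_polyploid(c(180L, 184L, 188L, 192L),
                              c(1000, 900, 600, 300)),
               c(180L, 184L, 188L))  # threshold 450
  expect_equal(call_polyploid(c(180L, 184L), c(1000, 900)), c(180L, 184L))
  # five peaks above threshold: the four tallest survive
  expect_equal(call_polyploid(c(180L, 184L, 188L, 192L, 196L),
                              c(1000, 990, 980, 970, 960)),
               c(180L, 184L, 188L, 192L))
  # the alternative mean-of-main-peaks reference is stricter
  expect_equal(call_polyploid(c(180L, 184L, 188L), c(1000, 900, 460),
                              reference = "mean"),
               c(180L, 184L))
  expect_error(call_polyploid(c(180L), c(100), ratio = 0), "ratio")
})

test_that("diploid alleles are always a subset of the polyploid call", {
  cfg <- simulation_config(n_site_groups = 1, pops_per_group = 2,
                           colonies_per_pop = 20, n_loci = 5,
                           chimera_rate = 0.5, seed = 21)
  st <- simulate_study(cfg)
  dd <- call_dataset(st$peaks[st$peaks$season == "summer", ], "diploid")
  pp <- call_dataset(st$peaks[st$peaks$season == "summer", ], "polyploid")
  for (loc in dd$loci) {
    dsub <- dd$calls[dd$calls$locus == loc, ]
    psub <- pp$calls[pp$calls$locus == loc, ]
    for (id in unique(dsub$sample_id)) {
      expect_true(all(unique(dsub$allele[dsub$sample_id == id]) %in%
                        psub$allele[psub$sample_id == id]))
    }
  }
})

test_that("chimera flags: >2 alleles at any locus; CC matches the design", {
  peaks <- toy_peaks()
  # add a third strong peak at L1 of s1 -> chimeric
  peaks <- rbind(peaks, data.frame(sample_id = "s1", population = "P1",
                                   site_group = "G1", season = "summer",
                                   locus = "L1", allele_size_bp = 192L,
                                   peak_height = 800))
  pp <- call_dataset(peaks, "polyploid")
  fc <- flag_chimeras(pp)
  expect_true(fc$flags$is_chimera[fc$flags$sample_id == "s1"])
  expect_false(fc$flags$is_chimera[fc$flags$sample_id == "s2"])
  expect_equal(fc$cc$cc, 0.5)

  # at the study design (rate 0.35, fusion 1) most seeds land inside the
  # observed field range of 17%-48% chimeric colonies
  inside <- vapply(1:10, function(s) {
    cfg <- simulation_config(n_site_groups = 1, pops_per_group = 1,
                             colonies_per_pop = 30, n_loci = 8,
                             chimera_rate = 0.35, fusion_fraction = 1,
                             missing_rate = 0, seed = s)
    st <- simulate_study(cfg)
    pp <- call_dataset(st$peaks[st$peaks$season == "summer", ], "polyploid")
    cc <- flag_chimeras(pp)$cc$cc
    cc >= 0.17 && cc <= 0.48
  }, logical(1))
  expect_gte(mean(inside), 0.7)
})

test_that("chimera proportion is non-decreasing as the ratio loosens", {
  cfg <- simulation_config(n_site_groups = 1, pops_per_group = 1,
                           colonies_per_pop = 30, n_loci = 6,
                           chimera_rate = 0.5, fusion_fraction = 0.6,
                           missing_rate = 0, seed = 2)
  st <- simulate_study(cfg)
  pk <- st$peaks[st$peaks$season == "summer", ]
  ccs <- vapply(c(0.9, 0.5, 0.2, 0.05), function(r)
    flag_chimeras(call_dataset(pk, "polyploid", ratio = r))$cc$cc,
    numeric(1))
  expect_true(all(diff(ccs) >= 0))
})

test_that("missingness filtering: enumerable toy, then idempotence", {
  # 10 samples x 3 loci; L2 missing in 2/10 (20%) -> dropped;
  # s1 then misses L1+L3 -> 2 missing of 2 kept loci; threshold is "more
  # than 2", so s1 survives; s2 misses nothing.
  g <- list()
  for (i in 1:10) {
    m <- matrix(rep(c(100L, 102L), 3), nrow = 1)
    g[[sprintf("s%02d", i)]] <- m
  }
  pop <- do.call(rbind, g)
  ds <- make_diploid(list(P1 = pop))
  drop_call <- function(ds, id, loc) {
    ds$calls <- ds$calls[!(ds$calls$sample_id == id & ds$calls$locus == loc), ]
    ds
  }
  ds <- drop_call(ds, "P1_i01", "L2")
  ds <- drop_call(ds, "P1_i02", "L2")
  ds <- drop_call(ds, "P1_i01", "L1")
  ds <- drop_call(ds, "P1_i01", "L3")
  f <- filter_dataset(ds, max_missing_per_locus = 0.10,
                      max_missing_loci_per_sample = 2)
  expect_equal(f$loci, c("L1", "L3"))
  expect_setequal(unique(f$samples$sample_id), sprintf("P1_i%02d", 1:10))
  rep <- attr(f, "filter_report")
  expect_equal(rep$dropped_loci, "L2")
  # a sample missing both surviving loci is dropped with threshold 1
  f2 <- filter_dataset(ds, max_missing_per_locus = 0.10,
                       max_missing_loci_per_sample = 1)
  expect_false("P1_i01" %in% f2$samples$sample_id)
  # idempotence
  f3 <- filter_dataset(f, max_missing_per_locus = 0.10,
                       max_missing_loci_per_sample = 2)
  expect_equal(f3$calls, f$calls)
  expect_equal(f3$samples, f$samples)
})

test_that("replicate concordance arithmetic and noise monotonicity", {
  ds <- call_dataset(toy_peaks(), "diploid")
  rc <- replicate_concordance(ds, data.frame(sample_a = "s1", sample_b = "s1"))
  expect_equal(rc$overall, 1)
  rc2 <- replicate_concordance(ds, data.frame(sample_a = "s1",
                                              sample_b = "s2"))
  expect_equal(rc2$overall, 0)  # s1 and s2 differ at both loci
  expect_error(replicate_concordance(ds, data.frame(sample_a = character(0),
                                                    sample_b = character(0))),
               "no replicate")

  # re-called replicates diverge more as peak-height noise grows
  conc <- vapply(c(0.1, 0.6, 1.2), function(sg) {
    cfg <- simulation_config(n_site_groups = 1, pops_per_group = 1,
                             colonies_per_pop = 25, n_loci = 6,
                             chimera_rate = 0.4, fusion_fraction = 0.5,
                             peak_sigma = sg, missing_rate = 0, seed = 13)
    tr <- simulate_allele_frequencies(cfg)
    col <- apply_chimerism(simulate_colonies(tr, cfg), tr, cfg)
    p1 <- simulate_peaks(col, tr, cfg, seed_label = "repA")
    p2 <- simulate_peaks(col, tr, cfg, seed_label = "repB")
    p2$sample_id <- paste0(p2$sample_id, "_r")
    both <- call_dataset(rbind(p1, p2), "polyploid")
    ids <- unique(p1$sample_id)
    replicate_concordance(both, data.frame(sample_a = ids,
                                           sample_b = paste0(ids, "_r")))$overall
  }, numeric(1))
  expect_true(all(diff(conc) < 0))
})

test_that("GenePop and polyploid CSV round-trip through files", {
  cfg <- simulation_config(n_site_groups = 1, pops_per_group = 2,
                           colonies_per_pop = 8, n_loci = 3,
                           chimera_rate = 0.4, missing_rate = 0.05, seed = 6)
  st <- simulate_study(cfg)
  pk <- st$peaks[st$peaks$season == "summer", ]
  dd <- call_dataset(pk, "diploid")
  gp <- tempfile(fileext = ".gen")
  write_genepop(dd, gp)
  back <- read_genepop(gp)
  expect_equal(length(back$loci), 3)
  expect_equal(nrow(back$samples), nrow(dd$samples))
  # allele content preserved per sample x locus
  for (loc in dd$loci) {
    a <- dd$calls[dd$calls$locus == loc, ]
    b <- back$calls[back$calls$locus == loc, ]
    sp_a <- split(a$allele, a$sample_id)
    sp_b <- split(b$allele, b$sample_id)
    expect_equal(lapply(sp_a, sort), lapply(sp_b, sort)[names(sp_a)])
  }
  pp <- call_dataset(pk, "polyploid")
  pcsv <- tempfile(fileext = ".csv")
  write_polyploid_csv(pp, pcsv)
  back2 <- read_polyploid_csv(pcsv)
  expect_equal(nrow(back2$samples), nrow(pp$samples))
  expect_equal(flag_chimeras(back2)$cc, flag_chimeras(pp)$cc)
})
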