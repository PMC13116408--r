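test_that("sample_read_support matches its stated expectations", {
  set.seed(61)
  # symmetric sampling: mean Hb of f = 0.5 draws sits at 0.5 within 3 SE
  sup <- sample_read_support(rep(0.5, 10000), mean_depth = 40, error_rate = 0)
  hb <- sup$alt_count / (sup$ref_count + sup$alt_count)
  expect_lt(abs(mean(hb, na.rm = TRUE) - 0.5), 3 * sd(hb, na.rm = TRUE) / 100)

  # fixed depth 40, f = 0.125 -> expected alt count 5
  sup <- sample_read_support(rep(0.125, 10000), mean_depth = 40,
                             error_rate = 0, depth = 40)
  se <- sd(sup$alt_count) / 100
  expect_lt(abs(mean(sup$alt_count) - 5), 3 * se)
  expect_true(all(sup$dp == 40L))
  expect_true(all(sup$other_count == 0L))

  # pure error: f = 0, e = 0.003, depth 1000 -> expected alt count 1 (e/3)
  sup <- sample_read_support(rep(0, 10000), mean_depth = 1000,
                             error_rate = 0.003, depth = 1000)
  se <- sd(sup$alt_count) / 100
  expect_lt(abs(mean(sup$alt_count) - 1), 3 * se)
  # and other-base miscalls arrive at 2e/3
  se_o <- sd(sup$other_count) / 100
  expect_lt(abs(mean(sup$other_count) - 2), 3 * se_o)
})

test_that("genotype_from_counts is the argmax of the binomial likelihoods", {
  g <- genotype_from_counts(0L, 50L, error_rate = 0.001)
  expect_equal(g$genotype, "hom_alt")
  expect_equal(g$gq, 99L)  # cap

  g <- genotype_from_counts(25L, 25L, error_rate = 0.001)
  expect_equal(g$genotype, "het")
  expect_gt(g$gq, 0L)

  # (1,1): compute the expected GQ from the likelihoods directly
  e <- 0.001
  l_het <- dbinom(1, 2, 0.5)
  l_hom <- max(dbinom(1, 2, e / 3), dbinom(1, 2, 1 - e))
  g <- genotype_from_counts(1L, 1L, error_rate = e)
  expect_equal(g$genotype, "het")
  expect_equal(g$gq, as.integer(round(10 * log10(l_het / l_hom))))

  # zero allele-informative reads -> missing with GQ 0
  g <- genotype_from_counts(0L, 0L, error_rate = e)
  expect_equal(g$genotype, "missing")
  expect_equal(g$gq, 0L)

  # property: the call always agrees with an independent argmax oracle
  set.seed(62)
  rc <- sample(0:60, 200, replace = TRUE)
  ac <- sample(0:60, 200, replace = TRUE)
  got <- genotype_from_counts(rc, ac, error_rate = 0.002)$genotype
  want <- vapply(seq_along(rc), function(i) {
    if (rc[i] + ac[i] == 0) "missing" else
      oracle_genotype(ac[i], rc[i] + ac[i], 0.002)
  }, character(1))
  expect_identical(got, want)
})

test_that("the simulated world respects its own truth-table invariants", {
  cfg <- simulation_config(n_loci = 6000L, lambda_postzygotic = 8,
                           n_somatic = 25L, seed = 63L)
  sim <- simulate_twin_pair(cfg)
  truth <- sim$truth

  # category conservation: somatic counts are configured, planted loci were
  # hom_ref germline, and every post-zygotic record is het in exactly one twin
  expect_equal(sum(truth$category == "somatic"), 2L * cfg$n_somatic)
  expect_equal(sum(truth$sample == "trace", na.rm = TRUE), cfg$n_somatic)
  pz <- truth[grepl("post_zygotic", category)]
  expect_true(all((pz$twin1_gt == "het") != (pz$twin2_gt == "het")))
  expect_true(all(pz$alt_fraction == 0.5))
  som <- truth[category == "somatic"]
  expect_true(all(som$twin1_gt == "hom_ref" & som$twin2_gt == "hom_ref"))
  expect_true(all(som$alt_fraction >= cfg$somatic_fraction_low &
                    som$alt_fraction <= cfg$somatic_fraction_high))
  germ <- truth[category == "germline"]
  expect_true(all(germ$twin1_gt == germ$twin2_gt))

  # per-locus structure
  expect_equal(nrow(truth), cfg$n_loci)
  expect_false(anyDuplicated(truth$pos) > 0)
  expect_equal(length(sim$trace), cfg$n_replicates)
  expect_equal(sim$trace[[1]]$sample_id, "trace")
})

test_that("planting more variants than available hom_ref loci errors", {
  cfg <- simulation_config(n_loci = 50L, p_het = 0.5, p_hom_alt = 0.4,
                           lambda_postzygotic = 100, postzygotic_exact = TRUE,
                           n_somatic = 10L, seed = 64L)
  expect_error(simulate_twin_pair(cfg), "not enough hom_ref")
})

test_that("a same-twin, noise-free pair is identical at every locus", {
  cfg <- simulation_config(n_loci = 2000L, lambda_postzygotic = 0,
                           n_somatic = 0L, error_rate = 0,
                           trace_twin = 1L, reference_twin = 1L, seed = 65L)
  sim <- simulate_twin_pair(cfg)
  expect_identical(sim$truth$twin1_gt, sim$truth$twin2_gt)
  expect_identical(sim$fractions$f_trace, sim$fractions$f_reference)
})

test_that("simulation is deterministic under its seed", {
  cfg <- simulation_config(n_loci = 1000L, n_somatic = 10L, seed = 66L)
  s1 <- simulate_twin_pair(cfg)
  s2 <- simulate_twin_pair(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$trace[[1]]$calls, s2$trace[[1]]$calls)
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- write_simulation(s1, d1)
  f2 <- write_simulation(s2, d2)
  for (k in setdiff(names(f1), "config")) {
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
  }
})

test_that("write_simulation emits the expected files, including panel VCFs", {
  cfg <- simulation_config(n_loci = 500L, n_somatic = 5L, n_replicates = 3L,
                           seed = 67L)
  sim <- simulate_twin_pair(cfg)
  d <- tempfile()
  files <- write_simulation(sim, d,
                            panel_loci = sim$truth[1:4, .(chrom, pos)])
  expect_length(grep("^(trace|reference)_rep", names(files)), 6L)  # 3 reps x 2
  expect_length(grep("^panel_", names(files)), 6L)
  expect_true(all(file.exists(unlist(files))))
  truth_back <- data.table::fread(files[["truth"]])
  expect_equal(nrow(truth_back), 500L)
  panel_cs <- read_sample_calls(files[["panel_trace_rep1"]])
  expect_equal(nrow(panel_cs$calls), 4L)
})

test_that("detection power at fixed depth factorizes into per-replicate acceptance", {
  # oracle: P(consensus het at Hb 0.4-0.6) for a true het at fixed depth d
  # equals p_rep^2 with p_rep from binomial enumeration (error-free reads,
  # genotype model at e = 0.002, GQ floor satisfied inside the window)
  d <- 30L
  e <- 0.002
  k <- 0:d
  called_het <- vapply(k, function(ki) oracle_genotype(ki, d, e) == "het",
                       logical(1))
  in_window <- k / d >= 0.4 & k / d <= 0.6
  p_rep <- sum(dbinom(k[called_het & in_window], d, 0.5))

  set.seed(68)
  n <- 4000L
  shotgun <- filter_preset("shotgun")
  reps <- lapply(c("rep1", "rep2"), function(rid) {
    sup <- sample_read_support(rep(0.5, n), d, error_rate = 0, depth = d)
    gt <- genotype_from_counts(sup$ref_count, sup$alt_count, e)
    make_replicate(data.table::data.table(
      chrom = "chr1", pos = seq_len(n), ref = "A", alt = "G",
      genotype = gt$genotype, ref_count = sup$ref_count,
      alt_count = sup$alt_count, other_count = sup$other_count, gq = gt$gq
    ), "trace", rid)
  })
  cons <- consensus_genotypes(reps, shotgun)
  emp <- sum(cons$genotype == "het") / n
  p_both <- p_rep^2
  se <- sqrt(p_both * (1 - p_both) / n)
  expect_lt(abs(emp - p_both), 3 * se)
})
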