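shotgun <- filter_preset("shotgun")
targeted <- filter_preset("targeted")

test_that("accept_genotype applies the filters with deterministic reason codes", {
  cases <- rbind(
    make_call(genotype = "het", ref_count = 15, alt_count = 15, gq = 50),
    make_call(genotype = "het", ref_count = 4, alt_count = 3, gq = 50),
    make_call(genotype = "het", ref_count = 24, alt_count = 6, gq = 50),
    make_call(genotype = "het", ref_count = 15, alt_count = 15, gq = 9),
    make_call(genotype = "missing", ref_count = 15, alt_count = 15, gq = 50),
    make_call(genotype = "het", ref_count = 0, alt_count = 0,
              other_count = 30, gq = 50)  # undefined Hb
  )
  res <- accept_genotype(cases, shotgun)
  expect_equal(res$accepted, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(res$reason,
               c(NA, "depth", "balance", "quality", "missing", "balance"))

  tres <- accept_genotype(rbind(
    make_call(genotype = "hom_alt", ref_count = 2, alt_count = 96,
              other_count = 2, gq = 60),
    make_call(genotype = "hom_alt", ref_count = 3, alt_count = 94,
              other_count = 3, gq = 60)
  ), targeted)
  expect_equal(tres$accepted, c(TRUE, FALSE))   # noise 0.04 < 0.05 <= 0.06
  expect_equal(tres$reason, c(NA, "noise"))
})

test_that("Hb window bounds are inclusive and noise is strict", {
  # Hb exactly at a bound is accepted: 4/10 = 0.4, 6/10 wait depth: use d=20
  onbound <- rbind(
    make_call(genotype = "het", ref_count = 12, alt_count = 8, gq = 50),  # 0.4
    make_call(genotype = "het", ref_count = 8, alt_count = 12, gq = 50)   # 0.6
  )
  expect_true(all(accept_genotype(onbound, shotgun)$accepted))
  # noise exactly at the ceiling is rejected (strict <)
  atmax <- make_call(genotype = "hom_alt", ref_count = 5, alt_count = 95,
                     gq = 60)
  expect_false(accept_genotype(atmax, targeted)$accepted)
})

test_that("without Hb and noise filters acceptance depends only on dp and gq", {
  plain <- filter_config(8, 10)
  set.seed(21)
  n <- 400
  calls <- make_call()[rep(1, n)]
  calls[, `:=`(pos = seq_len(n),
               genotype = sample(c("hom_ref", "het", "hom_alt"), n, TRUE),
               ref_count = sample(0:40, n, TRUE),
               alt_count = sample(0:40, n, TRUE),
               other_count = sample(0:5, n, TRUE),
               gq = sample(0:60, n, TRUE))]
  res <- accept_genotype(calls, plain)
  dp <- calls$ref_count + calls$alt_count + calls$other_count
  expect_identical(res$accepted, dp >= 8L & calls$gq >= 10L)
})

test_that("filter nesting: a narrower Hb window accepts a subset", {
  set.seed(22)
  n <- 500
  calls <- make_call()[rep(1, n)]
  calls[, `:=`(pos = seq_len(n),
               genotype = sample(c("hom_ref", "het", "hom_alt", "missing"),
                                 n, TRUE),
               ref_count = sample(0:60, n, TRUE),
               alt_count = sample(0:60, n, TRUE),
               gq = sample(0:99, n, TRUE))]
  windows <- list(c(0, 1), c(0.2, 0.8), c(0.4, 0.6), c(0.45, 0.55))
  acc <- lapply(windows, function(w) {
    accept_genotype(calls, filter_config(8, 10, w[1], w[2]))$accepted
  })
  for (i in 2:length(acc)) {
    expect_true(all(acc[[i]] <= acc[[i - 1]]))  # narrower implies wider
  }
})

test_that("replicate_consensus demands per-replicate acceptance and agreement", {
  het <- make_call(genotype = "het", ref_count = 15, alt_count = 15, gq = 50)
  hom <- make_call(genotype = "hom_ref", ref_count = 30, alt_count = 0, gq = 50)
  shallow <- make_call(genotype = "het", ref_count = 3, alt_count = 2, gq = 50)

  both_het <- replicate_consensus(rbind(het, het), shotgun)
  expect_true(both_het$consensus)
  expect_equal(both_het$genotype, "het")
  expect_equal(both_het$n_replicates, 2L)

  disc <- replicate_consensus(rbind(het, hom), shotgun)
  expect_false(disc$consensus)
  expect_equal(disc$reason, "replicate_discordant")

  failed <- replicate_consensus(rbind(het, shallow), shotgun)
  expect_false(failed$consensus)
  expect_equal(failed$reason, "replicate_failed_filter")

  expect_false(replicate_consensus(het, shotgun)$consensus)
  expect_equal(replicate_consensus(het, shotgun)$reason,
               "insufficient_replicates")

  other_locus <- make_call(pos = 999L)
  expect_error(replicate_consensus(rbind(het, other_locus), shotgun),
               "more than one locus")

  # order invariance
  expect_equal(replicate_consensus(rbind(het, shallow), shotgun)$reason,
               replicate_consensus(rbind(shallow, het), shotgun)$reason)
})

test_that("consensus_genotypes matches the per-locus contract across a call set", {
  calls1 <- rbind(
    make_call(pos = 1, genotype = "het"),
    make_call(pos = 2, genotype = "hom_alt", ref_count = 0, alt_count = 30),
    make_call(pos = 3, genotype = "het"),
    make_call(pos = 4, genotype = "het", ref_count = 3, alt_count = 3)  # dp 6
  )
  calls2 <- rbind(
    make_call(pos = 1, genotype = "het"),
    make_call(pos = 2, genotype = "het"),              # discordant replicates
    make_call(pos = 3, genotype = "het"),
    make_call(pos = 4, genotype = "het")
  )
  # pos 5 present in replicate 2 only -> no consensus
  calls2 <- rbind(calls2, make_call(pos = 5, genotype = "het"))
  reps <- list(make_replicate(calls1, replicate_id = "rep1"),
               make_replicate(calls2, replicate_id = "rep2"))
  cons <- consensus_genotypes(reps, shotgun)
  expect_equal(sort(cons$pos), c(1L, 3L))
  expect_equal(unique(cons$genotype), "het")
  rej <- attr(cons, "rejections")
  expect_equal(unname(rej[["replicate_failed_filter"]]), 2L)  # pos 4 and 5
  expect_equal(unname(rej[["replicate_discordant"]]), 1L)     # pos 2

  # replicate order does not matter
  cons_swapped <- consensus_genotypes(rev(reps), shotgun)
  expect_equal(cons_swapped$pos, cons$pos)
  expect_equal(cons_swapped$genotype, cons$genotype)
})

test_that("Monte-Carlo Hb acceptance of true heterozygotes matches the binomial tail", {
  # scaled-down version of the full acceptance check: 2 depths, 5000 draws
  set.seed(23)
  for (d in c(10L, 30L)) {
    n <- 5000L
    sup <- sample_read_support(rep(0.5, n), mean_depth = d, error_rate = 0,
                               depth = d)
    calls <- data.table::data.table(
      chrom = "chr1", pos = seq_len(n), ref = "A", alt = "G",
      genotype = "het", ref_count = sup$ref_count, alt_count = sup$alt_count,
      other_count = sup$other_count, gq = 99L
    )
    emp <- mean(accept_genotype(calls, shotgun)$accepted)
    p <- hb_window_prob(d, 0.4, 0.6)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(emp - p), 3 * se)
  }
})
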