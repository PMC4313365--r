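# The eight-step somatic filter cascade and its component predicates.

test_that("PNR is alt reads over depth with the zero-depth convention", {
  expect_equal(compute_pnr(6, 20), 0.3)
  expect_equal(compute_pnr(0, 37), 0)
  expect_equal(compute_pnr(37, 37), 1)
  expect_equal(compute_pnr(0, 0), 0)
  expect_error(compute_pnr(5, 4), "consistency error")
})

test_that("hard filters flag exactly the published failure modes", {
  d <- tiny_design()
  # five well-separated sites with chosen annotations
  st <- manual_site_table(
    d, "chr1", pos = c(1000, 2000, 3000, 4000, 5000),
    dp = matrix(10L, 5, 5), ad = matrix(0L, 5, 5),
    qual = c(99.9, 500, 500, 500, 500),
    qd = c(15, 1.49, 15, 15, 15),
    mq0 = c(0, 0, 6, 4, 0))
  # site 3: mq0 6 of total 50 (frac 0.12) -> flagged; site 4: frac 0.08 -> not
  fl <- flag_quality(st, tiny_config())
  expect_equal(fl$LowQual, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(fl$LowQD, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(fl$HARD_TO_VALIDATE, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_false(any(fl$SnpCluster))
  expect_equal(fl$pass, c(FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("SnpCluster flags runs of 3 variants within a 10 bp window", {
  d <- tiny_design()
  st <- manual_site_table(d, "chr1", pos = c(100, 105, 109, 300, 306, 315),
                          dp = matrix(30L, 6, 5), ad = matrix(0L, 6, 5))
  fl <- flag_quality(st, tiny_config())
  expect_equal(fl$SnpCluster, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_error(flag_quality(st[c(2, 1, 3:6)], tiny_config()),
               "ordering error")
})

test_that("coverage requires min depth in every sample, boundary inclusive", {
  d <- tiny_design()
  st <- manual_site_table(
    d, "chr1", pos = c(100, 200),
    dp = rbind(c(30L, 25L, 20L, 40L, 33L), c(30L, 25L, 19L, 40L, 33L)),
    ad = matrix(0L, 2, 5))
  expect_equal(pass_coverage(st, config = tiny_config()), c(TRUE, FALSE))
  # missing genotype excludes the site even at sufficient depth
  st$gt[1, 2] <- "./."
  expect_equal(pass_coverage(st, config = tiny_config()), c(FALSE, FALSE))
  expect_error(pass_coverage(st, required_samples = "nope"), "design error")
})

test_that("autosome and somatic predicates behave per the published rules", {
  cfg <- filter_config(known_chroms = c(paste0("chr", 1:22), "chrX", "chrMT"))
  expect_true(is_autosomal("chr7", cfg))
  expect_false(is_autosomal("chrX", cfg))
  expect_false(is_autosomal("chrMT", cfg))
  expect_error(is_autosomal("chr99", cfg), "naming error")
  d <- tiny_design()
  st <- manual_site_table(
    d, "chr1", pos = c(100, 200, 300),
    dp = rbind(c(35L, 30L, 30L, 30L, 30L), c(34L, 30L, 30L, 30L, 30L),
               c(36L, 30L, 30L, 30L, 30L)),
    ad = rbind(c(0L, 0L, 0L, 15L, 0L), c(17L, 0L, 0L, 15L, 0L),
               c(1L, 0L, 0L, 15L, 0L)))
  expect_equal(is_somatic(st, tiny_config()), c(TRUE, FALSE, FALSE))
  expect_equal(is_somatic(st, tiny_config(biopsy_evidence_rule = "alt_le1")),
               c(TRUE, FALSE, TRUE))
})

test_that("subclone calling applies the PNR and cross-subclone rules", {
  d <- tiny_design()
  mk <- function(sub_ad, sub_dp, other_ad, other_dp) {
    manual_site_table(
      d, "chr1", pos = 100,
      dp = rbind(c(30L, 30L, 30L, sub_dp, other_dp)),
      ad = rbind(c(0L, 0L, 0L, sub_ad, other_ad)))
  }
  cfg <- tiny_config()
  # PNR 0.45, other silent -> called
  expect_true(call_subclone(mk(18L, 40L, 0L, 40L), "d1_A1", config = cfg))
  # other subclone at PNR 0.125 with 5 alt reads -> removed
  expect_false(call_subclone(mk(18L, 40L, 5L, 40L), "d1_A1", config = cfg))
  # other subclone with a single alt read (not > 1) -> still called
  expect_true(call_subclone(mk(18L, 40L, 1L, 40L), "d1_A1", config = cfg))
  # below the calling threshold -> not called
  expect_false(call_subclone(mk(11L, 40L, 0L, 40L), "d1_A1", config = cfg))
  # boundary: PNR exactly 0.3 is called
  expect_true(call_subclone(mk(12L, 40L, 0L, 40L), "d1_A1", config = cfg))
})

test_that("dbSNP filtering keeps exactly the unflagged sites", {
  expect_equal(filter_dbsnp(logical(5)), rep(TRUE, 5))
  expect_equal(filter_dbsnp(rep(TRUE, 5)), rep(FALSE, 5))
  set.seed(1)
  flags <- sample(c(rep(TRUE, 40), rep(FALSE, 60)))
  expect_equal(sum(filter_dbsnp(flags)), 60)
  expect_equal(which(filter_dbsnp(flags)), which(!flags))
})

test_that("cross-individual filter removes shared calls from both donors", {
  a <- list(s1 = data.frame(chrom = "chr1", pos = c(10, 20), alt = "T"))
  b <- list(s2 = data.frame(chrom = "chr1", pos = c(20, 30), alt = "T"))
  out <- filter_cross_individual(list(d1 = a, d2 = b))
  expect_equal(out$d1$s1$pos, 10)
  expect_equal(out$d2$s2$pos, 30)
  # disjoint sets: identity
  out2 <- filter_cross_individual(
    list(d1 = a, d2 = list(s2 = data.frame(chrom = "chr2", pos = 20,
                                           alt = "T"))))
  expect_equal(out2$d1$s1$pos, c(10, 20))
  expect_warning(filter_cross_individual(list(d1 = a)), "no-op")
})

test_that("cascade equals the brute-force oracle on randomized simulations", {
  p <- tiny_params(artifact_fraction = 0.1)
  cfg <- tiny_config()
  for (seed in c(101, 202)) {
    designs <- list(tiny_design("d1"), tiny_design("d2"))
    tabs <- lapply(seq_along(designs), function(i) {
      tt <- simulate_truth(designs[[i]], p, seed + i)
      simulate_site_table(tt, designs[[i]], p, seed + 10 + i)
    })
    res <- run_cascade(tabs, cfg)
    orc <- oracle_cascade(tabs, cfg)
    for (d in names(orc))
      expect_equal(res$report$n_sites[res$report$donor == d],
                   orc[[d]]$counts)
    expect_identical(cascade_call_keys(res), oracle_call_keys(orc))
  }
})

test_that("survivor counts are non-increasing and pure steps commute", {
  p <- tiny_params(artifact_fraction = 0.15, dbsnp_somatic_prob = 0.2)
  cfg <- tiny_config()
  for (seed in 1:5) {
    d <- tiny_design()
    tt <- simulate_truth(d, p, seed)
    st <- simulate_site_table(tt, d, p, seed + 50)
    res <- run_cascade(st, cfg)
    expect_true(all(diff(res$report$n_sites) <= 0))
    # per-site predicates are order-insensitive: intersecting them in any
    # order gives the same survivor set as applying them sequentially
    st2 <- sort_sites(st)
    preds <- list(cov = pass_coverage(st2, config = cfg),
                  auto = is_autosomal(st2, cfg),
                  som = is_somatic(st2, cfg),
                  nodb = filter_dbsnp(st2))
    expected <- Reduce(`&`, preds)
    for (perm in list(c(4, 2, 1, 3), c(3, 1, 4, 2)))
      expect_equal(Reduce(`&`, preds[perm]), expected)
  }
})

test_that("clean simulations recover the truth classes exactly", {
  # artifact-free, error-free, depths always >= 20: every carried somatic
  # variant with PNR >= 0.3 is called and nothing else is
  p <- clean_params()
  cfg <- tiny_config()
  designs <- list(tiny_design("d1"), tiny_design("d2"))
  truths <- lapply(seq_along(designs), function(i)
    simulate_truth(designs[[i]], p, 300 + i))
  tabs <- lapply(seq_along(designs), function(i)
    simulate_site_table(truths[[i]], designs[[i]], p, 400 + i))
  res <- run_cascade(tabs, cfg)
  for (i in seq_along(designs)) {
    d <- designs[[i]]
    tt <- truths[[i]]
    st <- sort_sites(tabs[[i]])
    key_of <- function(df) paste(df$chrom, df$pos)
    for (sc in design_subclones(d)) {
      called <- res$calls[[d$donor_id]][[sc]]
      # expected: somatic truth variants carried by sc whose realized PNR
      # passes, minus dbSNP-flagged ones
      carried <- grepl(sc, tt$carriers) &
        tt$class %in% c("pre_existing", "culture_acquired") & !tt$dbsnp
      idx <- match(paste(tt$chrom, tt$pos)[carried], key_of(st$sites))
      pnr <- compute_pnr(st$ad[idx, sc], st$dp[idx, sc])
      expected_keys <- sort(paste(tt$chrom, tt$pos)[carried][pnr >= 0.3])
      expect_identical(sort(key_of(called$sites)), expected_keys)
    }
  }
})
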