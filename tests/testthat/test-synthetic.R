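# Synthetic data generator: truth architecture, evidence calibration, bins.

test_that("donor design validates its sample-role graph", {
  expect_s3_class(tiny_design(), "donor_design")
  expect_error(donor_design("d", "bio", "A", c(S1 = "B")),
               "parental clone")
  expect_error(donor_design("d", "A", "A", c(S1 = "A")), "unique")
  expect_error(sim_params(mean_depth = -1))
  expect_error(sim_params(artifact_fraction = 1.5), "\\[0, 1\\]")
})

test_that("truth tables honour requested class counts and carrier structure", {
  d <- tiny_design()
  p <- tiny_params(n_germline = 100, n_pre_existing_per_clone = 40,
                   n_culture_per_subclone = 50, artifact_fraction = 0.1)
  tt <- simulate_truth(d, p, seed = 7)
  # brute-force tally of the emitted table
  expect_equal(sum(tt$class == "culture_acquired"), 100)  # 50 x 2 subclones
  expect_equal(sum(tt$class %in% c("germline_het", "germline_hom")), 100)
  expect_equal(sum(tt$class == "pre_existing"), 80)
  expect_equal(sum(tt$class == "artifact"), round(0.1 * 280))
  expect_false(any(duplicated(paste(tt$chrom, tt$pos))))
  carr <- strsplit(tt$carriers, ",")
  all_samples <- design_samples(d)
  for (i in seq_len(nrow(tt))) {
    cl <- tt$class[i]
    if (cl %in% c("germline_het", "germline_hom"))
      expect_setequal(carr[[i]], all_samples)
    if (cl == "culture_acquired") {
      expect_length(carr[[i]], 1L)
      expect_true(carr[[i]] %in% design_subclones(d))
    }
    if (cl == "pre_existing") {
      expect_length(carr[[i]], 2L)
      sub <- intersect(carr[[i]], design_subclones(d))
      expect_identical(unname(d$subclone_of[[sub]]), setdiff(carr[[i]], sub))
    }
  }
})

test_that("generator is deterministic and handles the zero/capacity edges", {
  d <- tiny_design()
  p <- tiny_params()
  t1 <- simulate_truth(d, p, seed = 3)
  t2 <- simulate_truth(d, p, seed = 3)
  expect_identical(t1, t2)
  s1 <- simulate_site_table(t1, d, p, seed = 5)
  s2 <- simulate_site_table(t2, d, p, seed = 5)
  expect_identical(s1, s2)
  empty <- simulate_truth(d, tiny_params(n_germline = 0,
                                         n_pre_existing_per_clone = 0,
                                         n_culture_per_subclone = 0), 1)
  expect_equal(nrow(empty), 0L)
  small <- tiny_params(genome = genome_model("chr1", 100), n_germline = 500)
  expect_error(simulate_truth(d, small, 1), "exceeds genome length")
})

test_that("evidence model: allele fractions and depth are calibrated", {
  d <- tiny_design()
  p <- tiny_params(n_germline = 10000, n_pre_existing_per_clone = 0,
                   n_culture_per_subclone = 0, artifact_fraction = 0,
                   germline_hom_frac = 0, genome =
                     genome_model("chr1", 5e7))
  tt <- simulate_truth(d, p, seed = 11)
  st <- simulate_site_table(tt, d, p, seed = 12)
  expect_equal(mean(st$dp), 36.9, tolerance = 0.02)
  vaf <- sum(st$ad) / sum(st$dp)
  expect_gt(vaf, 0.49); expect_lt(vaf, 0.51)
})

test_that("error-free non-carriers and hom carriers hit the signal extremes", {
  d <- tiny_design()
  p <- clean_params(n_germline = 200, germline_hom_frac = 1,
                    n_pre_existing_per_clone = 50,
                    n_culture_per_subclone = 0)
  tt <- simulate_truth(d, p, seed = 2)
  st <- simulate_site_table(tt, d, p, seed = 2)
  hom <- tt$class == "germline_hom"
  expect_true(all(st$ad[hom, ] == st$dp[hom, ]))
  # pre-existing variants: zero alt reads in the biopsy and the other lineage
  pre <- which(tt$class == "pre_existing")
  for (i in pre) {
    noncarrier <- setdiff(design_samples(d),
                          strsplit(tt$carriers[i], ",")[[1]])
    expect_true(all(st$ad[i, noncarrier] == 0))
  }
})

test_that("3-copy CNV shifts het allele fractions to a 1/3 - 2/3 mixture", {
  d <- tiny_design()
  cnv <- data.frame(chrom = "chr1", start = 1, end = 5e6,
                    copy_number = 3,
                    carriers = paste(c("d1_A", "d1_A1"), collapse = ","),
                    stringsAsFactors = FALSE)
  p <- tiny_params(genome = genome_model("chr1", 5e6),
                   n_germline = 800, germline_hom_frac = 0,
                   n_pre_existing_per_clone = 0, n_culture_per_subclone = 0,
                   artifact_fraction = 0, mean_depth = 37,
                   cnv_segments = cnv)
  tt <- simulate_truth(d, p, seed = 21)
  st <- simulate_site_table(tt, d, p, seed = 22)
  vaf <- compute_pnr(st$ad[, "d1_A1"], st$dp[, "d1_A1"])
  lower <- vaf[vaf < 0.5]; upper <- vaf[vaf >= 0.5]
  expect_gt(length(lower), 100); expect_gt(length(upper), 100)
  expect_lt(abs(mean(lower) - 1 / 3), 0.05)
  expect_lt(abs(mean(upper) - 2 / 3), 0.05)
  # carrier depth scaled by 3/2
  expect_equal(mean(st$dp[, "d1_A1"]) / mean(st$dp[, "d1_bio"]), 1.5,
               tolerance = 0.05)
})

test_that("depth bins encode copy number, GC bias and BED coordinates", {
  d <- tiny_design()
  # zero noise, zero GC bias: everything exactly flat
  p0 <- tiny_params(gc_bias_amplitude = 0, bin_noise_sd = 0)
  b0 <- simulate_depth_bins(d, p0, bin_size = 5000, seed = 1)
  one <- b0[b0$sample == "d1_bio", ]
  expect_true(all(one$start %% 5000 == 0) && all(one$end - one$start == 5000))
  r0 <- normalize_bins(gc_correct(one))
  expect_true(all(abs(r0$corrected_ratio - 1) < 1e-12))
  # zero noise with an injected 3-copy segment (a minority of every GC
  # stratum): in-segment ratio exactly 1.5
  cnv <- data.frame(chrom = "chr1", start = 1, end = 1e6, copy_number = 3,
                    carriers = "d1_A1", stringsAsFactors = FALSE)
  p1 <- tiny_params(genome = genome_model(c("chr1", "chr2"), c(5e6, 5e6)),
                    gc_bias_amplitude = 0, bin_noise_sd = 0,
                    cnv_segments = cnv)
  b1 <- simulate_depth_bins(d, p1, bin_size = 5000, seed = 1)
  s1 <- normalize_bins(gc_correct(b1[b1$sample == "d1_A1", ]))
  inseg <- s1$chrom == "chr1" & s1$end <= 1e6
  expect_true(all(abs(s1$corrected_ratio[inseg] - 1.5) < 1e-9))
  expect_true(all(abs(s1$corrected_ratio[!inseg] - 1) < 1e-9))
})

test_that("GC bias induces a count-GC correlation that gc_correct removes", {
  d <- tiny_design()
  p <- tiny_params(genome = genome_model("chr1", 5.2e7),
                   gc_bias_amplitude = 0.2)
  b <- simulate_depth_bins(d, p, bin_size = 5000, seed = 9)
  one <- b[b$sample == "d1_bio", ]
  expect_gt(nrow(one), 10000)
  expect_gt(abs(cor(one$gc, one$raw_count)), 0.3)
  corr <- gc_correct(one)
  expect_lt(abs(cor(corr$gc, corr$corrected_ratio)), 0.05)
})
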