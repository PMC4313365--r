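# GC correction, normalization, segmentation, somatic flagging, VAF analysis.

test_that("gc correction is a stratified median ratio and is idempotent", {
  set.seed(1)
  n <- 2000
  b <- data.frame(sample = "s", chrom = "chr1",
                  start = (seq_len(n) - 1) * 5000,
                  end = seq_len(n) * 5000,
                  gc = runif(n, 0.3, 0.7))
  b$raw_count <- 1800  # flat counts
  c1 <- gc_correct(b)
  expect_true(all(abs(c1$corrected_ratio - 1) < 1e-12))
  b$raw_count <- rpois(n, 1800 * exp(0.8 * (b$gc - 0.5)))
  c2 <- gc_correct(b)
  expect_lt(abs(cor(c2$gc, c2$corrected_ratio)), 0.05)
  # idempotent: stratum medians of a corrected track are exactly 1
  c3 <- gc_correct(c2, value_col = "corrected_ratio")
  expect_equal(c3$corrected_ratio, c2$corrected_ratio, tolerance = 1e-9)
  b$raw_count <- 0
  expect_error(gc_correct(b), "degenerate")
})

test_that("normalization centres the autosomal median and is scale-free", {
  d <- tiny_design()
  cnv <- data.frame(chrom = "chr1", start = 1, end = 1e6, copy_number = 3,
                    carriers = "d1_A1", stringsAsFactors = FALSE)
  p <- tiny_params(genome = genome_model(c("chr1", "chr2"), c(5e6, 5e6)),
                   gc_bias_amplitude = 0, bin_noise_sd = 0,
                   cnv_segments = cnv)
  b <- simulate_depth_bins(d, p, 5000, 1)
  one <- b[b$sample == "d1_A1", ]
  nb <- normalize_bins(gc_correct(one))
  expect_equal(median(nb$corrected_ratio), 1)
  inseg <- nb$chrom == "chr1" & nb$end <= 1e6
  expect_true(all(abs(nb$log2_ratio[inseg] - log2(1.5)) < 1e-9))
  expect_true(all(abs(nb$log2_ratio[!inseg]) < 1e-9))
  # scaling raw counts 10x leaves log2 ratios unchanged
  one10 <- one
  one10$raw_count <- one10$raw_count * 10
  nb10 <- normalize_bins(gc_correct(one10))
  expect_equal(nb10$log2_ratio, nb$log2_ratio, tolerance = 1e-12)
})

test_that("segmentation finds injected gains and stays quiet on null tracks", {
  d <- tiny_design()
  p0 <- tiny_params(genome = genome_model(c("chr1", "chr2"), c(3e6, 3e6)))
  b0 <- simulate_depth_bins(d, p0, 5000, 3)
  null_seg <- segment_bins(normalize_bins(gc_correct(
    b0[b0$sample == "d1_bio", ])))
  expect_equal(nrow(null_seg), 0L)
  # injected 100-bin (500 kb) gain
  cnv <- data.frame(chrom = "chr1", start = 1000001, end = 1500000,
                    copy_number = 3, carriers = "d1_A1",
                    stringsAsFactors = FALSE)
  p1 <- tiny_params(genome = genome_model(c("chr1", "chr2"), c(3e6, 3e6)),
                    cnv_segments = cnv)
  b1 <- simulate_depth_bins(d, p1, 5000, 4)
  seg <- segment_bins(normalize_bins(gc_correct(
    b1[b1$sample == "d1_A1", ])))
  seg <- seg[seg$copy_state == "gain", ]
  expect_equal(nrow(seg), 1L)
  ov <- min(seg$end, 1500000) - max(seg$start, 1000000)
  expect_gte(ov / 500000, 0.95)
  expect_lt(abs(seg$mean_log2 - log2(1.5)), 0.08)
})

test_that("somatic flags match a brute-force interval-intersection oracle", {
  seg_a <- data.frame(chrom = "chr1", start = c(0, 5e6, 9e6),
                      end = c(1e6, 6e6, 9.5e6),
                      copy_state = c("gain", "loss", "gain"))
  seg_ref <- data.frame(chrom = "chr1", start = c(0, 5.5e6),
                        end = c(1e6, 6.5e6),
                        copy_state = c("gain", "loss"))
  out <- somatic_cnv(seg_a, seg_ref)
  expect_equal(out$somatic, c(FALSE, FALSE, TRUE))
  # class must match for masking
  seg_ref2 <- seg_ref
  seg_ref2$copy_state <- c("loss", "gain")
  expect_true(all(somatic_cnv(seg_a, seg_ref2)$somatic))
  # randomized oracle
  set.seed(5)
  for (rep in 1:5) {
    n <- 30
    s <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                    start = s0 <- sample(0:100, n, TRUE) * 1e5,
                    end = s0 + sample(1:20, n, TRUE) * 1e5,
                    copy_state = sample(c("gain", "loss"), n, TRUE))
    r <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                    start = r0 <- sample(0:100, n, TRUE) * 1e5,
                    end = r0 + sample(1:20, n, TRUE) * 1e5,
                    copy_state = sample(c("gain", "loss"), n, TRUE))
    got <- somatic_cnv(s, r)$somatic
    want <- vapply(seq_len(n), function(i) {
      for (j in seq_len(n)) {
        if (s$chrom[i] != r$chrom[j] || s$copy_state[i] != r$copy_state[j])
          next
        ov <- min(s$end[i], r$end[j]) - max(s$start[i], r$start[j])
        if (ov > 0 && ov >= 0.5 * (s$end[i] - s$start[i]) &&
            ov >= 0.5 * (r$end[j] - r$start[j])) return(FALSE)
      }
      TRUE
    }, NA)
    expect_equal(got, want)
  }
})

test_that("informative SNPs are biopsy-het, well-covered sites in the region", {
  d <- tiny_design()
  st <- manual_site_table(
    d, "chr1", pos = c(100, 200, 300, 400),
    dp = rbind(c(30L, 30L, 30L, 30L, 30L), c(40L, 30L, 30L, 30L, 30L),
               c(30L, 30L, 30L, 19L, 30L), c(30L, 30L, 30L, 30L, 30L)),
    ad = rbind(c(15L, 15L, 15L, 15L, 15L), c(38L, 15L, 15L, 15L, 15L),
               c(15L, 15L, 15L, 9L, 15L), c(15L, 15L, 15L, 10L, 15L)))
  region <- list(chrom = "chr1", start = 1, end = 1000)
  prof <- informative_snps(st, region, "d1_A1", tiny_config())
  # site 2 excluded (biopsy PNR 0.95), site 3 excluded (subclone depth 19)
  expect_equal(prof$pos, c(100, 400))
  expect_equal(prof$biopsy_vaf, c(0.5, 0.5))
  # brute-force scan agrees
  b <- d$biopsy
  want <- which(st$sites$pos >= 1 & st$sites$pos <= 1000 &
                  st$ad[, b] / st$dp[, b] >= 0.3 &
                  st$ad[, b] / st$dp[, b] <= 0.7 &
                  st$dp[, b] >= 20 & st$dp[, "d1_A1"] >= 20)
  expect_equal(prof$pos, st$sites$pos[want])
  expect_error(informative_snps(st, list(chrom = "chrZZ", start = 1, end = 2),
                                "d1_A1", tiny_config()), "naming error")
})

test_that("binomial mixture prefers the right model for diploid vs 3-copy", {
  # noise-free half fractions -> diploid preferred
  prof <- data.frame(alt_reads = rep(18L, 30), depth = rep(36L, 30))
  res <- test_het_gain(prof)
  expect_equal(res$preferred, "diploid")
  # simulated 3-copy region at depth 37, 200 SNPs -> gain with high support
  set.seed(9)
  n <- 200
  p <- ifelse(runif(n) < 0.5, 1 / 3, 2 / 3)
  dp <- rpois(n, 37)
  prof2 <- data.frame(alt_reads = rbinom(n, dp, p), depth = dp)
  res2 <- test_het_gain(prof2)
  expect_equal(res2$preferred, "gain")
  expect_gt(res2$log_lr, 10)
  # component symmetry: swapping mixture labels leaves the likelihood fixed
  res3 <- test_het_gain(prof2, gain_fracs = c(2 / 3, 1 / 3))
  expect_equal(res3$loglik_gain, res2$loglik_gain)
  expect_error(test_het_gain(prof2[1:5, ]), "insufficient data")
})
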