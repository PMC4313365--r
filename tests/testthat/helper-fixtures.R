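# Shared fixtures: a small two-donor study and compact simulation parameters.

tiny_design <- function(donor = "d1") {
  donor_design(donor, paste0(donor, "_bio"),
               paste0(donor, c("_A", "_B")),
               stats::setNames(paste0(donor, c("_A", "_B")),
                               paste0(donor, c("_A1", "_B1"))))
}

tiny_genome <- function() genome_model(c("chr1", "chr2"), c(2e6, 2e6))

tiny_params <- function(...) {
  defaults <- list(genome = tiny_genome(), n_germline = 300,
                   n_pre_existing_per_clone = 60,
                   n_culture_per_subclone = 20)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}

tiny_config <- function(...) {
  g <- tiny_genome()
  defaults <- list(autosomes = g$chrom, known_chroms = g$chrom)
  do.call(filter_config, utils::modifyList(defaults, list(...)))
}

# a clean (artifact-free, error-free) deeply covered simulation
clean_params <- function(...) {
  tiny_params(artifact_fraction = 0, error_rate = 0,
              depth_dispersion = 1e6, mean_depth = 40, ...)
}

# hand-built site table for targeted predicate checks
manual_site_table <- function(design, chrom, pos, dp, ad, gt = NULL,
                              qual = 500, qd = 15, mq0 = 0, dbsnp = FALSE,
                              ref = "A", alt = "T") {
  n <- length(pos)
  samples <- design_samples(design)
  fill <- function(m) {
    m <- matrix(as.integer(m), n, length(samples), byrow = TRUE)
    colnames(m) <- samples
    m
  }
  dp <- if (is.matrix(dp)) `colnames<-`(dp, samples) else fill(dp)
  ad <- if (is.matrix(ad)) `colnames<-`(ad, samples) else fill(ad)
  if (is.null(gt)) {
    gt <- matrix(ifelse(ad > 0, "0/1", "0/0"), n, length(samples))
    colnames(gt) <- samples
  }
  site_table(
    data.frame(chrom = rep_len(chrom, n), pos = pos,
               ref = rep_len(ref, n), alt = rep_len(alt, n),
               qual = rep_len(qual, n), qd = rep_len(qd, n),
               mq0 = rep_len(mq0, n), dbsnp = rep_len(dbsnp, n),
               stringsAsFactors = FALSE),
    dp = dp, ad = ad, gt = gt, design = design)
}
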