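# Synthetic data generator: truth tables, per-sample site evidence, depth bins.
# All randomness is local to each function (seed argument); the caller's RNG
# state is preserved.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

READ_LENGTH <- 100  # bp; paired-end 2 x 100 bp platform assumed by the depth model

#' Simulate a ground-truth variant table for a donor design
#'
#' Draws variant positions uniformly without replacement over the genome and
#' assigns each to one of five classes with the carrier structure the clonal
#' design implies: germline SNPs (het or hom) carried by every sample of the
#' donor; pre-existing somatic SNVs carried by one parental clone and its
#' subclone; culture-acquired SNVs private to one subclone; and low-quality
#' artifact sites.
#'
#' @param design A [donor_design()].
#' @param params A [sim_params()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @param gene_models Optional gene-model table (see [simulate_gene_models()]);
#'   when supplied, the `coding` column is filled by interval membership.
#' @return A `truth_table` data.frame with columns `donor_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `class`, `carriers` (comma-separated sample ids), `dbsnp`,
#'   `coding`.
#' @export
simulate_truth <- function(design, params, seed, gene_models = NULL) {
  stopifnot(inherits(design, "donor_design"), inherits(params, "sim_params"))
  genome <- params$genome
  clones <- design$parental_clones
  subclones <- design_subclones(design)
  n_real <- params$n_germline +
    params$n_pre_existing_per_clone * length(clones) +
    params$n_culture_per_subclone * length(subclones)
  n_artifact <- round(params$artifact_fraction * n_real)
  n_total <- n_real + n_artifact
  glen <- sum(genome$length)
  if (n_total > glen)
    stop("requested variant count (", n_total,
         ") exceeds genome length (", glen, ")")
  with_local_seed(seed, {
    cols <- c("donor_id", "chrom", "pos", "ref", "alt",
              "class", "carriers", "dbsnp", "coding")
    if (n_total == 0L) {
      tt <- data.frame(donor_id = character(), chrom = character(),
                       pos = integer(), ref = character(), alt = character(),
                       class = character(), carriers = character(),
                       dbsnp = logical(), coding = logical(),
                       stringsAsFactors = FALSE)
      class(tt) <- c("truth_table", "data.frame")
      return(tt)
    }
    # uniform positions without replacement over the concatenated genome
    offs <- cumsum(c(0, genome$length))[seq_len(nrow(genome))]
    lin <- sort(sample(glen, n_total, replace = FALSE))
    idx <- findInterval(lin - 1, cumsum(genome$length)) + 1L
    chrom <- genome$chrom[idx]
    pos <- as.integer(lin - offs[idx])
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_total, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    # class assignment: shuffle rows into class blocks
    ord <- sample.int(n_total)
    klass <- character(n_total)
    carriers <- character(n_total)
    all_samples <- paste(design_samples(design), collapse = ",")
    i <- 0L
    take <- function(n) {
      out <- ord[i + seq_len(n)]
      i <<- i + n
      out
    }
    g <- take(params$n_germline)
    n_hom <- round(params$germline_hom_frac * length(g))
    hom <- g[seq_len(n_hom)]
    het <- setdiff(g, hom)
    klass[het] <- "germline_het"; klass[hom] <- "germline_hom"
    carriers[g] <- all_samples
    for (cl in clones) {
      sub <- names(design$subclone_of)[design$subclone_of == cl]
      p <- take(params$n_pre_existing_per_clone)
      klass[p] <- "pre_existing"
      carriers[p] <- paste(c(cl, sub), collapse = ",")
    }
    for (sc in subclones) {
      cvar <- take(params$n_culture_per_subclone)
      klass[cvar] <- "culture_acquired"
      carriers[cvar] <- sc
    }
    if (n_artifact > 0L) {
      a <- take(n_artifact)
      klass[a] <- "artifact"
      carriers[a] <- sample(subclones, n_artifact, replace = TRUE)
    }
    dbsnp <- logical(n_total)
    is_g <- klass %in% c("germline_het", "germline_hom")
    dbsnp[is_g] <- stats::runif(sum(is_g)) < params$dbsnp_germline_prob
    dbsnp[!is_g] <- stats::runif(sum(!is_g)) < params$dbsnp_somatic_prob
    coding <- rep(NA, n_total)
    if (!is.null(gene_models)) {
      coding <- position_in_cds(chrom, pos, gene_models)
      # at coding positions the ref allele is dictated by the gene model
      gref <- cds_ref_base(chrom, pos, gene_models)
      fix <- which(!is.na(gref))
      ref[fix] <- gref[fix]
      alt[fix] <- vapply(ref[fix],
                         function(r) sample(setdiff(bases, r), 1L), "")
    }
    tt <- data.frame(donor_id = design$donor_id, chrom = chrom, pos = pos,
                     ref = ref, alt = alt, class = klass, carriers = carriers,
                     dbsnp = dbsnp, coding = coding, stringsAsFactors = FALSE)
    rownames(tt) <- NULL
    class(tt) <- c("truth_table", "data.frame")
    tt
  })
}

truth_carrier_list <- function(truth) strsplit(truth$carriers, ",", fixed = TRUE)

#' Simulate per-sample sequencing evidence for a truth table
#'
#' Per-sample depth is drawn from a negative binomial with mean `mean_depth`
#' and size `depth_dispersion`; alternative reads are binomial with success
#' fraction 0.5 (het carrier), 1 - error_rate (hom carrier) or `error_rate`
#' (non-carrier). Inside a simulated 3-copy gain, carrier depths are scaled by
#' 3/2 and heterozygous allele fractions shift to 1/3 or 2/3 depending on which
#' haplotype was duplicated (drawn once per site). Artifact sites receive, with
#' equal probability, a failing site quality (QUAL), quality-by-depth (QD) or
#' zero-mapping-quality (MQ0) profile so that each hard-filter branch is
#' exercised.
#'
#' @param truth A `truth_table` from [simulate_truth()].
#' @param design The [donor_design()] used to build `truth`.
#' @param params The [sim_params()] used to build `truth`.
#' @param seed Integer seed.
#' @return A [site_table()] holding per-site annotations and per-sample
#'   depth / alt-read / genotype matrices.
#' @export
simulate_site_table <- function(truth, design, params, seed) {
  stopifnot(inherits(truth, "data.frame"), inherits(design, "donor_design"),
            inherits(params, "sim_params"))
  if (nrow(truth) > 0 && !all(truth$chrom %in% params$genome$chrom))
    stop("truth table and simulation genome disagree on chromosome names")
  samples <- design_samples(design)
  n <- nrow(truth)
  with_local_seed(seed, {
    dp <- matrix(stats::rnbinom(n * length(samples),
                                mu = params$mean_depth,
                                size = params$depth_dispersion),
                 nrow = n, ncol = length(samples),
                 dimnames = list(NULL, samples))
    carr <- truth_carrier_list(truth)
    carrier <- matrix(FALSE, n, length(samples), dimnames = list(NULL, samples))
    for (j in seq_along(samples))
      carrier[, j] <- vapply(carr, function(cc) samples[j] %in% cc, NA)
    p_alt <- matrix(params$error_rate, n, length(samples))
    hom <- truth$class == "germline_hom"
    p_alt[carrier & !hom] <- 0.5
    p_alt[carrier & hom] <- 1 - params$error_rate
    # copy-number segments: scale carrier depth and shift het allele fractions
    if (!is.null(params$cnv_segments)) {
      seg_carriers <- cnv_carrier_list(params$cnv_segments)
      for (k in seq_len(nrow(params$cnv_segments))) {
        seg <- params$cnv_segments[k, ]
        cn <- seg$copy_number
        in_seg <- truth$chrom == seg$chrom & truth$pos >= seg$start &
          truth$pos <= seg$end
        if (!any(in_seg) || cn == 2) next
        # which haplotype was duplicated, per site (fixed across samples)
        alt_on_dup <- stats::runif(sum(in_seg)) < 0.5
        sj <- match(intersect(seg_carriers[[k]], samples), samples)
        for (j in sj) {
          dp[in_seg, j] <- stats::rnbinom(
            sum(in_seg), mu = params$mean_depth * cn / 2,
            size = params$depth_dispersion)
          het_here <- carrier[in_seg, j] & !hom[in_seg]
          pa <- p_alt[in_seg, j]
          if (cn == 3)
            pa[het_here] <- ifelse(alt_on_dup[het_here], 2 / 3, 1 / 3)
          p_alt[in_seg, j] <- pa
        }
      }
    }
    ad <- matrix(stats::rbinom(n * length(samples), as.vector(dp),
                               as.vector(p_alt)),
                 n, length(samples), dimnames = list(NULL, samples))
    gt <- matrix("0/0", n, length(samples), dimnames = list(NULL, samples))
    gt[carrier & !hom] <- "0/1"
    gt[carrier & hom] <- "1/1"
    # site-level quality annotations
    qual <- round(stats::runif(n, 200, 2000), 2)
    qd <- round(stats::runif(n, 5, 25), 2)
    mq0 <- integer(n)
    art <- which(truth$class == "artifact")
    if (length(art)) {
      mode <- sample(c("qual", "qd", "mq0"), length(art), replace = TRUE)
      qual[art[mode == "qual"]] <-
        round(stats::runif(sum(mode == "qual"), 0, 99.9), 2)
      qd[art[mode == "qd"]] <-
        round(stats::runif(sum(mode == "qd"), 0, 1.49), 2)
      tot_dp <- rowSums(dp)
      m <- art[mode == "mq0"]
      mq0[m] <- pmax(4L, as.integer(ceiling(0.15 * tot_dp[m])))
    }
    sites <- data.frame(chrom = truth$chrom, pos = truth$pos,
                        ref = truth$ref, alt = truth$alt,
                        qual = qual, qd = qd, mq0 = mq0,
                        dbsnp = truth$dbsnp, stringsAsFactors = FALSE)
    site_table(sites, dp = dp, ad = ad, gt = gt, design = design)
  })
}

#' Simulate per-sample binned read-depth tracks
#'
#' Bins each chromosome into fixed-width windows (BED convention: 0-based,
#' half-open), assigns each bin a GC fraction, and draws read counts whose
#' expectation is proportional to copy number and to a smooth exponential GC
#' bias curve. Carrier samples of a 3-copy segment get 1.5x expected counts
#' inside it. With `bin_noise_sd = 0` counts equal their expectation exactly.
#'
#' @param design A [donor_design()].
#' @param params A [sim_params()]; uses `mean_depth`, `gc_bias_amplitude`,
#'   `bin_noise_sd` and `cnv_segments`.
#' @param bin_size Bin width in bp (default 5000).
#' @param seed Integer seed.
#' @return A `depth_bins` data.frame with columns `sample`, `chrom`, `start`,
#'   `end`, `gc`, `raw_count`, `copy_number` (truth), plus attributes
#'   `bin_size` and `genome`.
#' @export
simulate_depth_bins <- function(design, params, bin_size = 5000, seed = 1L) {
  stopifnot(inherits(design, "donor_design"), inherits(params, "sim_params"),
            bin_size > 0)
  genome <- params$genome
  samples <- design_samples(design)
  with_local_seed(seed, {
    per_chrom <- lapply(seq_len(nrow(genome)), function(i) {
      nb <- floor(genome$length[i] / bin_size)
      if (nb == 0L) return(NULL)
      start <- (seq_len(nb) - 1L) * bin_size
      data.frame(chrom = genome$chrom[i], start = start,
                 end = start + bin_size, stringsAsFactors = FALSE)
    })
    bins <- do.call(rbind, per_chrom)
    nb <- nrow(bins)
    # smooth GC landscape along the genome
    gc <- 0.45 + 0.12 * sin(2 * pi * bins$start / 2e6) +
      if (params$bin_noise_sd > 0) stats::rnorm(nb, 0, 0.01) else 0
    gc <- pmin(pmax(gc, 0.25), 0.75)
    bias <- exp(4 * params$gc_bias_amplitude * (gc - 0.5))
    base_count <- params$mean_depth * bin_size / READ_LENGTH
    seg_carriers <- cnv_carrier_list(params$cnv_segments)
    out <- vector("list", length(samples))
    for (j in seq_along(samples)) {
      cn <- rep(2, nb)
      if (!is.null(params$cnv_segments)) {
        for (k in seq_len(nrow(params$cnv_segments))) {
          if (!(samples[j] %in% seg_carriers[[k]])) next
          seg <- params$cnv_segments[k, ]
          hit <- bins$chrom == seg$chrom & bins$start >= seg$start - 1 &
            bins$end <= seg$end
          cn[hit] <- seg$copy_number
        }
      }
      mu <- base_count * (cn / 2) * bias
      raw <- if (params$bin_noise_sd > 0) {
        stats::rpois(nb, mu * exp(stats::rnorm(nb, 0, params$bin_noise_sd) -
                                    params$bin_noise_sd^2 / 2))
      } else mu
      out[[j]] <- data.frame(sample = samples[j], bins, gc = gc,
                             raw_count = raw, copy_number = cn,
                             stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "bin_size") <- bin_size
    attr(res, "genome") <- genome
    class(res) <- c("depth_bins", "data.frame")
    res
  })
}

#' Approximate per-base depth of a depth bin
#'
#' Converts a bin's read count to mean per-base coverage assuming the
#' platform's read length.
#' @param bins A `depth_bins` data.frame.
#' @return Numeric vector of per-base depths.
#' @export
bin_depth <- function(bins) {
  bs <- attr(bins, "bin_size")
  if (is.null(bs)) bs <- bins$end - bins$start
  bins$raw_count * READ_LENGTH / bs
}
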