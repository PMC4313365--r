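# Read-depth copy-number analysis: stratified-median GC correction, coverage
# normalization, rule-based segmentation against log2 thresholds, somatic
# filtering against the reference sample, and a binomial-mixture test that
# confirms heterozygous gains from allele fractions of informative SNPs.

#' GC-correct binned read counts (one sample)
#'
#' Partitions bins into GC strata of width `stratum_width`, merges strata with
#' fewer than `min_stratum_bins` bins into their nearest neighbour, and divides
#' each bin's raw count by the median raw count of its stratum. Deterministic
#' and idempotent up to the stratum medians of an already-corrected track.
#'
#' @param bins A `depth_bins` data.frame for a single sample (columns `gc`,
#'   `raw_count`; a `corrected_ratio` column is added/overwritten).
#' @param stratum_width GC stratum width (default 0.02).
#' @param min_stratum_bins Minimum bins per stratum before merging (default 10).
#' @param value_col Column to correct (default `"raw_count"`).
#' @return `bins` with a `corrected_ratio` column.
#' @export
gc_correct <- function(bins, stratum_width = 0.02, min_stratum_bins = 10,
                       value_col = "raw_count") {
  stopifnot(is.data.frame(bins), "gc" %in% names(bins),
            value_col %in% names(bins))
  if (length(unique(bins$sample)) > 1)
    stop("gc_correct operates on one sample at a time")
  v <- bins[[value_col]]
  if (all(v == 0)) stop("degenerate input: all bin counts are zero")
  stratum <- floor(bins$gc / stratum_width)
  # merge sparse strata with their nearest (by GC) non-sparse neighbour
  tab <- table(stratum)
  levels <- as.numeric(names(tab))
  big <- levels[tab >= min_stratum_bins]
  if (length(big) == 0L) {
    stratum <- rep(0, length(stratum))  # one global stratum
  } else {
    remap <- vapply(levels, function(l) big[which.min(abs(big - l))], 0)
    stratum <- remap[match(stratum, levels)]
  }
  med <- tapply(v, stratum, stats::median)
  bins$corrected_ratio <- v / as.numeric(med[as.character(stratum)])
  bins
}

#' Normalize corrected ratios for genome coverage and take log2
#'
#' Scales the corrected ratio so the autosomal median equals 1, then computes
#' `log2_ratio`. Zero-count bins are marked missing (`NA` log2) and are
#' excluded from segmentation.
#'
#' @param bins Output of [gc_correct()].
#' @param autosomes Chromosome names treated as autosomal (default: all).
#' @return `bins` with `corrected_ratio` rescaled and a `log2_ratio` column.
#' @export
normalize_bins <- function(bins, autosomes = unique(bins$chrom)) {
  stopifnot("corrected_ratio" %in% names(bins))
  auto <- bins$chrom %in% autosomes & bins$corrected_ratio > 0
  if (!any(auto)) stop("no positive autosomal bins to normalize against")
  m <- stats::median(bins$corrected_ratio[auto])
  bins$corrected_ratio <- bins$corrected_ratio / m
  bins$log2_ratio <- ifelse(bins$corrected_ratio > 0,
                            log2(bins$corrected_ratio), NA_real_)
  bins
}

#' Segment a normalized depth track into copy-number segments
#'
#' Bins are classified `gain` when `log2_ratio >= gain_threshold`, `loss` when
#' `<= loss_threshold`, else `neutral`; maximal same-class runs of at least
#' `min_bins` bins are merged into segments, tolerating up to one interior
#' discordant bin per `discord_per` bins. Default thresholds correspond to a
#' single-copy change on a diploid background (log2(3/2) for a gain, log2(1/2)
#' for a loss) relaxed by `margin`; the default margin of 0.25 places the gain
#' threshold near the midpoint between the neutral and 3-copy levels, so each
#' bin is in effect assigned to the nearest copy state before run merging.
#'
#' @param bins Output of [normalize_bins()] (single sample).
#' @param gain_threshold,loss_threshold Log2 thresholds; defaults
#'   `log2(1.5) - margin` and `log2(0.5) + margin`.
#' @param margin Threshold relaxation (default 0.25).
#' @param min_bins Minimum bins per non-neutral segment (default 10).
#' @param discord_per One interior discordant bin tolerated per this many bins
#'   (default 10).
#' @return A data.frame of segments: `chrom`, `start`, `end` (0-based
#'   half-open), `copy_state`, `mean_log2`, `n_bins`.
#' @export
segment_bins <- function(bins, margin = 0.25,
                         gain_threshold = log2(1.5) - margin,
                         loss_threshold = log2(0.5) + margin,
                         min_bins = 10, discord_per = 10) {
  stopifnot("log2_ratio" %in% names(bins))
  bins <- bins[!is.na(bins$log2_ratio), , drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      copy_state = character(), mean_log2 = numeric(),
                      n_bins = integer(), stringsAsFactors = FALSE)
  if (nrow(bins) == 0L) return(empty)
  cls <- ifelse(bins$log2_ratio >= gain_threshold, "gain",
                ifelse(bins$log2_ratio <= loss_threshold, "loss", "neutral"))
  segs <- list()
  for (ch in unique(bins$chrom)) {
    i <- which(bins$chrom == ch)
    i <- i[order(bins$start[i])]
    k <- cls[i]
    r <- rle(k)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(cls = r$values, from = starts, to = ends,
                       stringsAsFactors = FALSE)
    # merge same-class non-neutral runs across short discordant gaps while the
    # discordance budget (1 per discord_per bins) holds
    nz <- which(runs$cls != "neutral")
    merged <- list()
    j <- 1L
    while (j <= length(nz)) {
      a <- nz[j]
      cur_from <- runs$from[a]; cur_to <- runs$to[a]; cur_cls <- runs$cls[a]
      jj <- j
      while (jj < length(nz)) {
        b <- nz[jj + 1L]
        if (runs$cls[b] != cur_cls) break
        cand_to <- runs$to[b]
        span <- cand_to - cur_from + 1L
        discord <- sum(k[cur_from:cand_to] != cur_cls)
        if (discord <= floor(span / discord_per)) {
          cur_to <- cand_to
          jj <- jj + 1L
        } else break
      }
      merged[[length(merged) + 1L]] <- c(cur_from, cur_to)
      j <- jj + 1L
      # record class via closure below
      attr(merged[[length(merged)]], "cls") <- cur_cls
    }
    for (m in merged) {
      sel <- i[m[1]:m[2]]
      n_conc <- sum(cls[sel] == attr(m, "cls"))
      if (n_conc < min_bins) next
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start = min(bins$start[sel]), end = max(bins$end[sel]),
        copy_state = attr(m, "cls"),
        mean_log2 = mean(bins$log2_ratio[sel]),
        n_bins = length(sel), stringsAsFactors = FALSE)
    }
  }
  if (!length(segs)) return(empty)
  do.call(rbind, c(segs, make.row.names = FALSE))
}

#' Flag somatic copy-number segments against a reference sample
#'
#' A sample segment is somatic unless a same-class segment in the reference
#' (e.g. the donor biopsy) overlaps it reciprocally by at least `min_overlap`.
#'
#' @param segments_sample,segments_reference Segment data.frames from
#'   [segment_bins()].
#' @param min_overlap Reciprocal overlap fraction (default 0.5).
#' @return `segments_sample` with a logical `somatic` column.
#' @export
somatic_cnv <- function(segments_sample, segments_reference,
                        min_overlap = 0.5) {
  if (nrow(segments_sample) == 0L) {
    segments_sample$somatic <- logical(0)
    return(segments_sample)
  }
  somatic <- rep(TRUE, nrow(segments_sample))
  for (i in seq_len(nrow(segments_sample))) {
    s <- segments_sample[i, ]
    if (nrow(segments_reference) == 0L) next
    r <- segments_reference[segments_reference$chrom == s$chrom &
                              segments_reference$copy_state == s$copy_state, ]
    for (j in seq_len(nrow(r))) {
      ov <- min(s$end, r$end[j]) - max(s$start, r$start[j])
      if (ov <= 0) next
      if (ov / (s$end - s$start) >= min_overlap &&
          ov / (r$end[j] - r$start[j]) >= min_overlap) {
        somatic[i] <- FALSE
        break
      }
    }
  }
  segments_sample$somatic <- somatic
  segments_sample
}

#' Informative SNPs in a region
#'
#' SNPs heterozygous in the biopsy (biopsy PNR within `het_band`) with depth at
#' least `min_depth` in both the biopsy and the queried sample; their allele
#' fractions read out haplotype dosage inside a candidate copy-number region.
#'
#' @param x A [site_table()].
#' @param region List or data.frame row with `chrom`, `start`, `end`
#'   (1-based, inclusive).
#' @param sample_id Sample whose allele fractions are profiled.
#' @param config A [filter_config()] (uses `min_depth`).
#' @param het_band Biopsy PNR band defining heterozygosity (default
#'   `c(0.3, 0.7)`).
#' @return A `vaf_profile` data.frame: `chrom`, `pos`, `alt_reads`, `depth`,
#'   `vaf`, `biopsy_vaf`.
#' @export
informative_snps <- function(x, region, sample_id,
                             config = filter_config(),
                             het_band = c(0.3, 0.7)) {
  stopifnot(inherits(x, "site_table"))
  if (!is.null(config$known_chroms) &&
      !(region$chrom %in% config$known_chroms))
    stop("naming error: unknown chromosome ", region$chrom)
  b <- x$design$biopsy
  bpnr <- compute_pnr(x$ad[, b], x$dp[, b])
  keep <- x$sites$chrom == region$chrom &
    x$sites$pos >= region$start & x$sites$pos <= region$end &
    bpnr >= het_band[1] & bpnr <= het_band[2] &
    x$dp[, b] >= config$min_depth & x$dp[, sample_id] >= config$min_depth
  out <- data.frame(chrom = x$sites$chrom[keep], pos = x$sites$pos[keep],
                    alt_reads = x$ad[keep, sample_id],
                    depth = x$dp[keep, sample_id],
                    vaf = compute_pnr(x$ad[keep, sample_id],
                                      x$dp[keep, sample_id]),
                    biopsy_vaf = bpnr[keep], stringsAsFactors = FALSE)
  class(out) <- c("vaf_profile", "data.frame")
  out
}

#' Binomial-mixture test for a heterozygous gain
#'
#' Compares, on the alt-read counts of informative SNPs, the log-likelihood of
#' an equal-weight two-component binomial mixture with success fractions
#' 1/3 and 2/3 (a 3-copy heterozygous gain: the duplicated haplotype carries
#' either the alt or the ref allele) against a single binomial at 1/2
#' (diploid). The mixture likelihood is symmetric in the two components.
#'
#' @param profile A `vaf_profile` from [informative_snps()].
#' @param min_snps Minimum informative SNPs required (default 20).
#' @param gain_fracs Mixture success fractions (default `c(1/3, 2/3)`).
#' @return List with `log_lr` (gain minus diploid log-likelihood),
#'   `preferred` (`"gain"` or `"diploid"`), `loglik_gain`, `loglik_diploid`,
#'   `n_snps`, and `component` (per-SNP posterior-modal component, 1 or 2).
#' @export
test_het_gain <- function(profile, min_snps = 20, gain_fracs = c(1/3, 2/3)) {
  n <- nrow(profile)
  if (n < min_snps)
    stop("insufficient data: ", n, " informative SNPs (need >= ", min_snps, ")")
  k <- profile$alt_reads
  d <- profile$depth
  l1 <- stats::dbinom(k, d, gain_fracs[1], log = TRUE)
  l2 <- stats::dbinom(k, d, gain_fracs[2], log = TRUE)
  # log(0.5 exp(l1) + 0.5 exp(l2)), stably
  m <- pmax(l1, l2)
  loglik_gain <- sum(m + log(0.5 * exp(l1 - m) + 0.5 * exp(l2 - m)))
  loglik_diploid <- sum(stats::dbinom(k, d, 0.5, log = TRUE))
  log_lr <- loglik_gain - loglik_diploid
  list(log_lr = log_lr,
       preferred = if (log_lr > 0) "gain" else "diploid",
       loglik_gain = loglik_gain, loglik_diploid = loglik_diploid,
       n_snps = n,
       component = ifelse(l2 > l1, 2L, 1L))
}

#' Full per-sample CNV pipeline on a multi-sample bin track
#'
#' Convenience wrapper: GC-corrects, normalizes and segments each sample's
#' track, then flags segments somatic against the reference sample.
#'
#' @param bins A multi-sample `depth_bins` data.frame.
#' @param reference_id Reference sample (e.g. the donor biopsy).
#' @param autosomes Autosome names for normalization.
#' @param ... Passed to [segment_bins()].
#' @return Named list per non-reference sample of somatic-flagged segment
#'   data.frames.
#' @export
call_cnv <- function(bins, reference_id, autosomes = unique(bins$chrom), ...) {
  samples <- unique(bins$sample)
  if (!reference_id %in% samples)
    stop("reference sample ", reference_id, " not in bin track")
  prep <- function(s) {
    b <- bins[bins$sample == s, , drop = FALSE]
    normalize_bins(gc_correct(b), autosomes = autosomes)
  }
  ref_seg <- segment_bins(prep(reference_id), ...)
  out <- list()
  for (s in setdiff(samples, reference_id))
    out[[s]] <- somatic_cnv(segment_bins(prep(s), ...), ref_seg)
  out
}
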