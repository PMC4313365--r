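# Attribution of filtered somatic calls to pre-existing vs culture-acquired
# classes, false-negative-rate estimation from germline SNP recovery, and the
# surveyed genome fraction.

#' Attribute somatic calls to pre-existing vs culture-acquired
#'
#' Somatic substitutions with evidence in both the parental clonal culture and
#' its subclone pre-date the culture period (acquired in vivo or during
#' derivation); substitutions private to the subclone were acquired during
#' culture. "Evidence" in the parental clone defaults to at least 2
#' alternative reads or PNR at or above the calling threshold.
#'
#' @param cascade A `cascade_result` from [run_cascade()], or a named list of
#'   per-subclone [site_table()]s for a single donor.
#' @param config A [filter_config()]; `parental_evidence_rule` selects the
#'   evidence rule.
#' @return A data.frame of attributed calls with columns `donor`, `subclone`,
#'   `chrom`, `pos`, `ref`, `alt`, `parental_alt`, `parental_depth`,
#'   `parental_pnr`, `label` (`"pre_existing"` or `"culture_acquired"`).
#' @export
attribute_calls <- function(cascade, config = filter_config()) {
  calls <- if (inherits(cascade, "cascade_result")) cascade$calls
           else stop("expected a cascade_result from run_cascade()")
  out <- list()
  for (d in names(calls)) {
    for (sc in names(calls[[d]])) {
      x <- calls[[d]][[sc]]
      design <- x$design
      if (!sc %in% names(design$subclone_of))
        stop("design error: subclone ", sc, " not in design of donor ", d)
      parent <- design$subclone_of[[sc]]
      n <- length(x)
      if (n == 0L) next
      palt <- x$ad[, parent]
      pdp <- x$dp[, parent]
      ppnr <- compute_pnr(palt, pdp)
      evid <- switch(config$parental_evidence_rule,
                     alt2_or_pnr = palt >= 2 | ppnr >= config$pnr_call,
                     alt1 = palt >= 1,
                     pnr = ppnr >= config$pnr_call)
      out[[length(out) + 1L]] <- data.frame(
        donor = d, subclone = sc,
        chrom = x$sites$chrom, pos = x$sites$pos,
        ref = x$sites$ref, alt = x$sites$alt,
        parental_alt = palt, parental_depth = pdp, parental_pnr = ppnr,
        label = ifelse(evid, "pre_existing", "culture_acquired"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(donor = character(), subclone = character(),
                      chrom = character(), pos = integer(), ref = character(),
                      alt = character(), parental_alt = integer(),
                      parental_depth = integer(), parental_pnr = numeric(),
                      label = character(), stringsAsFactors = FALSE))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Per-subclone stability summary
#'
#' Tallies attributed calls per subclone: total somatic substitutions, those
#' pre-dating culture, and those acquired during culture; optionally coding
#' consequence counts when a `consequence` column is present (see
#' [classify_variants()]). When an FNR estimate is supplied, FNR-adjusted
#' totals (`total / (1 - FNR)`) are reported alongside the raw counts; raw
#' counts are the headline numbers.
#'
#' @param attributed Output of [attribute_calls()].
#' @param design A [donor_design()] or list of them (subclones with zero calls
#'   are then reported as zero rows).
#' @param fnr Optional named numeric vector of per-subclone FNR estimates.
#' @return A data.frame with one row per subclone: `donor`, `subclone`,
#'   `total`, `pre_existing`, `culture_acquired`, optional coding counts, and
#'   `total_fnr_adjusted` when `fnr` is given.
#' @export
summarize_stability <- function(attributed, design = NULL, fnr = NULL) {
  subs <- if (!is.null(design)) {
    dl <- if (inherits(design, "donor_design")) list(design) else design
    do.call(rbind, lapply(dl, function(d)
      data.frame(donor = d$donor_id, subclone = design_subclones(d),
                 stringsAsFactors = FALSE)))
  } else unique(attributed[, c("donor", "subclone")])
  tally <- function(d, sc) {
    a <- attributed[attributed$donor == d & attributed$subclone == sc, ]
    row <- data.frame(donor = d, subclone = sc, total = nrow(a),
                      pre_existing = sum(a$label == "pre_existing"),
                      culture_acquired = sum(a$label == "culture_acquired"),
                      stringsAsFactors = FALSE)
    if ("consequence" %in% names(attributed)) {
      row$coding <- sum(a$consequence != "noncoding")
      row$synonymous <- sum(a$consequence == "synonymous")
      row$nonsynonymous <- sum(a$consequence == "nonsynonymous")
    }
    row
  }
  out <- do.call(rbind, Map(tally, subs$donor, subs$subclone))
  rownames(out) <- NULL
  if (!is.null(fnr)) {
    f <- fnr[out$subclone]
    out$fnr <- unname(f)
    out$total_fnr_adjusted <- ifelse(is.na(f) | f >= 1, NA_real_,
                                     out$total / (1 - f))
  }
  stopifnot(all(out$total == out$pre_existing + out$culture_acquired))
  out
}

#' Build the germline SNP set for FNR estimation
#'
#' Germline SNPs are substitutions that pass cascade steps 1-4 (quality,
#' coverage in all samples, autosomes) and are called in the donor's biopsy
#' with PNR >= `pnr_call` and more than one alternative read.
#'
#' @param x A [site_table()] for one donor.
#' @param config A [filter_config()].
#' @return A [site_table()] subset: the germline SNP set.
#' @export
build_germline_set <- function(x, config = filter_config()) {
  stopifnot(inherits(x, "site_table"))
  x <- sort_sites(x)
  q <- flag_quality(x, config)$pass
  cov <- pass_coverage(x, config = config)
  auto <- is_autosomal(x, config)
  b <- x$design$biopsy
  bpnr <- compute_pnr(x$ad[, b], x$dp[, b])
  keep <- q & cov & auto & bpnr >= config$pnr_call & x$ad[, b] >= 2
  x[keep]
}

#' Wilson score interval for a binomial proportion
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
wilson_interval <- function(k, n, conf = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Estimate the false-negative rate from germline SNP recovery
#'
#' Re-calls each germline SNP in the subclone under the calling criteria
#' (cascade steps 1-4 plus the step-6 PNR rule); the fraction of germline SNPs
#' missed estimates the FNR of somatic calling in that subclone. A Wilson
#' score interval is attached.
#'
#' @param germline A [site_table()] from [build_germline_set()]. The quality,
#'   coverage and autosome criteria (steps 1-4) are already satisfied by
#'   construction; the step-6 call rule is evaluated here.
#' @param subclone_id Subclone to evaluate.
#' @param config A [filter_config()].
#' @param conf Confidence level for the interval (default 0.95).
#' @return List with `fnr`, `n_germline`, `n_missed`, `conf_low`, `conf_high`.
#' @export
estimate_fnr <- function(germline, subclone_id, config = filter_config(),
                         conf = 0.95) {
  stopifnot(inherits(germline, "site_table"))
  n <- length(germline)
  if (n == 0L) stop("undefined estimate: empty germline SNP set")
  called <- call_subclone(germline, subclone_id, config = config)
  k <- sum(!called)
  ci <- wilson_interval(k, n, conf)
  list(fnr = k / n, n_germline = n, n_missed = k,
       conf_low = unname(ci["lower"]), conf_high = unname(ci["upper"]))
}

#' Surveyed fraction of the autosomal genome
#'
#' Fraction of the autosomal genome with depth at least `min_depth` in every
#' sample of the donor, computed from binned depth tracks (bin-length
#' weighted).
#'
#' @param bins A `depth_bins` data.frame from [simulate_depth_bins()] or
#'   [read_depth_bins()], covering all design samples.
#' @param design A [donor_design()].
#' @param config A [filter_config()]; uses `min_depth` and `autosomes`.
#' @return Fraction in \[0, 1\].
#' @export
surveyed_fraction <- function(bins, design, config = filter_config()) {
  stopifnot(inherits(design, "donor_design"))
  samples <- design_samples(design)
  miss <- setdiff(samples, unique(bins$sample))
  if (length(miss))
    stop("design error: no depth track for sample(s): ",
         paste(miss, collapse = ", "))
  bins <- bins[bins$sample %in% samples & bins$chrom %in% config$autosomes, ]
  if (nrow(bins) == 0L) return(NA_real_)
  depth <- bin_depth(bins)
  key <- paste(bins$chrom, bins$start)
  ok <- tapply(depth >= config$min_depth, key, all)
  width <- tapply(bins$end - bins$start, key, function(w) w[1])
  sum(width[ok]) / sum(width)
}
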