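#' Somatic filter configuration
#'
#' Every threshold of the eight-step somatic base-substitution filter cascade.
#' Defaults are the published hard-filter settings: sites are dropped when
#' QUAL < 100, QD < 1.5, or MQ0 >= 4 with MQ0/DP > 0.1; variant clusters of 3+
#' substitutions within a 10 bp window are dropped; every sample of the donor
#' must reach 20x depth; subclone calls require a proportion of non-reference
#' reads (PNR) >= 0.3, with cross-subclone removal when the other subclone
#' shows 0 < PNR < 0.3 on more than one alternative read.
#'
#' @param min_qual Minimum site quality (QUAL); default 100.
#' @param min_qd Minimum quality-by-depth (QD); default 1.5.
#' @param mq0_min_count,mq0_max_frac HARD_TO_VALIDATE rule: flagged when
#'   MQ0 >= `mq0_min_count` AND MQ0 / total DP > `mq0_max_frac` (defaults 4, 0.1).
#' @param cluster_window,cluster_size SnpCluster rule: `cluster_size` or more
#'   variants within any `cluster_window` bp window (defaults 10 bp, 3).
#' @param min_depth Minimum per-sample depth required in all samples; default 20.
#' @param pnr_call PNR threshold to call a substitution in a subclone; default 0.3.
#' @param cross_min_alt Minimum alternative reads in the other subclone for
#'   cross-subclone removal ("more than one read", so default 2).
#' @param autosomes Chromosome names counted as autosomal.
#' @param known_chroms Optional full set of valid chromosome names; when given,
#'   unseen names raise an error instead of silently failing the autosome test.
#' @param biopsy_evidence_rule How "no evidence in the biopsy" is read:
#'   `"alt0"` (default; zero alternative reads), `"alt_le1"` (at most one), or
#'   `"pnr0"` (PNR exactly zero).
#' @param parental_evidence_rule Rule for attribution: `"alt2_or_pnr"`
#'   (default; parental alt reads >= 2 OR parental PNR >= `pnr_call`),
#'   `"alt1"` (any parental alt read), or `"pnr"` (parental PNR >= `pnr_call`).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_qual = 100, min_qd = 1.5,
                          mq0_min_count = 4, mq0_max_frac = 0.1,
                          cluster_window = 10, cluster_size = 3,
                          min_depth = 20, pnr_call = 0.3, cross_min_alt = 2,
                          autosomes = paste0("chr", 1:22),
                          known_chroms = NULL,
                          biopsy_evidence_rule = c("alt0", "alt_le1", "pnr0"),
                          parental_evidence_rule = c("alt2_or_pnr", "alt1", "pnr")) {
  stopifnot(min_qual >= 0, min_qd >= 0, mq0_min_count >= 0,
            mq0_max_frac >= 0, cluster_window >= 1, cluster_size >= 1,
            min_depth >= 0, cross_min_alt >= 0,
            pnr_call > 0, pnr_call <= 1)
  structure(
    list(min_qual = min_qual, min_qd = min_qd,
         mq0_min_count = mq0_min_count, mq0_max_frac = mq0_max_frac,
         cluster_window = cluster_window, cluster_size = cluster_size,
         min_depth = min_depth, pnr_call = pnr_call,
         cross_min_alt = cross_min_alt,
         autosomes = as.character(autosomes),
         known_chroms = known_chroms,
         biopsy_evidence_rule = match.arg(biopsy_evidence_rule),
         parental_evidence_rule = match.arg(parental_evidence_rule)),
    class = "filter_config")
}

#' Proportion of non-reference reads (PNR)
#'
#' The calling statistic: alternative reads over depth. By convention the PNR
#' of a zero-depth observation is 0.
#'
#' @param alt_reads,depth Non-negative integer vectors (recycled).
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' compute_pnr(6, 20)   # 0.3
#' compute_pnr(0, 0)    # 0, by convention
#' @export
compute_pnr <- function(alt_reads, depth) {
  if (any(alt_reads < 0 | depth < 0))
    stop("read counts must be non-negative")
  if (any(alt_reads > depth))
    stop("consistency error: alt_reads > depth")
  ifelse(depth == 0, 0, alt_reads / depth)
}

#' Site-level hard-filter flags (cascade step 2)
#'
#' Computes the four hard-filter flags per site: HARD_TO_VALIDATE (MQ0 rule on
#' total site depth), LowQual (QUAL below threshold), LowQD (QD below
#' threshold), and SnpCluster (member of a run of `cluster_size` variants
#' spanning less than `cluster_window` bp on one chromosome).
#'
#' @param x A [site_table()] sorted by chromosome then position.
#' @param config A [filter_config()].
#' @return A data.frame of logicals with columns `HARD_TO_VALIDATE`,
#'   `LowQual`, `LowQD`, `SnpCluster` and a `pass` column (no flag set).
#' @export
flag_quality <- function(x, config = filter_config()) {
  stopifnot(inherits(x, "site_table"), inherits(config, "filter_config"))
  s <- x$sites
  if (nrow(s) > 1L &&
      !identical(order(s$chrom, s$pos), seq_len(nrow(s))))
    stop("ordering error: sites must be sorted by (chromosome, position)")
  total_dp <- rowSums(x$dp)
  htv <- s$mq0 >= config$mq0_min_count &
    ifelse(total_dp > 0, s$mq0 / total_dp, 0) > config$mq0_max_frac
  lowqual <- s$qual < config$min_qual
  lowqd <- s$qd < config$min_qd
  cluster <- logical(nrow(s))
  k <- config$cluster_size
  for (ch in unique(s$chrom)) {
    i <- which(s$chrom == ch)
    p <- s$pos[i]
    if (length(p) >= k) {
      for (j in seq_len(length(p) - k + 1L)) {
        if (p[j + k - 1L] - p[j] <= config$cluster_window - 1L)
          cluster[i[j:(j + k - 1L)]] <- TRUE
      }
    }
  }
  out <- data.frame(HARD_TO_VALIDATE = htv, LowQual = lowqual,
                    LowQD = lowqd, SnpCluster = cluster)
  out$pass <- !(htv | lowqual | lowqd | cluster)
  out
}

#' Per-sample coverage filter (cascade step 3)
#'
#' A site passes when every required sample has depth at least `min_depth` and
#' a non-missing genotype (depth cannot be asserted for a missing call).
#'
#' @param x A [site_table()].
#' @param required_samples Sample ids that must all be covered; default all
#'   samples of the design.
#' @param config A [filter_config()].
#' @return Logical vector, one element per site.
#' @export
pass_coverage <- function(x, required_samples = design_samples(x$design),
                          config = filter_config()) {
  stopifnot(inherits(x, "site_table"))
  miss <- setdiff(required_samples, colnames(x$dp))
  if (length(miss))
    stop("design error: sample(s) missing from site table: ",
         paste(miss, collapse = ", "))
  dp <- x$dp[, required_samples, drop = FALSE]
  gt <- x$gt[, required_samples, drop = FALSE]
  ok <- dp >= config$min_depth & gt != "./."
  if (nrow(dp) == 0L) return(logical(0))
  rowSums(ok) == length(required_samples)
}

#' Autosome membership (cascade step 4)
#'
#' @param chrom Character vector of chromosome names (or a [site_table()]).
#' @param config A [filter_config()].
#' @return Logical vector.
#' @export
is_autosomal <- function(chrom, config = filter_config()) {
  if (inherits(chrom, "site_table")) chrom <- chrom$sites$chrom
  if (!is.null(config$known_chroms)) {
    unknown <- setdiff(unique(chrom), config$known_chroms)
    if (length(unknown))
      stop("naming error: unknown chromosome(s): ",
           paste(unknown, collapse = ", "))
  }
  chrom %in% config$autosomes
}

#' Somatic filter: no evidence in the biopsy (cascade step 5)
#'
#' @param x A [site_table()].
#' @param config A [filter_config()]; `biopsy_evidence_rule` selects how
#'   "no evidence" is read (default: zero alternative reads in the biopsy).
#' @return Logical vector: `TRUE` where the site is somatic.
#' @export
is_somatic <- function(x, config = filter_config()) {
  stopifnot(inherits(x, "site_table"))
  b <- x$design$biopsy
  alt <- x$ad[, b]
  dp <- x$dp[, b]
  switch(config$biopsy_evidence_rule,
         alt0 = alt == 0,
         alt_le1 = alt <= 1,
         pnr0 = compute_pnr(alt, dp) == 0)
}

#' Subclone calling with cross-subclone removal (cascade step 6)
#'
#' A substitution is called in a subclone when its PNR is at least `pnr_call`,
#' unless any other subclone of the same donor shows sub-threshold evidence
#' (0 < PNR < `pnr_call` with at least `cross_min_alt` alternative reads), in
#' which case it is removed as likely shared (hence not culture-private and
#' suspect at this stage).
#'
#' @param x A [site_table()].
#' @param subclone_id The subclone being called.
#' @param other_subclone_ids Other subclone(s) of the same donor; default all
#'   remaining subclones in the design.
#' @param config A [filter_config()].
#' @return Logical vector: `TRUE` where called.
#' @export
call_subclone <- function(x, subclone_id,
                          other_subclone_ids =
                            setdiff(design_subclones(x$design), subclone_id),
                          config = filter_config()) {
  stopifnot(inherits(x, "site_table"),
            subclone_id %in% colnames(x$dp))
  pnr <- compute_pnr(x$ad[, subclone_id], x$dp[, subclone_id])
  called <- pnr >= config$pnr_call
  for (o in other_subclone_ids) {
    opnr <- compute_pnr(x$ad[, o], x$dp[, o])
    remove <- opnr > 0 & opnr < config$pnr_call &
      x$ad[, o] >= config$cross_min_alt
    called <- called & !remove
  }
  called
}

#' dbSNP filter (cascade step 7)
#'
#' Removes sites flagged as known polymorphisms.
#'
#' @param x A [site_table()] (or logical dbsnp vector).
#' @return Logical vector: `TRUE` where the site survives (not in dbSNP).
#' @export
filter_dbsnp <- function(x) {
  flags <- if (inherits(x, "site_table")) x$sites$dbsnp else x
  !flags
}

#' Cross-individual filter (cascade step 8)
#'
#' A call is removed when the same substitution (chromosome, position, alt
#' allele) was called in any sample of another donor.
#'
#' @param calls_by_donor Named list: donor id -> named list of per-subclone
#'   call data.frames, each with columns `chrom`, `pos`, `alt` (extra columns
#'   preserved).
#' @return The same structure with shared calls removed.
#' @export
filter_cross_individual <- function(calls_by_donor) {
  stopifnot(is.list(calls_by_donor))
  if (length(calls_by_donor) < 2L) {
    warning("single donor: cross-individual filter is a no-op")
    return(calls_by_donor)
  }
  keys <- lapply(calls_by_donor, function(subs)
    unique(unlist(lapply(subs, site_key), use.names = FALSE)))
  out <- calls_by_donor
  for (d in names(calls_by_donor)) {
    other_keys <- unique(unlist(keys[setdiff(names(keys), d)],
                                use.names = FALSE))
    out[[d]] <- lapply(calls_by_donor[[d]], function(df) {
      df[!(site_key(df) %in% other_keys), , drop = FALSE]
    })
  }
  out
}

cascade_steps <- c(
  "1" = "multi-sample called substitutions",
  "2" = "hard quality filters (HARD_TO_VALIDATE, LowQual, LowQD, SnpCluster)",
  "3" = "coverage >= min_depth in all samples",
  "4" = "autosomal chromosomes",
  "5" = "no evidence in the biopsy (somatic)",
  "6" = "called in a subclone (PNR rule, cross-subclone removal)",
  "7" = "not in dbSNP",
  "8" = "no evidence in the other individual")

# per-donor steps 1-7; returns alive index and per-subclone call indices
cascade_one_donor <- function(x, config) {
  x <- sort_sites(x)
  n <- length(x)
  counts <- integer(7)
  counts[1] <- n
  alive <- seq_len(n)
  q <- flag_quality(x, config)
  alive <- alive[q$pass[alive]]
  counts[2] <- length(alive)
  cov <- pass_coverage(x, config = config)
  alive <- alive[cov[alive]]
  counts[3] <- length(alive)
  auto <- is_autosomal(x, config)
  alive <- alive[auto[alive]]
  counts[4] <- length(alive)
  som <- is_somatic(x, config)
  alive <- alive[som[alive]]
  counts[5] <- length(alive)
  subclones <- design_subclones(x$design)
  calls <- lapply(subclones, function(sc) {
    called <- call_subclone(x, sc, config = config)
    alive[called[alive]]
  })
  names(calls) <- subclones
  alive <- sort(unique(unlist(calls, use.names = FALSE)))
  counts[6] <- length(alive)
  nodb <- filter_dbsnp(x)
  calls <- lapply(calls, function(i) i[nodb[i]])
  alive <- sort(unique(unlist(calls, use.names = FALSE)))
  counts[7] <- length(alive)
  list(x = x, counts = counts, calls = calls)
}

#' Run the eight-step somatic filter cascade
#'
#' Applies the full filter cascade to one or more donors' site tables: hard
#' quality filters, coverage in all samples, autosomes only, no biopsy
#' evidence, subclone PNR calling with cross-subclone removal, dbSNP removal,
#' and (with two or more donors) cross-individual removal. Step 1 is the input
#' call set.
#'
#' @param site_tables A [site_table()] or a list of them (one per donor).
#' @param config A [filter_config()].
#' @return An object of class `cascade_result`: a list with `report` (a
#'   data.frame of survivor counts per donor and step), `calls` (per donor, a
#'   named list of per-subclone [site_table()]s carrying full evidence), and
#'   `config`.
#' @export
run_cascade <- function(site_tables, config = filter_config()) {
  if (inherits(site_tables, "site_table")) site_tables <- list(site_tables)
  stopifnot(all(vapply(site_tables, inherits, NA, "site_table")))
  donors <- vapply(site_tables, function(x) x$design$donor_id, "")
  if (anyDuplicated(donors)) stop("duplicate donor ids across site tables")
  names(site_tables) <- donors
  per_donor <- lapply(site_tables, cascade_one_donor, config = config)
  # step 8 across donors, on call identities
  call_frames <- lapply(per_donor, function(pd)
    lapply(pd$calls, function(i) pd$x$sites[i, c("chrom", "pos", "alt")]))
  if (length(per_donor) >= 2L) {
    kept <- filter_cross_individual(call_frames)
  } else {
    kept <- suppressWarnings(filter_cross_individual(call_frames))
  }
  report <- list()
  calls <- list()
  for (d in donors) {
    pd <- per_donor[[d]]
    final_idx <- lapply(names(pd$calls), function(sc) {
      pd$calls[[sc]][site_key(pd$x$sites[pd$calls[[sc]], ]) %in%
                       site_key(kept[[d]][[sc]])]
    })
    names(final_idx) <- names(pd$calls)
    n8 <- length(unique(unlist(final_idx, use.names = FALSE)))
    counts <- c(pd$counts, n8)
    report[[d]] <- data.frame(donor = d, step = 1:8,
                              description = unname(cascade_steps),
                              n_sites = counts, stringsAsFactors = FALSE)
    calls[[d]] <- lapply(final_idx, function(i) pd$x[i])
  }
  structure(list(report = do.call(rbind, c(report, make.row.names = FALSE)),
                 calls = calls, config = config),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("<cascade_result>\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
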