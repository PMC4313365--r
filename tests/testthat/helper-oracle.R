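# Independent brute-force re-implementation of the filter cascade, written as
# plain per-site loops over the raw matrices. Used only as a test oracle.

oracle_cascade <- function(tables, cfg) {
  per_donor <- lapply(tables, function(x) {
    ord <- order(x$sites$chrom, x$sites$pos)
    x <- x[ord]
    s <- x$sites
    n <- nrow(s)
    samples <- design_samples(x$design)
    subclones <- design_subclones(x$design)
    biopsy <- x$design$biopsy
    alive <- rep(TRUE, n)
    counts <- integer(7)
    counts[1] <- n
    # step 2: hard filters, each recomputed independently per site
    for (i in seq_len(n)) {
      tot <- sum(x$dp[i, ])
      if (s$mq0[i] >= cfg$mq0_min_count && tot > 0 &&
          s$mq0[i] / tot > cfg$mq0_max_frac) alive[i] <- FALSE
      if (s$qual[i] < cfg$min_qual) alive[i] <- FALSE
      if (s$qd[i] < cfg$min_qd) alive[i] <- FALSE
      # cluster: any window of cluster_window bp containing >= cluster_size
      # variants of the same chromosome, this site included
      near <- s$pos[s$chrom == s$chrom[i] &
                      abs(s$pos - s$pos[i]) < cfg$cluster_window]
      for (w in (s$pos[i] - cfg$cluster_window + 1):s$pos[i]) {
        m <- sum(near >= w & near <= w + cfg$cluster_window - 1)
        if (m >= cfg$cluster_size) { alive[i] <- FALSE; break }
      }
    }
    counts[2] <- sum(alive)
    # step 3: coverage in every sample
    for (i in which(alive)) {
      for (sm in samples) {
        if (x$dp[i, sm] < cfg$min_depth || x$gt[i, sm] == "./.")
          alive[i] <- FALSE
      }
    }
    counts[3] <- sum(alive)
    # step 4: autosomes
    for (i in which(alive))
      if (!(s$chrom[i] %in% cfg$autosomes)) alive[i] <- FALSE
    counts[4] <- sum(alive)
    # step 5: no evidence in biopsy
    for (i in which(alive)) {
      ev <- switch(cfg$biopsy_evidence_rule,
                   alt0 = x$ad[i, biopsy] > 0,
                   alt_le1 = x$ad[i, biopsy] > 1,
                   pnr0 = x$dp[i, biopsy] > 0 &&
                     x$ad[i, biopsy] / x$dp[i, biopsy] > 0)
      if (ev) alive[i] <- FALSE
    }
    counts[5] <- sum(alive)
    # step 6: per-subclone PNR call with cross-subclone removal
    calls <- lapply(subclones, function(sc) {
      idx <- integer(0)
      others <- setdiff(subclones, sc)
      for (i in which(alive)) {
        pnr <- if (x$dp[i, sc] == 0) 0 else x$ad[i, sc] / x$dp[i, sc]
        if (pnr < cfg$pnr_call) next
        removed <- FALSE
        for (o in others) {
          op <- if (x$dp[i, o] == 0) 0 else x$ad[i, o] / x$dp[i, o]
          if (op > 0 && op < cfg$pnr_call && x$ad[i, o] >= cfg$cross_min_alt)
            removed <- TRUE
        }
        if (!removed) idx <- c(idx, i)
      }
      idx
    })
    names(calls) <- subclones
    alive6 <- sort(unique(unlist(calls)))
    counts[6] <- length(alive6)
    # step 7: dbSNP
    calls <- lapply(calls, function(idx) idx[!s$dbsnp[idx]])
    counts[7] <- length(unique(unlist(calls)))
    list(x = x, counts = counts, calls = calls)
  })
  names(per_donor) <- vapply(tables, function(x) x$design$donor_id, "")
  # step 8: remove calls seen in any other donor
  keyset <- lapply(per_donor, function(pd) {
    unique(unlist(lapply(pd$calls, function(idx)
      paste(pd$x$sites$chrom[idx], pd$x$sites$pos[idx], pd$x$sites$alt[idx]))))
  })
  out <- list()
  for (d in names(per_donor)) {
    pd <- per_donor[[d]]
    others <- unique(unlist(keyset[setdiff(names(keyset), d)]))
    final <- lapply(pd$calls, function(idx) {
      keep <- integer(0)
      for (i in idx) {
        key <- paste(pd$x$sites$chrom[i], pd$x$sites$pos[i], pd$x$sites$alt[i])
        if (!(key %in% others)) keep <- c(keep, i)
      }
      keep
    })
    counts <- c(pd$counts, length(unique(unlist(final))))
    out[[d]] <- list(counts = counts, x = pd$x, calls = final)
  }
  out
}

# normalized call identities (donor, subclone, chrom, pos, alt) for comparison
cascade_call_keys <- function(res) {
  out <- character(0)
  for (d in names(res$calls))
    for (sc in names(res$calls[[d]])) {
      x <- res$calls[[d]][[sc]]
      if (length(x) > 0)
        out <- c(out, paste(d, sc, x$sites$chrom, x$sites$pos, x$sites$alt))
    }
  sort(out)
}

oracle_call_keys <- function(orc) {
  out <- character(0)
  for (d in names(orc))
    for (sc in names(orc[[d]]$calls)) {
      idx <- orc[[d]]$calls[[sc]]
      s <- orc[[d]]$x$sites
      if (length(idx) > 0)
        out <- c(out, paste(d, sc, s$chrom[idx], s$pos[idx], s$alt[idx]))
    }
  sort(out)
}
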