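#' Multi-sample site table
#'
#' The central evidence container: one row per biallelic site, with site-level
#' quality annotations and per-sample depth (DP), alternative-read (AD) and
#' genotype matrices across the samples of one donor design.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`
#'   (single bases), `qual` (phred-like site quality), `qd` (quality by depth),
#'   `mq0` (zero-mapping-quality read count), `dbsnp` (logical membership flag).
#' @param dp,ad Integer matrices, rows matching `sites`, columns named by
#'   sample id: per-sample depth and alternative-read counts.
#' @param gt Character matrix of genotypes in `{"0/0","0/1","1/1","./."}`.
#' @param design The [donor_design()] the samples belong to.
#' @return An object of class `site_table`.
#' @export
site_table <- function(sites, dp, ad, gt, design) {
  stopifnot(inherits(design, "donor_design"), is.data.frame(sites))
  req <- c("chrom", "pos", "ref", "alt", "qual", "qd", "mq0", "dbsnp")
  if (!all(req %in% names(sites)))
    stop("`sites` must have columns: ", paste(req, collapse = ", "))
  samples <- design_samples(design)
  for (m in list(dp, ad, gt)) {
    if (!is.matrix(m) || nrow(m) != nrow(sites))
      stop("dp/ad/gt must be matrices with one row per site")
    if (!setequal(colnames(m), samples))
      stop("sample columns do not match the design")
  }
  dp <- dp[, samples, drop = FALSE]
  ad <- ad[, samples, drop = FALSE]
  gt <- gt[, samples, drop = FALSE]
  if (nrow(sites) > 0) {
    if (any(ad > dp)) stop("alt_reads exceed depth for some site/sample")
    if (any(sites$pos < 1)) stop("positions must be >= 1")
    if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  }
  structure(list(sites = sites, dp = dp, ad = ad, gt = gt, design = design),
            class = "site_table")
}

#' @export
print.site_table <- function(x, ...) {
  cat("<site_table>", nrow(x$sites), "sites x", ncol(x$dp),
      "samples (donor", x$design$donor_id, ")\n")
  invisible(x)
}

#' Number of sites in a site table
#' @param x A `site_table`.
#' @param ... Unused.
#' @export
length.site_table <- function(x) nrow(x$sites)

#' Subset a site table by row index
#' @param x A `site_table`.
#' @param i Row index (logical or integer).
#' @param ... Unused.
#' @export
`[.site_table` <- function(x, i, ...) {
  site_table(x$sites[i, , drop = FALSE],
             x$dp[i, , drop = FALSE],
             x$ad[i, , drop = FALSE],
             x$gt[i, , drop = FALSE],
             x$design)
}

#' Order a site table by chromosome then position
#' @param x A `site_table`.
#' @return The reordered `site_table`.
#' @export
sort_sites <- function(x) {
  stopifnot(inherits(x, "site_table"))
  x[order(x$sites$chrom, x$sites$pos)]
}

site_key <- function(x) {
  s <- if (inherits(x, "site_table")) x$sites else x
  paste(s$chrom, s$pos, s$alt, sep = ":")
}
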