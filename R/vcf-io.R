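# Multi-sample VCF 4.2 I/O for the donor-design site table.
# Dialect (fixed): QD, MQ0 in INFO; dbSNP membership as the DB INFO flag;
# per-sample FORMAT GT:AD:DP with AD as "ref,alt". The ID column is unused.

#' Write a site table as a multi-sample VCF
#'
#' @param x A [site_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design_vcf <- function(x, path) {
  stopifnot(inherits(x, "site_table"))
  samples <- design_samples(x$design)
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=clonestab"),
    paste0("##clonestab_donor=", x$design$donor_id),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=MQ0,Number=1,Type=Integer,Description=\"Reads with mapping quality zero\">",
    "##INFO=<ID=DB,Number=0,Type=Flag,Description=\"dbSNP membership\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  n <- nrow(x$sites)
  if (n == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  info <- paste0("QD=", format(x$sites$qd, trim = TRUE, scientific = FALSE),
                 ";MQ0=", x$sites$mq0,
                 ifelse(x$sites$dbsnp, ";DB", ""))
  gtcols <- vapply(seq_along(samples), function(j) {
    paste0(x$gt[, j], ":", x$dp[, j] - x$ad[, j], ",", x$ad[, j], ":",
           x$dp[, j])
  }, character(n))
  if (n == 1L) gtcols <- matrix(gtcols, nrow = 1L)
  body <- paste(x$sites$chrom, x$sites$pos, ".", x$sites$ref, x$sites$alt,
                format(x$sites$qual, trim = TRUE, scientific = FALSE), "PASS",
                info, "GT:AD:DP",
                apply(gtcols, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a multi-sample VCF into a site table
#'
#' Parses a VCF 4.x file (via vcfR) and validates its sample columns against a
#' donor design. Consumes per-sample GT, AD and DP, site QUAL, and the QD, MQ0
#' and DB INFO annotations.
#'
#' @param path VCF file path.
#' @param design The expected [donor_design()].
#' @return A [site_table()].
#' @export
read_design_vcf <- function(path, design) {
  stopifnot(inherits(design, "donor_design"))
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[[1]], "##fileformat=VCF"))
    stop("parse error at line 1: not a VCF file")
  header_i <- which(startsWith(lines, "#CHROM"))
  if (length(header_i) != 1L)
    stop("parse error: expected exactly one #CHROM header line")
  cols <- strsplit(lines[header_i], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L)
    stop("parse error at line ", header_i, ": no sample columns")
  file_samples <- cols[-(1:9)]
  samples <- design_samples(design)
  extra <- setdiff(file_samples, samples)
  missing <- setdiff(samples, file_samples)
  if (length(extra))
    stop("design error: file sample(s) not in design: ",
         paste(extra, collapse = ", "))
  if (length(missing))
    stop("design error: design sample(s) absent from file: ",
         paste(missing, collapse = ", "))
  n_body <- length(lines) - header_i
  if (n_body == 0L) {
    empty <- matrix(integer(), 0, length(samples),
                    dimnames = list(NULL, samples))
    return(site_table(
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), qual = numeric(), qd = numeric(),
                 mq0 = integer(), dbsnp = logical(), stringsAsFactors = FALSE),
      dp = empty, ad = empty,
      gt = matrix(character(), 0, length(samples),
                  dimnames = list(NULL, samples)),
      design = design))
  }
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("parse error reading ", path, ": ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  info_field <- function(key) {
    val <- vcfR::extract.info(v, element = key)
    val
  }
  qd <- suppressWarnings(as.numeric(info_field("QD")))
  mq0 <- suppressWarnings(as.integer(info_field("MQ0")))
  info_raw <- v@fix[, "INFO"]
  dbsnp <- grepl("(^|;)DB(;|$)", info_raw)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  ad_raw <- vcfR::extract.gt(v, element = "AD")
  alt_of <- function(s) as.integer(sub("^[0-9]+,", "", s))
  ad <- apply(ad_raw, 2L, alt_of)
  if (is.null(dim(ad))) ad <- matrix(ad, nrow = nrow(gt),
                                     dimnames = dimnames(gt))
  storage.mode(dp) <- "integer"
  sites <- data.frame(
    chrom = unname(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = unname(fix[, "REF"]),
    alt = unname(fix[, "ALT"]),
    qual = as.numeric(fix[, "QUAL"]),
    qd = qd, mq0 = mq0, dbsnp = dbsnp,
    stringsAsFactors = FALSE)
  bad <- which(is.na(sites$pos) | is.na(sites$qual))
  if (length(bad))
    stop("parse error at data line ", bad[1], ": malformed record")
  rownames(gt) <- rownames(dp) <- rownames(ad) <- NULL
  site_table(sites, dp = dp, ad = ad, gt = gt, design = design)
}
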