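#' Donor sample design
#'
#' Describes the sample-role graph for one donor: a reference biopsy, one or
#' more parental clonal cultures, and for each parental clone a matched
#' subclonal culture derived from it after a period of expansion. Somatic
#' variants shared by a parental clone and its subclone pre-date the culture
#' period; variants private to a subclone arose during it.
#'
#' @param donor_id Single string identifying the donor.
#' @param biopsy Sample id of the reference biopsy.
#' @param parental_clones Character vector of parental clonal culture ids.
#' @param subclone_of Named character vector mapping each subclone id to its
#'   parental clone id, e.g. `c(A1 = "A", B1 = "B")`.
#' @return An object of class `donor_design`.
#' @examples
#' donor_design("d1", "d1_biopsy", c("d1_A", "d1_B"),
#'              c(d1_A1 = "d1_A", d1_B1 = "d1_B"))
#' @export
donor_design <- function(donor_id, biopsy, parental_clones, subclone_of) {
  stopifnot(is.character(donor_id), length(donor_id) == 1L,
            is.character(biopsy), length(biopsy) == 1L,
            is.character(parental_clones), length(parental_clones) >= 1L,
            is.character(subclone_of), length(subclone_of) >= 1L)
  if (is.null(names(subclone_of)) || any(!nzchar(names(subclone_of))))
    stop("`subclone_of` must be a named vector (subclone id -> parental clone id)")
  if (!all(subclone_of %in% parental_clones))
    stop("every subclone must map to a parental clone of the same donor")
  ids <- c(biopsy, parental_clones, names(subclone_of))
  if (anyDuplicated(ids))
    stop("sample ids must be unique; biopsy, clones and subclones must be distinct")
  structure(
    list(donor_id = donor_id,
         biopsy = biopsy,
         parental_clones = parental_clones,
         subclone_of = subclone_of),
    class = "donor_design")
}

#' @export
print.donor_design <- function(x, ...) {
  cat("<donor_design> donor:", x$donor_id, "\n")
  cat("  biopsy:  ", x$biopsy, "\n")
  for (s in names(x$subclone_of))
    cat("  lineage: ", x$biopsy, "->", x$subclone_of[[s]], "->", s, "\n")
  invisible(x)
}

#' All sample ids of a design
#'
#' @param design A [donor_design()].
#' @return Character vector: biopsy, parental clones, subclones (in that order).
#' @export
design_samples <- function(design) {
  stopifnot(inherits(design, "donor_design"))
  c(design$biopsy, design$parental_clones, names(design$subclone_of))
}

#' Subclone ids of a design
#' @param design A [donor_design()].
#' @return Character vector of subclone sample ids.
#' @export
design_subclones <- function(design) {
  stopifnot(inherits(design, "donor_design"))
  names(design$subclone_of)
}

#' Default two-donor study design
#'
#' The canonical design of the study this package models: two donors, each with
#' a biopsy, two independently derived parental clonal cultures (A and B), and
#' one subclone per parental clone obtained by a second clonal expansion.
#'
#' @param donor_ids Character vector of donor ids (default `c("donor1","donor2")`).
#' @return A list of [donor_design()] objects, one per donor.
#' @export
default_study_design <- function(donor_ids = c("donor1", "donor2")) {
  lapply(donor_ids, function(d) {
    clones <- paste0(d, "_", c("A", "B"))
    subs <- paste0(d, "_", c("A1", "B1"))
    donor_design(d, paste0(d, "_biopsy"), clones,
                 stats::setNames(clones, subs))
  })
}

#' Synthetic genome model
#'
#' @param names Chromosome names.
#' @param lengths Chromosome lengths in bp.
#' @param autosome Logical vector flagging autosomes.
#' @return A data.frame with columns `chrom`, `length`, `autosome`.
#' @export
genome_model <- function(names, lengths, autosome = rep(TRUE, length(names))) {
  stopifnot(length(names) == length(lengths),
            length(names) == length(autosome),
            all(lengths > 0))
  data.frame(chrom = as.character(names), length = as.numeric(lengths),
             autosome = as.logical(autosome), stringsAsFactors = FALSE)
}

#' Simulation parameters
#'
#' Parameters controlling the synthetic-data generator. Defaults reflect the
#' study conditions this package models: ~36.9x mean autosomal coverage with
#' negative-binomial overdispersion, binomial allele sampling, a small
#' per-read error rate at non-carrier sites, and a configurable fraction of
#' low-quality artifact sites.
#'
#' @param genome A [genome_model()] data.frame.
#' @param n_germline Number of germline SNPs per donor.
#' @param n_pre_existing_per_clone Somatic SNVs acquired in vivo or during
#'   derivation, per parental clone (shared with its subclone).
#' @param n_culture_per_subclone Somatic SNVs acquired during culture, private
#'   to each subclone.
#' @param mean_depth Mean per-sample sequencing depth (default 36.9).
#' @param depth_dispersion Negative-binomial size parameter; larger means
#'   closer to Poisson (default 20).
#' @param artifact_fraction Fraction of additional artifact sites, relative to
#'   the number of real variant sites (default 0.05).
#' @param error_rate Per-read probability of an alternative read at a
#'   non-carrier site (default 1e-3).
#' @param dbsnp_germline_prob Probability a germline SNP carries a dbSNP
#'   membership flag (default 0.95).
#' @param dbsnp_somatic_prob Probability a somatic SNV carries a spurious dbSNP
#'   flag (default 0.01).
#' @param germline_hom_frac Fraction of germline SNPs that are homozygous
#'   (default 1/3, the typical het:hom ~ 2:1 of human genomes).
#' @param cnv_segments Optional data.frame with columns `chrom`, `start`,
#'   `end` (1-based inclusive), `copy_number`, and a list/character column
#'   `carriers` of carrier sample ids (comma-separated string accepted).
#' @param gc_bias_amplitude Amplitude of the smooth GC bias curve applied to
#'   binned read counts (default 0.2).
#' @param bin_noise_sd Log-normal noise sd on binned counts (default 0.1).
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(genome = genome_model(paste0("chr", 1:2), c(5e6, 5e6)),
                       n_germline = 1000,
                       n_pre_existing_per_clone = 100,
                       n_culture_per_subclone = 30,
                       mean_depth = 36.9,
                       depth_dispersion = 20,
                       artifact_fraction = 0.05,
                       error_rate = 1e-3,
                       dbsnp_germline_prob = 0.95,
                       dbsnp_somatic_prob = 0.01,
                       germline_hom_frac = 1 / 3,
                       cnv_segments = NULL,
                       gc_bias_amplitude = 0.2,
                       bin_noise_sd = 0.1) {
  stopifnot(is.data.frame(genome), nrow(genome) >= 1L,
            all(c("chrom", "length", "autosome") %in% names(genome)),
            mean_depth > 0, depth_dispersion > 0,
            n_germline >= 0, n_pre_existing_per_clone >= 0,
            n_culture_per_subclone >= 0)
  probs <- c(artifact_fraction, error_rate, dbsnp_germline_prob,
             dbsnp_somatic_prob, germline_hom_frac)
  if (any(probs < 0 | probs > 1))
    stop("probabilities and fractions must lie in [0, 1]")
  if (!is.null(cnv_segments)) {
    stopifnot(is.data.frame(cnv_segments),
              all(c("chrom", "start", "end", "copy_number", "carriers") %in%
                    names(cnv_segments)),
              all(cnv_segments$chrom %in% genome$chrom),
              all(cnv_segments$end > cnv_segments$start),
              all(cnv_segments$copy_number >= 0))
  }
  structure(
    list(genome = genome, n_germline = n_germline,
         n_pre_existing_per_clone = n_pre_existing_per_clone,
         n_culture_per_subclone = n_culture_per_subclone,
         mean_depth = mean_depth, depth_dispersion = depth_dispersion,
         artifact_fraction = artifact_fraction, error_rate = error_rate,
         dbsnp_germline_prob = dbsnp_germline_prob,
         dbsnp_somatic_prob = dbsnp_somatic_prob,
         germline_hom_frac = germline_hom_frac,
         cnv_segments = cnv_segments,
         gc_bias_amplitude = gc_bias_amplitude,
         bin_noise_sd = bin_noise_sd),
    class = "sim_params")
}

# carriers column may be a list column or comma-separated strings; normalize
# to a list of character vectors
cnv_carrier_list <- function(cnv_segments) {
  if (is.null(cnv_segments)) return(list())
  carr <- cnv_segments$carriers
  if (is.list(carr)) lapply(carr, as.character)
  else strsplit(as.character(carr), ",", fixed = TRUE)
}
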