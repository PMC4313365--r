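# End-to-end orchestration and tabular I/O: simulate (or load) donor data, run
# the filter cascade, attribute calls, estimate FNR, survey coverage, call
# CNVs, and write a consolidated report bundle with provenance.

#' Write / read depth bins as tab-separated tables
#'
#' @param bins A `depth_bins` data.frame.
#' @param path File path.
#' @return `path` invisibly (writer); a `depth_bins` data.frame (reader).
#' @export
write_depth_bins <- function(bins, path) {
  utils::write.table(bins, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_bins
#' @param bin_size Bin width in bp, recorded as an attribute on read.
#' @export
read_depth_bins <- function(path, bin_size = NULL) {
  b <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if (is.null(bin_size)) bin_size <- b$end[1] - b$start[1]
  attr(b, "bin_size") <- bin_size
  class(b) <- c("depth_bins", "data.frame")
  b
}

#' Write bins or segments in BED format (0-based, half-open)
#'
#' @param x data.frame with `chrom`, `start`, `end` plus extra columns.
#' @param path Output path.
#' @param extra_cols Extra columns to carry after the three BED fields.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, extra_cols = setdiff(names(x),
                                                    c("chrom", "start", "end"))) {
  bed <- cbind(x[, c("chrom", "start", "end")], x[, extra_cols, drop = FALSE])
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

provenance_header <- function(seed, config_hash) {
  c(paste0("# clonestab ", as.character(utils::packageVersion("clonestab"))),
    paste0("# seed=", seed),
    paste0("# config_hash=", config_hash))
}

write_tsv_with_provenance <- function(df, path, seed, config_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full genome-stability analysis on simulated donor data
#'
#' Orchestrates every stage on a simulated study: truth and evidence generation
#' for each donor, the eight-step filter cascade (cross-individual step across
#' donors), attribution of calls to pre-existing vs culture-acquired classes,
#' coding-consequence annotation, germline-SNP FNR estimation per subclone,
#' surveyed-genome-fraction computation, and GC-corrected read-depth CNV
#' calling with a binomial-mixture heterozygous-gain test on somatic gains.
#'
#' @param params A [sim_params()].
#' @param designs List of [donor_design()]s (default [default_study_design()]).
#' @param config A [filter_config()]; its `autosomes`/`known_chroms` are
#'   aligned to the simulation genome automatically when left at defaults.
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param out_dir Optional output directory; when given, the report bundle is
#'   written there (TSV/JSON/VCF/BED) with provenance headers.
#' @param bin_size CNV bin width in bp (default 5000).
#' @param n_genes,n_codons Synthetic gene models for coding annotation;
#'   defaults (100 genes x 333 codons on the 10 Mb default genome) put ~1% of
#'   the genome in coding sequence, the human genome-wide coding fraction.
#' @return A list: `filter_report`, `attributed`, `summary`, `fnr`,
#'   `surveyed`, `cnv`, `het_gain_tests`, `truth`, `provenance`.
#' @export
run_full_pipeline <- function(params = sim_params(),
                              designs = default_study_design(),
                              config = NULL, seed = 1L, out_dir = NULL,
                              bin_size = 5000, n_genes = 100, n_codons = 333) {
  if (inherits(designs, "donor_design")) designs <- list(designs)
  if (is.null(config))
    config <- filter_config(
      autosomes = params$genome$chrom[params$genome$autosome],
      known_chroms = params$genome$chrom)
  seed <- as.integer(seed)
  config_hash <- rlang::hash(list(params = unclass(params),
                                  config = unclass(config), seed = seed))
  models <- simulate_gene_models(params$genome, n_genes = n_genes,
                                 n_codons = n_codons, seed = seed + 17L)
  truth <- list(); tables <- list(); bins <- list()
  for (i in seq_along(designs)) {
    d <- designs[[i]]
    truth[[d$donor_id]] <- simulate_truth(d, params, seed + 100L * i, models)
    tables[[d$donor_id]] <- simulate_site_table(truth[[d$donor_id]], d,
                                                params, seed + 100L * i + 1L)
    bins[[d$donor_id]] <- simulate_depth_bins(d, params, bin_size,
                                              seed + 100L * i + 2L)
  }
  cascade <- run_cascade(unname(tables), config)
  attributed <- attribute_calls(cascade, config)
  if (nrow(attributed) > 0)
    attributed <- classify_variants(attributed, models)
  fnr <- list()
  surveyed <- list()
  for (d in designs) {
    germ <- build_germline_set(tables[[d$donor_id]], config)
    for (sc in design_subclones(d))
      fnr[[sc]] <- estimate_fnr(germ, sc, config)
    surveyed[[d$donor_id]] <- surveyed_fraction(bins[[d$donor_id]], d, config)
  }
  fnr_vec <- vapply(fnr, `[[`, 0, "fnr")
  summary <- summarize_stability(attributed, designs, fnr = fnr_vec)
  cnv <- list(); het_tests <- list()
  for (d in designs) {
    segs <- call_cnv(bins[[d$donor_id]], d$biopsy,
                     autosomes = config$autosomes)
    cnv[[d$donor_id]] <- segs
    for (s in names(segs)) {
      som <- segs[[s]][segs[[s]]$somatic & segs[[s]]$copy_state == "gain", ]
      for (k in seq_len(nrow(som))) {
        region <- list(chrom = som$chrom[k], start = som$start[k] + 1,
                       end = som$end[k])
        prof <- informative_snps(tables[[d$donor_id]], region, s, config)
        het_tests[[paste(s, som$chrom[k], som$start[k], sep = ":")]] <-
          tryCatch(test_het_gain(prof),
                   error = function(e) list(error = conditionMessage(e)))
      }
    }
  }
  bundle <- list(filter_report = cascade$report, cascade = cascade,
                 attributed = attributed, summary = summary,
                 fnr = fnr, surveyed = surveyed, cnv = cnv,
                 het_gain_tests = het_tests, truth = truth,
                 provenance = list(seed = seed, config_hash = config_hash,
                                   version = as.character(
                                     utils::packageVersion("clonestab"))))
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir, tables)
  bundle
}

write_report_bundle <- function(bundle, out_dir, tables = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- bundle$provenance$seed
  h <- bundle$provenance$config_hash
  write_tsv_with_provenance(bundle$filter_report,
                            file.path(out_dir, "filter_report.tsv"), seed, h)
  write_tsv_with_provenance(bundle$summary,
                            file.path(out_dir, "stability_summary.tsv"),
                            seed, h)
  if (nrow(bundle$attributed) > 0)
    write_tsv_with_provenance(bundle$attributed,
                              file.path(out_dir, "attributed_calls.tsv"),
                              seed, h)
  seg_all <- list()
  for (d in names(bundle$cnv))
    for (s in names(bundle$cnv[[d]])) {
      seg <- bundle$cnv[[d]][[s]]
      if (nrow(seg)) seg_all[[paste(d, s)]] <- cbind(sample = s, seg)
    }
  if (length(seg_all))
    write_bed(do.call(rbind, c(seg_all, make.row.names = FALSE))[
      , c("chrom", "start", "end", "sample", "copy_state", "mean_log2",
          "somatic")],
      file.path(out_dir, "cnv_segments.bed"))
  if (!is.null(tables))
    for (d in names(tables))
      write_design_vcf(tables[[d]],
                       file.path(out_dir, paste0(d, "_sites.vcf")))
  json <- list(provenance = bundle$provenance,
               surveyed_fraction = bundle$surveyed,
               fnr = bundle$fnr,
               summary = bundle$summary)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Load a run configuration from a YAML file
#'
#' Recognized top-level keys: `seed`, `out_dir`, `bin_size`, `params` (fields
#' of [sim_params()]; `genome` as a list of `{chrom, length, autosome}`
#' records), `filter` (fields of [filter_config()]), `designs` (a list of
#' donor records with `donor_id`, `biopsy`, `parental_clones`, `subclone_of`)
#' and `vcfs` (a map from donor id to a multi-sample VCF path).
#'
#' @param path YAML file path.
#' @return List with `params`, `config`, `seed`, `out_dir`, `bin_size`,
#'   `designs`, `vcfs`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  p <- y$params %||% list()
  if (!is.null(p$genome)) {
    g <- do.call(rbind, lapply(p$genome, as.data.frame))
    p$genome <- genome_model(g$chrom, g$length,
                             if ("autosome" %in% names(g)) g$autosome
                             else rep(TRUE, nrow(g)))
  }
  params <- do.call(sim_params, p)
  config <- if (is.null(y$filter)) NULL else do.call(filter_config, y$filter)
  designs <- if (is.null(y$designs)) NULL else lapply(y$designs, function(d)
    donor_design(d$donor_id, d$biopsy, unlist(d$parental_clones),
                 unlist(d$subclone_of)))
  list(params = params, config = config,
       seed = y$seed %||% 1L, out_dir = y$out_dir,
       bin_size = y$bin_size %||% 5000,
       designs = designs, vcfs = y$vcfs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
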