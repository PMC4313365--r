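# Coding-consequence annotation against minimal gene models: ordered coding
# intervals plus the coding sequence, classification by codon translation.

#' Gene model set
#'
#' @param intervals data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (1-based, inclusive), `rank` (exon order in
#'   transcript orientation, 5' to 3').
#' @param cds Named character vector of coding sequences (one per gene,
#'   transcript orientation; length must equal the summed interval lengths and
#'   be a multiple of 3).
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(intervals, cds) {
  stopifnot(is.data.frame(intervals),
            all(c("gene_id", "chrom", "strand", "start", "end", "rank") %in%
                  names(intervals)),
            all(intervals$end >= intervals$start),
            all(intervals$strand %in% c("+", "-")))
  for (g in unique(intervals$gene_id)) {
    iv <- intervals[intervals$gene_id == g, ]
    iv <- iv[order(iv$rank), ]
    len <- sum(iv$end - iv$start + 1)
    if (!g %in% names(cds)) stop("no coding sequence for gene ", g)
    if (nchar(cds[[g]]) != len)
      stop("coding sequence length mismatch for gene ", g)
    if (len %% 3 != 0)
      stop("coding length of gene ", g, " is not a multiple of 3")
    gpos <- genomic_positions(iv)
    if (anyDuplicated(gpos)) stop("overlapping intervals in gene ", g)
  }
  structure(list(intervals = intervals, cds = cds), class = "gene_models")
}

# genomic positions of a gene's CDS in transcript (5'->3') order
genomic_positions <- function(iv) {
  iv <- iv[order(iv$rank), ]
  unlist(lapply(seq_len(nrow(iv)), function(i) {
    p <- iv$start[i]:iv$end[i]
    if (iv$strand[i] == "-") rev(p) else p
  }), use.names = FALSE)
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify substitutions as noncoding / synonymous / nonsynonymous
#'
#' A variant outside every coding interval is noncoding. Otherwise the affected
#' codon is translated before and after the substitution (reverse-complementing
#' alleles for minus-strand genes) under the standard nuclear genetic code; the
#' variant is synonymous when the amino acid is unchanged. A variant coding in
#' any overlapping model is classified by the first model in `gene_id` order;
#' it counts as coding if coding in any model.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (single bases).
#' @param models A [gene_models()] object.
#' @return `variants` with added columns `consequence` (`"noncoding"`,
#'   `"synonymous"`, `"nonsynonymous"`), `gene_id`, `aa_ref`, `aa_alt`.
#' @export
classify_variants <- function(variants, models) {
  stopifnot(inherits(models, "gene_models"), is.data.frame(variants))
  n <- nrow(variants)
  consequence <- rep("noncoding", n)
  gene <- rep(NA_character_, n)
  aa_ref <- rep(NA_character_, n)
  aa_alt <- rep(NA_character_, n)
  code <- Biostrings::GENETIC_CODE
  gids <- sort(unique(models$intervals$gene_id))
  for (g in gids) {
    iv <- models$intervals[models$intervals$gene_id == g, ]
    gpos <- genomic_positions(iv)
    cds <- strsplit(models$cds[[g]], "")[[1]]
    chrom <- iv$chrom[1]; strand <- iv$strand[1]
    hit <- which(variants$chrom == chrom & variants$pos %in% gpos &
                   consequence == "noncoding")
    for (i in hit) {
      cpos <- match(variants$pos[i], gpos)  # 1-based position in CDS
      ref_t <- variants$ref[i]; alt_t <- variants$alt[i]
      if (strand == "-") {
        ref_t <- comp_base[[ref_t]]
        alt_t <- comp_base[[alt_t]]
      }
      if (cds[cpos] != ref_t)
        stop("consistency error: ref base ", variants$ref[i], " at ",
             chrom, ":", variants$pos[i],
             " does not match gene model ", g)
      codon_i <- (cpos - 1) %/% 3
      codon <- cds[codon_i * 3 + 1:3]
      codon_alt <- codon
      codon_alt[(cpos - 1) %% 3 + 1] <- alt_t
      a0 <- code[[paste(codon, collapse = "")]]
      a1 <- code[[paste(codon_alt, collapse = "")]]
      consequence[i] <- if (a0 == a1) "synonymous" else "nonsynonymous"
      gene[i] <- g; aa_ref[i] <- a0; aa_alt[i] <- a1
    }
  }
  variants$consequence <- consequence
  variants$gene_id <- gene
  variants$aa_ref <- aa_ref
  variants$aa_alt <- aa_alt
  variants
}

# is each (chrom, pos) inside any coding interval?
position_in_cds <- function(chrom, pos, models) {
  iv <- models$intervals
  out <- logical(length(chrom))
  for (i in seq_len(nrow(iv)))
    out <- out | (chrom == iv$chrom[i] & pos >= iv$start[i] & pos <= iv$end[i])
  out
}

# reference base dictated by the gene model at a coding position (genome
# strand), or NA outside coding intervals
cds_ref_base <- function(chrom, pos, models) {
  out <- rep(NA_character_, length(chrom))
  for (g in unique(models$intervals$gene_id)) {
    iv <- models$intervals[models$intervals$gene_id == g, ]
    gpos <- genomic_positions(iv)
    cds <- strsplit(models$cds[[g]], "")[[1]]
    hit <- which(chrom == iv$chrom[1] & pos %in% gpos & is.na(out))
    for (i in hit) {
      b <- cds[match(pos[i], gpos)]
      out[i] <- if (iv$strand[1] == "-") comp_base[[b]] else b
    }
  }
  out
}

#' Simulate synthetic gene models
#'
#' Places non-overlapping genes on the genome, each with 1-3 coding exons, a
#' random strand, and a random in-frame coding sequence starting with ATG.
#'
#' @param genome A [genome_model()] data.frame.
#' @param n_genes Number of genes (default 20).
#' @param n_codons Codons per gene (default 100).
#' @param seed Integer seed.
#' @return A [gene_models()] object.
#' @export
simulate_gene_models <- function(genome, n_genes = 20, n_codons = 100,
                                 seed = 1L) {
  with_local_seed(seed, {
    len <- n_codons * 3
    ivs <- list(); cds <- character(0)
    taken <- lapply(genome$chrom, function(z) integer(0))
    names(taken) <- genome$chrom
    for (k in seq_len(n_genes)) {
      gid <- sprintf("gene%03d", k)
      for (try in 1:100) {
        ci <- sample(nrow(genome), 1, prob = genome$length)
        chrom <- genome$chrom[ci]
        n_ex <- sample(1:3, 1)
        # split len into n_ex in-frame-agnostic chunks
        cuts <- sort(sample(seq_len(len - 1), n_ex - 1))
        exlen <- diff(c(0, cuts, len))
        gaps <- sample(50:500, n_ex)  # intron + upstream offsets
        span <- sum(exlen) + sum(gaps)
        start0 <- sample(genome$length[ci] - span, 1)
        starts <- start0 + cumsum(gaps) + cumsum(c(0, exlen[-n_ex]))
        ends <- starts + exlen - 1
        used <- unlist(Map(seq, starts, ends))
        if (length(intersect(used, taken[[chrom]])) == 0) {
          taken[[chrom]] <- c(taken[[chrom]], used)
          strand <- sample(c("+", "-"), 1)
          rank <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
          ivs[[length(ivs) + 1L]] <- data.frame(
            gene_id = gid, chrom = chrom, strand = strand,
            start = starts, end = ends, rank = rank,
            stringsAsFactors = FALSE)
          cds[gid] <- paste0("ATG", paste(
            sample(c("A", "C", "G", "T"), len - 3, replace = TRUE),
            collapse = ""))
          break
        }
      }
    }
    gene_models(do.call(rbind, c(ivs, make.row.names = FALSE)), cds)
  })
}

#' Write gene models as a GFF-like table plus a CDS FASTA
#'
#' @param models A [gene_models()] object.
#' @param gff_path,fasta_path Output paths (tab-separated intervals; FASTA of
#'   coding sequences).
#' @return Invisibly, the two paths.
#' @export
write_gene_models <- function(models, gff_path, fasta_path) {
  utils::write.table(models$intervals, gff_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(models$cds), fasta_path)
  invisible(c(gff_path, fasta_path))
}

#' Read gene models written by [write_gene_models()]
#'
#' @param gff_path,fasta_path Input paths.
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(gff_path, fasta_path) {
  iv <- utils::read.table(gff_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  gene_models(iv, stats::setNames(as.character(seqs), names(seqs)))
}
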