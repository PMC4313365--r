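---
title: "Methods: genome stability analysis of clonally expanded cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome stability analysis of clonally expanded cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonestab)
```

# Study design and rationale

The analysis targets a clonal-expansion design: per donor, a tissue biopsy is
sequenced alongside clonal cultures derived from single cells of that biopsy
("parental clones") and second-generation clones derived from single cells of
a parental clone ("subclones"). Every somatic variant present in a subclone
was either already present in the founding cell of the parental clone
(*pre-existing*, i.e. acquired in vivo) or arose during culture between the
two cloning steps (*culture-acquired*). Counting and classifying these
variants, and verifying copy-number neutrality, quantifies the genomic
fidelity of the expansion protocol.

`donor_design()` encodes one donor (biopsy id, parental clone ids, a
subclone-to-parent map); `default_study_design()` builds the standard
two-donor layout used throughout.

# Somatic substitution calling

`run_cascade()` applies eight sequential filters to a multi-sample site table
(`site_table`: per-site metadata plus DP/AD/GT matrices over all samples of a
donor). Survivor counts per step are returned as a tidy report.

1. **Input**: all multi-sample called substitutions.
2. **Hard quality filters**: `HARD_TO_VALIDATE` (MQ0 ≥ 4 *and*
   MQ0/total DP > 0.1), `LowQual` (QUAL < 100.0), `LowQD` (QD < 1.5), and
   `SnpCluster`. The cluster filter flags any site belonging to a set of
   ≥ `cluster_size` (default 3) variants on one chromosome whose positions
   fit in a `cluster_window` = 10 bp window, i.e. maximum span 9 bp — so
   positions 100, 105, 109 are all flagged. This span-≤-window−1 reading
   matches the standard variant-filtration clusterWindowSize semantics.
3. **Coverage**: DP ≥ `min_depth` (default 20) in *every* sample of the
   donor, and no missing genotype.
4. **Autosomes** only (`autosomes`, default chr1–chr22).
5. **Somatic**: no evidence in the biopsy. The default rule (`alt0`) demands
   zero ALT reads in the biopsy; `alt_le1` (tolerate a single stray read) and
   `pnr0` are available because bulk-evidence stringency is a genuine design
   choice — a single biopsy ALT read may be error or genuine low-frequency
   in-vivo presence.
6. **Subclone call**: PNR = AD/DP ≥ `pnr_call` (default 0.3) in a subclone.
   A call is removed if another subclone shows sub-threshold evidence
   (0 < PNR < 0.3 *and* AD ≥ `cross_min_alt` = 2) — such shared
   low-frequency sites are inconsistent with a clonal origin and are treated
   as artifacts. The "more than one alternative read" wording behind this
   rule is interpreted as an ALT **read-count** threshold (AD ≥ 2), not an
   allele-count threshold; a single stray read is compatible with sequencing
   error, two or more are not.
7. **dbSNP**: known polymorphisms are removed (likely germline leakage).
8. **Cross-individual**: calls present in another donor are removed (shared
   artifacts); with a single donor this step is a warning no-op.

Numerical conventions: PNR is defined as 0 at DP = 0; sites are processed in
(chrom, pos) sort order; step counts are the number of *distinct sites*
surviving (a site called in both subclones counts once).

`attribute_calls()` labels each subclone call *pre-existing* when the
parental clone shows evidence — default rule `alt2_or_pnr`: AD ≥ 2 **or**
PNR ≥ 0.3 in the parent — and *culture-acquired* otherwise. Stricter
(`pnr`: PNR ≥ 0.3 only) and looser (`alt1`: any ALT read) rules are
provided; the default is deliberately permissive toward pre-existing because
a true pre-existing variant is expected near PNR 0.5 in the parent and two
independent ALT reads are already strong evidence, while misclassifying a
pre-existing variant as culture-acquired would inflate the safety-relevant
count.

# False-negative rate and surveyed fraction

`build_germline_set()` collects high-confidence germline SNPs: sites passing
steps 1–4 with biopsy PNR ≥ 0.3 and biopsy AD > 1. `estimate_fnr()` then
asks what fraction of these the step-6 subclone caller would miss; since
germline SNPs are present in every cell, each miss is a genuine false
negative of the PNR rule at the realized local depth. A Wilson score
interval (closed form, no continuity correction) accompanies the point
estimate. `summarize_stability()` reports per-subclone totals, the
attribution split, coding consequences, and FNR-adjusted totals
(total / (1 − FNR)).

`surveyed_fraction()` computes the bin-length-weighted fraction of the
genome at depth ≥ `min_depth` in **all** samples of the donor jointly — the
joint definition is the correct denominator for variant counts that
themselves require coverage in every sample (step 3).

# Copy-number analysis

`call_cnv()` chains four steps over fixed-width depth bins (BED-style
0-based half-open coordinates; variants use 1-based VCF coordinates):

1. `gc_correct()`: bins are stratified by GC content in strata of width
   0.02; each bin's count is divided by its stratum median (strata with
   < 10 bins are merged into the nearest populated stratum). Stratified
   medians are robust to the segments being sought, provided altered
   segments remain a minority of each stratum.
2. `normalize_bins()`: division by the sample's autosomal median.
3. log2 ratio against the reference (biopsy) sample, then `segment_bins()`:
   bins are classified as loss / neutral / gain by thresholds
   `log2(0.5) + margin` and `log2(1.5) − margin`, and same-class runs are
   merged when they hold ≥ `min_bins` = 10 bins with at most 1 discordant
   bin per 10. **Margin default 0.25**: with realistic bin noise
   (log-normal sd 0.1, i.e. ~0.14 in log2), a small margin such as 0.1
   leaves the gain threshold at 0.485 and misclassifies 20–25% of true
   3-copy bins, which a 1-in-10 discordance budget cannot absorb — true
   gains fragment and are missed. 0.25 places each threshold near the
   midpoint between adjacent copy-state levels (nearest-state assignment:
   gain threshold ≈ 0.335, loss ≈ −0.75), restoring sensitivity without
   inflating false calls (the null specificity test over 20 diploid seeds
   yields zero somatic segments). Both thresholds remain user parameters.
4. Segments are *somatic* if no same-class reference segment reciprocally
   overlaps ≥ 50%.

For a putative heterozygous gain, `informative_snps()` extracts germline
heterozygous SNPs (biopsy PNR in 0.3–0.7) inside the segment and
`test_het_gain()` compares log-likelihoods of a balanced mixture
0.5·Binom(1/3) + 0.5·Binom(2/3) (three copies: the duplicated allele is ALT
or REF with equal probability) versus Binom(1/2) (two copies). A positive
log-likelihood ratio supports a genuine allele-specific gain; the test
requires ≥ 20 informative SNPs by default.

# Coding annotation and growth kinetics

`classify_variants()` translates the affected codon before and after the
substitution (standard genetic code via Biostrings) over `gene_models()`
transcripts, handling minus-strand genes by complementation, and labels
calls synonymous / nonsynonymous / noncoding.

`fit_growth()` fits log-linear least squares `log(count) ~ time`; the
doubling time is ln(2)/rate (NA for non-positive rates). `ammonia_rate()`
converts concentrations to nM, computes the elimination slope (OLS over all
points, or two-point `endpoint`), and reports
−slope·volume_ml/(cells/10⁶) — numerically nM·ml = pmol, so the result is
the amount eliminated per hour per million cells. The worked case 1.5 →
1.0 mM over 24 h in 1 ml with 10⁶ cells gives 20,833.33.

# The synthetic generator

`simulate_truth()` / `simulate_site_table()` / `simulate_depth_bins()`
generate data *at the study conditions by default*; parameters are never
tuned per test. Defaults and rationale (`sim_params()`):

| Parameter | Default | Rationale |
|---|---|---|
| `genome` | 2 chromosomes × 5 Mb | desk-scale; all rates are per-genome counts, not densities |
| `mean_depth` | 36.9 | the study's mean WGS coverage |
| `depth_dispersion` | 20 (negative binomial size) | realistic overdispersion; CV ≈ 0.27 at 37× |
| `n_germline` | 1000 | enough germline SNPs for stable FNR estimates |
| `n_pre_existing_per_clone` | 100 | in-vivo load per founding cell |
| `n_culture_per_subclone` | 30 | culture-acquired load per expansion |
| `germline_hom_frac` | 1/3 | typical human WGS het:hom ≈ 2:1 |
| `error_rate` | 1e-3 | per-read substitution error (Illumina-like) |
| `artifact_fraction` | 0.05 | sites violating one hard filter, equal mix of the three modes |
| `dbsnp_germline_prob` / `dbsnp_somatic_prob` | 0.95 / 0.01 | germline SNPs are mostly known; somatic rarely |
| `gc_bias_amplitude` | 0.2 | exponential GC–depth coupling |
| `bin_noise_sd` | 0.1 | log-normal bin-count noise |

Allele counts are Binomial(DP, p) with p = 0.5 (het carrier), 1 − error
(hom), error (non-carrier); sites inside a heterozygous 3-copy segment use
p = 1/3 or 2/3 with the duplicated allele chosen per site. Depth bins get a
sinusoidal GC landscape (period 2 Mb) and an exponential GC bias; with
`bin_noise_sd = 0` and infinite dispersion the generator is exactly
deterministic, which the tests exploit for closed-form checks.

**What the generator does not emulate**: coverage gaps and mappability
(surveyed fraction is therefore ≈ 1), mutational signatures/spectra
(alleles are uniform), indels and structural variants other than simple
copy-number segments, mapping artifacts beyond the three modeled quality
modes, and contamination. Conclusions about absolute real-data performance
therefore come from the filter logic, not the simulation.

All randomness is confined to explicit integer seeds via an internal
`with_local_seed()` (the global RNG state is saved and restored), and every
pipeline output carries a provenance header (package version, seed, config
hash).

# Running the pipeline

```{r, eval = FALSE}
bundle <- run_full_pipeline(seed = 1, out_dir = "results/run1")
bundle$summary
```

`write_report_bundle()` emits `filter_report.tsv`, `stability_summary.tsv`,
`attributed_calls.tsv`, `cnv_segments.bed`, per-donor multi-sample VCFs and
`report.json`. A command-line front end (subcommands `simulate`, `filter`,
`cnv`, `growth`, `run-all`) lives at
`system.file("scripts", "clonestab-cli.R", package = "clonestab")` and is
configured by YAML files read with `load_run_config()`.
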