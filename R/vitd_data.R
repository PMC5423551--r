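# Accessors for the packaged vitamin D / atopy summary statistics: the four
# 25OHD-lowering variants (per-allele effects on natural-log 25OHD from the
# CaMos replication cohort) and their published associations with asthma
# (UK Biobank + GABRIEL meta-analysis), childhood asthma (GABRIEL), atopic
# dermatitis (EAGLE eczema consortium) and natural-log total serum IgE
# (GABRIEL).

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "ivwmr")
  if (path == "") stop("packaged data file not found: ", file, call. = FALSE)
  path
}

#' Packaged vitamin D instrument metadata
#'
#' The four 25OHD-associated variants used as MR instruments, with locus,
#' pathway classification, the published F-statistics and the per-SNP
#' variance in 25OHD explained. The exposure SEs in
#' [vitd_study_tables()] are back-derived from these F-statistics
#' (`se = |beta| / sqrt(F)`), since the source cohort did not publish them;
#' the F and variance-explained columns themselves are carried verbatim as
#' metadata and are not recomputed from one another (their underlying sample
#' sizes differ).
#'
#' @return Data frame with columns `rsid`, `locus`, `gene_product`,
#'   `mechanism`, `pathway`, `f_stat`, `variance_explained` (fraction).
#' @export
vitd_instruments <- function() {
  meta <- utils::read.delim(.extdata("table1_instruments.tsv"),
                            stringsAsFactors = FALSE)
  meta$pathway <- classify_pathway(meta$locus)
  meta$variance_explained <- meta$variance_explained_pct / 100
  meta$variance_explained_pct <- NULL
  meta
}

#' Packaged GWAS summary tables for the vitamin D / atopy analysis
#'
#' Reads the five packaged summary-statistics tables: the SNP effects on
#' natural-log 25OHD (the exposure) and on each of the four outcomes. Outcome
#' effects published as odds ratios with 95% CIs are converted to log-odds
#' with SEs at load time; the IgE table is on the linear (natural-log IU/ml)
#' scale. All tables are stored in a single consistent allele orientation, so
#' harmonization leaves them unchanged. The asthma table already incorporates
#' the published perfect-proxy substitution for the CYP24A1 variant, which
#' was absent from one contributing biobank (proxy r2 = 1.0).
#'
#' @return Named list of `study_table` objects: `exposure`, `asthma`,
#'   `childhood_asthma`, `atopic_dermatitis`, `ige`.
#' @examples
#' tabs <- vitd_study_tables()
#' mr_ivw(tabs$exposure, tabs$atopic_dermatitis)
#' @export
vitd_study_tables <- function() {
  list(
    exposure = read_summary_table(.extdata("table1_exposure.tsv"),
                                  study_id = "CaMos/SUNLIGHT",
                                  trait = "ln 25OHD", scale = "linear"),
    asthma = read_summary_table(.extdata("table1_asthma.tsv"),
                                study_id = "UK Biobank + GABRIEL",
                                trait = "asthma"),
    childhood_asthma = read_summary_table(
      .extdata("table1_childhood_asthma.tsv"),
      study_id = "GABRIEL", trait = "childhood asthma"),
    atopic_dermatitis = read_summary_table(
      .extdata("table1_atopic_dermatitis.tsv"),
      study_id = "EAGLE", trait = "atopic dermatitis"),
    ige = read_summary_table(.extdata("table1_ige.tsv"),
                             study_id = "GABRIEL", trait = "ln IgE",
                             scale = "linear")
  )
}

#' Packaged instrument-validation inputs
#'
#' Synthetic stand-ins for the external validation inputs: per-instrument
#' confounder-association p-values (body mass index and smoking, from large
#' anthropometric and tobacco-use consortia in the original analysis; only
#' the per-confounder minima were published, so the remaining values here are
#' constructed and the files are labelled synthetic) and pairwise
#' linkage-disequilibrium r-squared values consistent with the published
#' statement that all pairs satisfy r2 <= 0.01.
#'
#' @return List with data frames `confounders` (rsid, confounder, p) and
#'   `ld_pairs` (rsid_a, rsid_b, r2).
#' @export
vitd_validation_inputs <- function() {
  list(
    confounders = utils::read.delim(.extdata("synthetic_confounders.tsv"),
                                    stringsAsFactors = FALSE),
    ld_pairs = utils::read.delim(.extdata("synthetic_ld_pairs.tsv"),
                                 stringsAsFactors = FALSE)
  )
}
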