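# Build a study_table by writing a data frame through the TSV dialect and
# reading it back, so tests exercise the same path users do.
write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
              row.names = FALSE)
  path
}

st <- function(df, study_id = "test", trait = "trait",
               scale = "log_odds", level = 0.95) {
  read_summary_table(write_tsv(df), study_id, trait, scale, level)
}

# one-row SNP records for harmonize_pair tests
rec <- function(rsid = "rs1", ea = "C", oa = "T", beta = 0.1, se = 0.05,
                eaf = NA_real_) {
  data.frame(rsid = rsid, effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se, stringsAsFactors = FALSE)
}
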