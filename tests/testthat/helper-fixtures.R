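# Fixtures built in code at test time.

# The canonical 10-SNP QC fixture: 20 participants; exactly one chrX SNP,
# one indel, two call-rate failures (one of which is also monomorphic, to
# exercise single-fate accounting), one MAF failure and one HWE failure;
# four clean SNPs survive.
make_qc_fixture <- function() {
  n <- 20L
  ids <- sprintf("S%02d", seq_len(n))
  clean <- c(rep(0L, 9), rep(1L, 9), rep(2L, 2))   # MAF 0.325, HWE-happy
  dosage <- cbind(
    snp_clean1 = clean,
    snp_clean2 = rev(clean),
    snp_chrx   = clean,
    snp_indel  = clean,
    snp_cr1    = replace(clean, 1L, NA),           # call rate 0.95
    snp_cr2    = replace(rep(0L, n), 2L, NA),      # call rate + MAF fail
    snp_maf    = rep(0L, n),                       # monomorphic
    snp_hwe    = c(rep(0L, 10), rep(2L, 10)),      # (10, 0, 10): p ~ 1.3e-6
    snp_clean3 = clean,
    snp_clean4 = clean)
  snps <- data.frame(
    snp_id = colnames(dosage),
    chrom = c("1", "2", "X", "5", "6", "7", "8", "9", "10", "11"),
    pos = seq(1000L, by = 1000L, length.out = 10L),
    ref = "A", alt = "G", minor_allele = "G",
    indel = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
              FALSE, FALSE),
    stringsAsFactors = FALSE)
  snps$alt[snps$snp_id == "snp_indel"] <- "GT"
  snps$minor_allele[snps$snp_id == "snp_indel"] <- "GT"
  genotype_matrix(dosage, ids, snps)
}

# small genotype matrix built by hand for scoring tests
make_tiny_gm <- function(dosage, n_ids = nrow(dosage)) {
  m <- ncol(dosage)
  snps <- data.frame(
    snp_id = colnames(dosage),
    chrom = as.character(rep_len(1:22, m)),
    pos = seq_len(m) * 100L,
    ref = "A", alt = "C", minor_allele = "C", indel = FALSE,
    stringsAsFactors = FALSE)
  genotype_matrix(dosage, sprintf("P%02d", seq_len(n_ids)), snps)
}

# compact cohort configuration for fast simulation-based tests
small_config <- function(...) {
  cohort_config(n_participants = 150, n_snps = 24,
                panel_sizes = c(C = 6, F = 6, E = 6), ...)
}

# deltas + phenotypes -> fitted covariates for a cohort, using the truth
# deltas directly (no diary aggregation), for fitting-layer tests
truth_covariates <- function(cohort) {
  tr <- cohort$truth
  phen <- cohort$phenotypes
  i <- match(tr$deltas$participant_id, phen$participant_id)
  data.frame(participant_id = tr$deltas$participant_id,
             gender = phen$sex[i], age = phen$age[i],
             age_sq = phen$age[i]^2,
             delta_c = tr$deltas$delta_c, delta_f = tr$deltas$delta_f,
             delta_e = tr$deltas$delta_e,
             delta_bfm = tr$delta_bfm,
             group = phen$group[i], stringsAsFactors = FALSE)
}
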