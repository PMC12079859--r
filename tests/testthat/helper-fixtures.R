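# shared fixtures, all built in code

# a tiny well-formed variant table
make_variants <- function(n = 3, seed = 1) {
  set.seed(seed)
  beta <- rnorm(n, 0, 0.1)
  se <- runif(n, 0.01, 0.05)
  data.frame(
    variant_id = paste0("rs", seq_len(n)),
    chrom = "1", pos = seq_len(n) * 1000L,
    effect_allele = "A", other_allele = "G",
    eaf = runif(n, 0.1, 0.9), beta = beta, se = se,
    pval = 2 * pnorm(-abs(beta / se)), n = 10000L
  )
}

# force stated p-values while keeping beta/se consistent with them
set_p <- function(df, p) {
  z <- qnorm(p / 2, lower.tail = FALSE)
  df$se <- 0.02
  df$beta <- z * 0.02
  df$pval <- p
  df
}

# harmonized pairs with chosen exposure/outcome betas
make_pairs <- function(beta_exp, beta_out, se_exp = 0.02, se_out = 0.02,
                       eaf = 0.3, n_exp = 50000, n_out = 50000) {
  k <- length(beta_exp)
  data.frame(
    variant_id = paste0("rs", seq_len(k)), chrom = "1", pos = seq_len(k) * 1e5,
    effect_allele = "A", other_allele = "G",
    beta_exp = beta_exp, se_exp = rep_len(se_exp, k),
    eaf_exp = rep_len(eaf, k), pval_exp = 2 * pnorm(-abs(beta_exp / rep_len(se_exp, k))),
    n_exp = rep_len(n_exp, k),
    beta_out = beta_out, se_out = rep_len(se_out, k), eaf_out = rep_len(eaf, k),
    pval_out = 2 * pnorm(-abs(beta_out / rep_len(se_out, k))),
    n_out = rep_len(n_out, k), flipped = FALSE, proxy_of = NA_character_
  )
}

# small LD world: ids on one chromosome with explicit pairwise r2
make_ld <- function(ids, pos, r2_pairs = NULL, window_bp = Inf) {
  ld_reference(data.frame(variant_id = ids, chrom = "1", pos = pos),
               r2_pairs, window_bp = window_bp)
}

# scaled-down simulation for fast tests
small_params <- function(...) {
  sim_params(n_individuals = 1500, n_gwas = 3000, n_eqtl = 300,
             n_blocks = 12, snps_per_block = 8, ...)
}

# max-PP_H4 per variant against the two synthetic tissues
study_pp4 <- function(study, instruments) {
  ta <- assign_tissues(instruments, study$exposure_stats, study$eqtl_panels,
                       tissue_groups = list(A = "tissue_a", B = "tissue_b"))
  pp4_table(ta, variant_ids = instruments$variant_id, tissues = c("A", "B"))
}

# instruments taken from the planted truth (no discovery-selection curse)
truth_instruments <- function(study) {
  inst <- study$exposure_stats[
    study$exposure_stats$variant_id %in% study$truth$variant_id, ]
  class(inst) <- c("instrument_set", class(inst))
  attr(inst, "selection") <- list(p_thresh = 1, r2_thresh = 0.001, window_bp = 1e7)
  inst
}
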