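# Shared fixture builders. Everything is constructed in code; no files.

# A minimal summary-stat data.frame with sensible defaults.
make_stats <- function(snp, beta, se, pval = NULL, chr = "1",
                       pos = seq_along(snp) * 1e6,
                       effect_allele = "A", other_allele = "G",
                       eaf = 0.3, n = 1e5) {
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  data.frame(snp = snp, chr = chr, pos = as.integer(pos),
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pval = pval, n = n,
             stringsAsFactors = FALSE)
}

# Harmonized-instrument data.frame straight from betas.
make_inst <- function(beta_exp, beta_out, se_out, se_exp = 0.01,
                      snp = sprintf("rs%03d", seq_along(beta_exp))) {
  data.frame(snp = snp, beta_exp = beta_exp, se_exp = se_exp,
             beta_out = beta_out, se_out = se_out,
             eaf_exp = 0.3, eaf_out = 0.3,
             status = "aligned", kept = TRUE, reason = NA_character_,
             stringsAsFactors = FALSE)
}

# Aligned instruments read off an uncorrupted synthetic pair (exposure and
# outcome share alleles, so no harmonization algebra is needed).
instruments_from_sim <- function(sim) {
  make_inst(sim$exposure$beta, sim$outcome$beta, sim$outcome$se,
            se_exp = sim$exposure$se, snp = sim$exposure$snp)
}

# Independent oracle: weighted median by explicit cumulative-weight
# interpolation, written directly from the definition.
oracle_weighted_median <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]; w <- w[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (p[1] >= 0.5) return(r[1])
  for (j in seq_along(p)[-1]) {
    if (p[j] >= 0.5) {
      lo <- j - 1
      return(r[lo] + (r[j] - r[lo]) * (0.5 - p[lo]) / (p[j] - p[lo]))
    }
  }
  r[length(r)]
}

# Independent oracle: dense-grid argmax of the weighted normal-kernel
# density with the normal-reference bandwidth.
oracle_mode <- function(ratio, w, phi = 1, grid_n = 20001) {
  h <- phi * 0.9 * min(sd(ratio), IQR(ratio) / 1.349) * length(ratio)^(-1 / 5)
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = grid_n)
  dens <- vapply(grid, function(x) sum(w * dnorm((x - ratio) / h)), numeric(1))
  grid[which.max(dens)]
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
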