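# Allele harmonization: express exposure and outcome effects on the same
# effect allele, inferring strand for palindromic SNPs from allele frequency.

.harmonized_cols <- c("snp", "beta_exp", "se_exp", "beta_out", "se_out",
                      "eaf_exp", "eaf_out", "status", "kept", "reason")

.h_row <- function(snp, exp, out_beta, out_se, out_eaf, status,
                   kept = TRUE, reason = NA_character_) {
  data.frame(snp = snp,
             beta_exp = exp$beta, se_exp = exp$se,
             beta_out = out_beta, se_out = out_se,
             eaf_exp = exp$eaf, eaf_out = out_eaf,
             status = status, kept = kept, reason = reason,
             stringsAsFactors = FALSE)
}

#' Harmonize one exposure/outcome pair onto a shared effect allele
#'
#' Resolves allele orientation between the exposure and outcome rows of a
#' single SNP:
#' \itemize{
#'   \item identical allele pair, same orientation — `aligned`;
#'   \item identical pair, swapped orientation — `flipped`: the outcome beta
#'     is negated and its frequency replaced by `1 - eaf`;
#'   \item non-palindromic pair matching only after complementing the outcome
#'     alleles — `strand_corrected` (then aligned/flipped logic on the
#'     complemented alleles);
#'   \item palindromic pair (A/T or G/C): strand is inferred from allele
#'     frequency. If either side's minor-allele frequency exceeds `maf_limit`
#'     the SNP is discarded as `non-inferable palindromic`; otherwise
#'     frequencies on the same side of 0.5 give `frequency_inferred`
#'     (aligned) and opposite sides give `frequency_inferred_flipped`;
#'   \item irreconcilable allele sets — discarded, `incompatible alleles`.
#' }
#' Palindromic SNPs missing a frequency on either side are discarded
#' (`missing frequency`); a minor-allele frequency exactly equal to
#' `maf_limit` is still inferable.
#'
#' @param exposure,outcome one-row summary-statistic data.frames for the same
#'   rsID.
#' @param maf_limit palindromic inference limit on the minor-allele
#'   frequency, default 0.42.
#' @return one-row data.frame with columns `snp`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`, `eaf_exp`, `eaf_out`, `status`, `kept`, `reason`.
#' @export
harmonize <- function(exposure, outcome, maf_limit = 0.42) {
  if (exposure$snp != outcome$snp)
    stop(mr_error("config", sprintf("snp mismatch: %s vs %s",
                                    exposure$snp, outcome$snp)))
  e1 <- exposure$effect_allele; e2 <- exposure$other_allele
  o1 <- outcome$effect_allele;  o2 <- outcome$other_allele
  pal <- is_palindromic(e1, e2)

  if (pal) {
    # complementation is undetectable: orientation must come from frequency
    same <- identical(c(o1, o2), c(e1, e2))
    swapped <- identical(c(o1, o2), c(e2, e1))
    if (!same && !swapped)
      return(.h_row(exposure$snp, exposure, outcome$beta, outcome$se,
                    outcome$eaf, "discarded", FALSE, "incompatible alleles"))
    if (is.na(exposure$eaf) || is.na(outcome$eaf))
      return(.h_row(exposure$snp, exposure, outcome$beta, outcome$se,
                    outcome$eaf, "discarded", FALSE, "missing frequency"))
    # a swapped palindromic pair reads as the complement strand: fold the
    # reported orientation back before frequency comparison
    beta_o <- if (swapped) -outcome$beta else outcome$beta
    eaf_o  <- if (swapped) 1 - outcome$eaf else outcome$eaf
    maf_e <- pmin(exposure$eaf, 1 - exposure$eaf)
    maf_o <- pmin(outcome$eaf, 1 - outcome$eaf)
    if (maf_e > maf_limit || maf_o > maf_limit)
      return(.h_row(exposure$snp, exposure, outcome$beta, outcome$se,
                    outcome$eaf, "discarded", FALSE,
                    "non-inferable palindromic"))
    same_side <- (exposure$eaf > 0.5) == (eaf_o > 0.5)
    if (same_side)
      return(.h_row(exposure$snp, exposure, beta_o, outcome$se, eaf_o,
                    "frequency_inferred"))
    return(.h_row(exposure$snp, exposure, -beta_o, outcome$se, 1 - eaf_o,
                  "frequency_inferred_flipped"))
  }

  orient <- function(a1, a2, strand) {
    if (identical(c(a1, a2), c(e1, e2)))
      .h_row(exposure$snp, exposure, outcome$beta, outcome$se, outcome$eaf,
             if (strand) "strand_corrected" else "aligned")
    else if (identical(c(a1, a2), c(e2, e1)))
      .h_row(exposure$snp, exposure, -outcome$beta, outcome$se,
             if (is.na(outcome$eaf)) NA_real_ else 1 - outcome$eaf,
             if (strand) "strand_corrected" else "flipped")
    else NULL
  }
  res <- orient(o1, o2, FALSE)
  if (is.null(res))
    res <- orient(unname(.complement[o1]), unname(.complement[o2]), TRUE)
  if (is.null(res))
    res <- .h_row(exposure$snp, exposure, outcome$beta, outcome$se,
                  outcome$eaf, "discarded", FALSE, "incompatible alleles")
  res
}

#' Harmonize all shared SNPs between two summary-statistic tables
#'
#' Inner join on rsID, then [harmonize()] per pair. SNPs present in the
#' exposure but absent from the outcome are returned separately — they are
#' the candidates for LD proxy search.
#'
#' @inheritParams harmonize
#' @param exposures,outcomes summary-statistic data.frames.
#' @return list with `instruments` (kept rows), `discarded` (rows with
#'   `kept = FALSE`), `tally` (named counts by discard reason), and
#'   `absent` (exposure rsIDs missing from the outcome table).
#' @export
harmonize_all <- function(exposures, outcomes, maf_limit = 0.42) {
  shared <- intersect(exposures$snp, outcomes$snp)
  if (!length(shared))
    stop(mr_error("degenerate", "no shared instruments between exposure and outcome"))
  rows <- lapply(shared, function(s) {
    harmonize(exposures[exposures$snp == s, , drop = FALSE],
              outcomes[outcomes$snp == s, , drop = FALSE],
              maf_limit = maf_limit)
  })
  all <- do.call(rbind, rows)
  list(instruments = all[all$kept, , drop = FALSE],
       discarded   = all[!all$kept, , drop = FALSE],
       tally       = table_tally(all$reason[!all$kept]),
       absent      = setdiff(exposures$snp, outcomes$snp))
}

#' Write harmonized instruments as TSV
#' @param instruments harmonized data.frame.
#' @param path output path.
#' @export
write_harmonized <- function(instruments, path) {
  utils::write.table(instruments[, .harmonized_cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
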