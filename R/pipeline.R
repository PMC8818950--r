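# End-to-end orchestration: read -> significance filter -> clump -> outcome
# lookup with proxy fallback -> harmonize -> estimate -> sensitivity.

#' Build a run configuration
#'
#' Defaults follow the conventional analysis settings: genome-wide
#' significance 5e-8, clumping at r2 0.01 within a 10,000 kb window, proxy
#' minimum r2 0.8, palindromic inference limit MAF 0.42, all five
#' estimators, Bonferroni correction over 5 methods.
#'
#' @param exposure,outcome paths to summary-statistic tables, or data.frames.
#' @param ld path to an LD TSV, or an [ld_matrix()], or `NULL`.
#' @param exposure_map,outcome_map [column_map()]s for non-canonical dialects.
#' @param pval_threshold instrument significance cutoff.
#' @param clump_r2,clump_kb clumping parameters.
#' @param proxy_r2 minimum r2 for outcome proxy lookup.
#' @param maf_limit palindromic inference limit.
#' @param methods estimator names to run.
#' @param n_boot bootstrap replicates for median/mode standard errors.
#' @param seed integer seed (required; recorded in the report).
#' @param bonferroni_m number of tests for the corrected threshold.
#' @param ivw_variant `"fixed"` or `"multiplicative"`.
#' @return list of class `mr_config`.
#' @export
mr_config <- function(exposure, outcome, ld = NULL,
                      exposure_map = column_map(), outcome_map = column_map(),
                      pval_threshold = 5e-8, clump_r2 = 0.01,
                      clump_kb = 10000, proxy_r2 = 0.8, maf_limit = 0.42,
                      methods = c("ivw", "egger", "weighted_median",
                                  "simple_mode", "weighted_mode"),
                      n_boot = 1000, seed, bonferroni_m = 5,
                      ivw_variant = c("fixed", "multiplicative")) {
  if (missing(seed)) stop(mr_error("config", "seed is required"))
  ivw_variant <- match.arg(ivw_variant)
  structure(as.list(environment()), class = "mr_config")
}

.load_table <- function(x, map) {
  if (is.data.frame(x)) x else read_summary_stats(x, map)
}

#' Run the full two-sample MR analysis
#'
#' Stages, in order: read both tables; keep genome-wide significant exposure
#' SNPs; LD-clump them to independent instruments; look each up in the
#' outcome, falling back to the best LD proxy at `proxy_r2` for missing
#' ones; harmonize onto shared effect alleles; run the requested estimators;
#' compute the sensitivity diagnostics. Every significant exposure SNP ends
#' in exactly one provenance bin (`selected`, `clumped_out`, `proxied`,
#' `unmatched`, `discarded`).
#'
#' @param config an [mr_config()].
#' @return list of class `mr_report`: `estimates` (named `mr_estimate`s),
#'   `estimates_table`, `sensitivity`, `provenance`, `tally`, `config`,
#'   `seed`, `version`.
#' @export
run_mr <- function(config) {
  stopifnot(inherits(config, "mr_config"))
  expo <- .load_table(config$exposure, config$exposure_map)
  outc <- .load_table(config$outcome, config$outcome_map)
  ld <- if (is.character(config$ld)) read_ld_matrix(config$ld) else config$ld

  sig <- filter_genome_wide_significant(expo, config$pval_threshold)
  if (nrow(sig) < 1L)
    stop(mr_error("degenerate", "no genome-wide significant exposure SNPs"))
  clumped <- ld_clump(sig, ld, config$clump_r2, config$clump_kb)
  provenance <- data.frame(snp = sig$snp,
                           bin = ifelse(sig$snp %in% clumped$snp,
                                        "selected", "clumped_out"),
                           detail = NA_character_, stringsAsFactors = FALSE)

  # outcome lookup with proxy fallback for clumped index SNPs
  missing_ids <- setdiff(clumped$snp, outc$snp)
  proxy_rows <- list()
  for (m in missing_ids) {
    cand <- outc[!(outc$snp %in% clumped$snp), , drop = FALSE]
    pr <- find_proxy(m, cand, ld, config$proxy_r2)
    i <- match(m, provenance$snp)
    if (is.null(pr)) {
      provenance$bin[i] <- "unmatched"
    } else {
      provenance$bin[i] <- "proxied"
      provenance$detail[i] <- sprintf("proxy=%s r2=%.3f", pr$snp,
                                      attr(pr, "proxy_r2"))
      # the proxy's own exposure row must exist to form the pair
      if (pr$snp %in% expo$snp) proxy_rows[[m]] <- pr$snp
      else provenance$bin[i] <- "unmatched"
    }
  }
  use_exp <- clumped[clumped$snp %in% outc$snp, , drop = FALSE]
  if (length(proxy_rows))
    use_exp <- rbind(use_exp,
                     expo[expo$snp %in% unlist(proxy_rows), , drop = FALSE])

  h <- harmonize_all(use_exp, outc, config$maf_limit)
  disc <- h$discarded$snp
  idx <- provenance$snp %in% disc & provenance$bin == "selected"
  provenance$bin[idx] <- "discarded"
  provenance$detail[idx] <-
    h$discarded$reason[match(provenance$snp[idx], h$discarded$snp)]
  inst <- h$instruments
  if (nrow(inst) < 2L)
    stop(mr_error("degenerate", paste0(
      "fewer than 2 kept instruments; provenance: ",
      paste(sprintf("%s=%s", provenance$snp, provenance$bin), collapse = ", "))))

  est <- mr_estimate_all(inst, methods = config$methods,
                         n_boot = config$n_boot, seed = config$seed,
                         ivw_variant = config$ivw_variant)
  sens <- sensitivity_report(inst, bonferroni_m = config$bonferroni_m)
  tab <- estimates_table(est)
  tab$significant <- tab$pval < sens$bonferroni_alpha
  structure(list(
    estimates = est, estimates_table = tab, sensitivity = sens,
    instruments = inst, provenance = provenance,
    tally = c(table(provenance$bin)), config = config, seed = config$seed,
    version = as.character(utils::packageVersion("mrpipe"))),
    class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat("MR run:", nrow(x$instruments), "instruments;",
      paste(sprintf("%s=%d", names(x$tally), x$tally), collapse = " "), "\n")
  for (e in x$estimates) print(e)
  if (!is.null(x$sensitivity$q_ivw))
    cat(sprintf("Cochran's Q = %.2f (df %d, p = %.3g)\n",
                x$sensitivity$q_ivw$Q, x$sensitivity$q_ivw$df,
                x$sensitivity$q_ivw$p))
  invisible(x)
}

.table2_order <- c("egger", "weighted_median", "ivw", "simple_mode",
                   "weighted_mode")
.table2_labels <- c(egger = "MR Egger", weighted_median = "Weighted median",
                    ivw = "Inverse variance weighted",
                    simple_mode = "Simple mode",
                    weighted_mode = "Weighted mode",
                    wald_ratio = "Wald ratio")

#' Combine run reports into a publication-style long table
#'
#' One row per (exposure, outcome, method), methods in the conventional
#' order (MR Egger, Weighted median, Inverse variance weighted, Simple mode,
#' Weighted mode), with a star on p-values below the Bonferroni-corrected
#' threshold.
#'
#' @param reports list of `mr_report`s (or a single report).
#' @param labels optional data.frame with `exposure`/`outcome` labels, one
#'   row per report.
#' @return data.frame with columns `exposure`, `outcome`, `method`, `nsnp`,
#'   `beta`, `se`, `pval`, `starred`.
#' @export
format_table2 <- function(reports, labels = NULL) {
  if (inherits(reports, "mr_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1)
  rows <- lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    t <- r$estimates_table
    t <- t[order(match(t$method, .table2_order)), , drop = FALSE]
    if (!is.null(labels)) {
      t$exposure <- labels$exposure[i]; t$outcome <- labels$outcome[i]
    }
    data.frame(exposure = t$exposure, outcome = t$outcome,
               method = unname(.table2_labels[t$method]), nsnp = t$nsnp,
               beta = t$beta, se = t$se, pval = t$pval,
               starred = t$significant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a run report to an output directory
#'
#' Writes `estimates.tsv` (publication layout), `sensitivity.json`,
#' `provenance.tsv` and `run.log`.
#'
#' @param report an `mr_report`.
#' @param out_dir directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(format_table2(report),
                     file.path(out_dir, "estimates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  s <- report$sensitivity
  sens <- list(q_ivw = s$q_ivw, q_egger = s$q_egger,
               egger_intercept = s$egger_intercept,
               funnel_asymmetry = s$funnel$asymmetry,
               f_stats = as.list(s$f_stats),
               bonferroni_alpha = s$bonferroni_alpha,
               seed = report$seed, version = report$version)
  jsonlite::write_json(sens, file.path(out_dir, "sensitivity.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(report$provenance, file.path(out_dir, "provenance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(s$loo))
    utils::write.table(s$loo, file.path(out_dir, "leave_one_out.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(s$funnel$data, file.path(out_dir, "funnel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("mrpipe %s seed=%d", report$version, report$seed),
               sprintf("%s: %d", names(report$tally), report$tally)),
             file.path(out_dir, "run.log"))
  invisible(out_dir)
}
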