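# Canonical column order shared by the reader, writer and the synthetic
# generator. `n` is optional on input.
.canonical_fields <- c("snp", "chr", "pos", "effect_allele", "other_allele",
                       "eaf", "beta", "se", "pval", "n")
.required_fields  <- setdiff(.canonical_fields, "n")

#' Build a column map for a summary-statistic file dialect
#'
#' Maps the canonical field names (`snp`, `chr`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`) to the header names used
#' by a particular file. Fields not supplied default to their canonical names,
#' so `column_map()` with no arguments describes the canonical dialect.
#'
#' @param ... named character scalars, e.g. `snp = "variant_id"`.
#' @param .json optional path to a JSON file holding such a mapping; entries
#'   in `...` override it.
#' @return a named character vector of class `mr_column_map`.
#' @examples
#' column_map(snp = "rsid", pval = "p_value")
#' @export
column_map <- function(..., .json = NULL) {
  map <- stats::setNames(.canonical_fields, .canonical_fields)
  if (!is.null(.json)) {
    j <- jsonlite::read_json(.json, simplifyVector = TRUE)
    map[names(j)] <- unlist(j)
  }
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("column_map entries must be named", call. = FALSE)
    bad <- setdiff(names(dots), .canonical_fields)
    if (length(bad))
      stop("unknown canonical field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    map[names(dots)] <- unlist(dots)
  }
  if (anyDuplicated(map))
    stop("column_map maps two canonical fields to the same header",
         call. = FALSE)
  structure(map, class = "mr_column_map")
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) {
  unname(.complement[a1] == a2)
}

# Validate one parsed table row-wise; returns list(keep = logical, reason =
# character). Reasons follow the rejection-tally vocabulary used in tests.
.validate_rows <- function(df) {
  n <- nrow(df)
  reason <- character(n)
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[reason == "" & cond] <<- why
  }
  valid_allele <- function(a) !is.na(a) & a %in% names(.complement)
  flag(is.na(df$snp) | df$snp == "", "missing snp id")
  flag(!valid_allele(df$effect_allele) | !valid_allele(df$other_allele),
       "non-SNP allele")
  flag(valid_allele(df$effect_allele) & valid_allele(df$other_allele) &
         df$effect_allele == df$other_allele, "identical alleles")
  flag(is.na(df$beta), "missing beta")
  flag(is.na(df$se) | df$se <= 0, "nonpositive se")
  flag(is.na(df$pval) | df$pval < 0 | df$pval > 1, "invalid pval")
  # eaf may be missing (flagged, handled at harmonization) but if present must
  # be a proper frequency
  flag(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "invalid eaf")
  flag(is.na(df$pos) | df$pos < 1, "invalid position")
  dup <- duplicated(df$snp) | duplicated(df$snp, fromLast = TRUE)
  flag(!is.na(df$snp) & dup, "duplicate snp id")
  list(keep = reason == "", reason = reason)
}

#' Read a GWAS summary-statistic table
#'
#' Reads a tab- or comma-delimited table (delimiter auto-detected from the
#' header line), renames columns through `column_map`, coerces types,
#' uppercases alleles, and drops rows violating the record invariants
#' (biallelic single-nucleotide alleles, `se > 0`, `0 < eaf < 1`,
#' `0 <= pval <= 1`, unique rsIDs). Rejections are tallied per reason in the
#' `"rejections"` attribute of the result.
#'
#' @param path file path.
#' @param map an [column_map()]; defaults to the canonical dialect.
#' @return a `data.frame` with the canonical columns, attribute `rejections`
#'   (named integer vector of drop counts by reason).
#' @export
read_summary_stats <- function(path, map = column_map()) {
  if (!file.exists(path))
    stop(mr_error("config", sprintf("summary-statistic file not found: %s", path)))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           na.strings = c("NA", "", "."))
  missing_cols <- setdiff(unname(map[.required_fields]), names(raw))
  if (length(missing_cols))
    stop(mr_error("config", sprintf("mapped column(s) absent from %s: %s",
                                    path, paste(missing_cols, collapse = ", "))))
  df <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
    snp           = raw[[map[["snp"]]]],
    chr           = as.character(raw[[map[["chr"]]]]),
    pos           = suppressWarnings(as.integer(raw[[map[["pos"]]]])),
    effect_allele = toupper(raw[[map[["effect_allele"]]]]),
    other_allele  = toupper(raw[[map[["other_allele"]]]]),
    eaf           = suppressWarnings(as.numeric(raw[[map[["eaf"]]]])),
    beta          = suppressWarnings(as.numeric(raw[[map[["beta"]]]])),
    se            = suppressWarnings(as.numeric(raw[[map[["se"]]]])),
    pval          = suppressWarnings(as.numeric(raw[[map[["pval"]]]]))
  )
  df$n <- if (map[["n"]] %in% names(raw))
    suppressWarnings(as.numeric(raw[[map[["n"]]]])) else NA_real_
  v <- .validate_rows(df)
  out <- df[v$keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    stop(mr_error("degenerate", sprintf("no valid rows in %s", path)))
  attr(out, "rejections") <- table_tally(v$reason[!v$keep])
  out
}

table_tally <- function(reasons) {
  if (!length(reasons)) return(stats::setNames(integer(0), character(0)))
  tab <- table(reasons)
  stats::setNames(as.integer(tab), names(tab))
}

#' Write summary statistics in the canonical TSV dialect
#'
#' @param records data.frame of summary statistics.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(records, path) {
  cols <- intersect(.canonical_fields, names(records))
  utils::write.table(records[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep genome-wide significant associations
#'
#' Strict inequality `pval < threshold`, preserving input order. The
#' conventional genome-wide threshold 5e-8 is the default.
#'
#' @param records summary-statistic data.frame.
#' @param threshold p-value cutoff in (0, 1].
#' @return the subset of `records` with `pval < threshold`.
#' @export
filter_genome_wide_significant <- function(records, threshold = 5e-8) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 1)
  out <- records[records$pval < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Classed conditions so the pipeline / CLI can map failures to exit codes.
mr_error <- function(class, message) {
  structure(class = c(paste0("mr_", class, "_error"), "error", "condition"),
            list(message = message, call = NULL))
}
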