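# Instrument selection: LD clumping, proxy lookup, instrument strength.

#' Construct an LD matrix object
#'
#' @param r2 square symmetric matrix of pairwise squared correlations in
#'   \[0, 1\] with unit diagonal.
#' @param snp_ids rsIDs labelling rows/columns (defaults to dimnames).
#' @return an object of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, snp_ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(snp_ids)) stop("ld_matrix requires snp ids", call. = FALSE)
  if (anyDuplicated(snp_ids)) stop("duplicate snp ids in LD matrix", call. = FALSE)
  if (nrow(r2) != ncol(r2) || nrow(r2) != length(snp_ids))
    stop("LD matrix must be square with one id per row", call. = FALSE)
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE))
    stop("LD r2 entries must lie in [0, 1]", call. = FALSE)
  if (any(abs(r2 - t(r2)) > 1e-8, na.rm = TRUE))
    stop("LD matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(r2) - 1) > 1e-8))
    stop("LD matrix diagonal must equal 1", call. = FALSE)
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, r2 = r2), class = "ld_matrix")
}

#' Read an LD matrix from TSV
#'
#' Accepts either the long format (columns `snp_a`, `snp_b`, `r2`;
#' symmetrized on load, unlisted pairs set to 0) or a square matrix with an
#' rsID header row and first column.
#'
#' @param path file path.
#' @return an [ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (identical(tolower(header[seq_len(min(3, length(header)))]),
                c("snp_a", "snp_b", "r2"))) {
    long <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    ids <- sort(unique(c(long$snp_a, long$snp_b)))
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    m[cbind(long$snp_a, long$snp_b)] <- long$r2
    m[cbind(long$snp_b, long$snp_a)] <- long$r2
    diag(m) <- 1
    ld_matrix(m, ids)
  } else {
    m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                     row.names = 1, check.names = FALSE))
    ld_matrix(m)
  }
}

# Pairwise r2 with "unlinked unless stated" semantics for SNPs absent from
# the matrix; NA means both present but the entry itself is missing.
.ld_lookup <- function(ld, a, b) {
  if (is.null(ld)) return(0)
  ids <- ld$snp_ids
  if (!(a %in% ids) || !(b %in% ids)) return(0)
  ld$r2[a, b]
}

#' Greedy LD clumping
#'
#' Sorts records by ascending p-value (ties broken by rsID) and repeatedly
#' takes the best remaining SNP as an index, discarding every remaining SNP on
#' the same chromosome within `window_kb` whose squared correlation with the
#' index exceeds `r2_threshold`. SNPs absent from `ld` are treated as unlinked.
#'
#' @param records summary-statistic data.frame with `chr` and `pos`.
#' @param ld an [ld_matrix()] or `NULL` (all SNPs treated as unlinked). A pair
#'   present in the matrix whose entry is `NA` raises an
#'   `LD information required` error — co-located SNPs are never silently
#'   assumed independent.
#' @param r2_threshold squared-correlation cutoff, default 0.01.
#' @param window_kb distance window in kilobases, default 10000 (10 Mb).
#' @return the retained index SNPs, in selection order.
#' @export
ld_clump <- function(records, ld = NULL, r2_threshold = 0.01,
                     window_kb = 10000) {
  stopifnot(r2_threshold >= 0, r2_threshold <= 1, window_kb > 0)
  if (nrow(records) <= 1L) return(records)
  ord <- order(records$pval, records$snp)
  pool <- records[ord, , drop = FALSE]
  keep <- integer(0)
  alive <- rep(TRUE, nrow(pool))
  window_bp <- window_kb * 1000
  for (i in seq_len(nrow(pool))) {
    if (!alive[i]) next
    keep <- c(keep, i)
    idx <- pool[i, ]
    js <- which(alive & seq_len(nrow(pool)) > i)
    for (j in js) {
      cand <- pool[j, ]
      if (cand$chr != idx$chr) next
      if (abs(cand$pos - idx$pos) > window_bp) next
      r2 <- .ld_lookup(ld, idx$snp, cand$snp)
      if (is.na(r2))
        stop(mr_error("config", sprintf(
          "LD information required for co-located SNPs %s and %s",
          idx$snp, cand$snp)))
      if (r2 > r2_threshold) alive[j] <- FALSE
    }
  }
  out <- pool[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find an LD proxy for a SNP missing from the outcome table
#'
#' Returns the available SNP with maximal r2 to `target`, provided
#' `r2 >= min_r2`; ties broken by lowest p-value, then lexicographic rsID.
#'
#' @param target rsID absent from `available`.
#' @param available candidate summary-statistic data.frame.
#' @param ld an [ld_matrix()] covering `target` and candidates.
#' @param min_r2 minimum acceptable squared correlation, default 0.8.
#' @return a one-row data.frame, or `NULL` when no candidate qualifies.
#' @export
find_proxy <- function(target, available, ld, min_r2 = 0.8) {
  stopifnot(min_r2 > 0, min_r2 <= 1)
  if (target %in% available$snp)
    stop(mr_error("config", sprintf(
      "proxy target %s already present in the available table", target)))
  if (is.null(ld) || !(target %in% ld$snp_ids)) return(NULL)
  r2 <- vapply(available$snp, function(s) {
    v <- .ld_lookup(ld, target, s)
    if (is.na(v)) 0 else v
  }, numeric(1))
  ok <- which(r2 >= min_r2)
  if (!length(ok)) return(NULL)
  ord <- ok[order(-r2[ok], available$pval[ok], available$snp[ok])]
  out <- available[ord[1L], , drop = FALSE]
  attr(out, "proxy_r2") <- unname(r2[ord[1L]])
  rownames(out) <- NULL
  out
}

#' Single-SNP instrument-strength F-statistic
#'
#' The single-instrument approximation `(beta/se)^2`; values above ~10 are
#' conventionally taken to indicate limited weak-instrument bias.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), all `> 0`.
#' @return nonnegative F value(s).
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) stop(mr_error("degenerate", "f_statistic requires se > 0"))
  (beta / se)^2
}
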