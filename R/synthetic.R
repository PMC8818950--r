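# Synthetic paired GWAS summary statistics under a known causal model: the
# test bed for clumping, harmonization, estimation and the diagnostics.

#' Define a synthetic two-sample MR scenario
#'
#' Encodes the generative model: per-SNP true exposure effects with spread
#' `beta_x_sd`, a shared causal effect `theta` carrying them into the
#' outcome, optional per-SNP direct (pleiotropic) effects drawn from
#' `normal(pleiotropy_mean, pleiotropy_sd)` independently of instrument
#' strength (so balanced pleiotropy satisfies the InSIDE condition and
#' `pleiotropy_mean != 0` makes it directional), GWAS sampling noise driven
#' by the two sample sizes through `se = 1/sqrt(2 n f (1-f))`, and
#' harmonization corruptions (allele swaps and strand complements) applied
#' only to the emitted outcome table.
#'
#' @param nsnp instrument count.
#' @param theta true causal effect (log-odds per unit exposure).
#' @param pleiotropy_mean,pleiotropy_sd direct-effect distribution; mean 0 is
#'   balanced, nonzero directional.
#' @param beta_x_sd spread of true exposure effects.
#' @param n_exp,n_out GWAS sample sizes for the exposure and outcome studies.
#' @param maf_range allele-frequency interval frequencies are drawn from.
#' @param frac_palindromic fraction of SNPs given A/T or G/C alleles.
#' @param frac_palindromic_high among palindromic SNPs, the share whose
#'   frequency is forced into the non-inferable band (MAF > 0.42).
#' @param frac_allele_swapped,frac_strand_flipped corruption rates for the
#'   outcome table.
#' @param ld_blocks list of `c(size, r2)` pairs; SNPs not covered are
#'   unlinked singletons.
#' @param seed integer seed; the same scenario and seed reproduce the tables
#'   exactly.
#' @return list of class `mr_scenario`.
#' @export
mr_scenario <- function(nsnp = 50, theta = 0.5,
                        pleiotropy_mean = 0, pleiotropy_sd = 0,
                        beta_x_sd = 0.08,
                        n_exp = 100000, n_out = 20000,
                        maf_range = c(0.1, 0.9),
                        frac_palindromic = 0.2,
                        frac_palindromic_high = 0.25,
                        frac_allele_swapped = 0,
                        frac_strand_flipped = 0,
                        ld_blocks = NULL, seed = 1) {
  stopifnot(nsnp >= 1, pleiotropy_sd >= 0, beta_x_sd >= 0,
            n_exp > 0, n_out > 0,
            maf_range[1] > 0, maf_range[2] < 1, maf_range[1] < maf_range[2])
  fr <- c(frac_palindromic, frac_palindromic_high,
          frac_allele_swapped, frac_strand_flipped)
  stopifnot(all(fr >= 0), all(fr <= 1))
  if (!is.null(ld_blocks) && sum(vapply(ld_blocks, `[`, numeric(1), 1)) > nsnp)
    stop(mr_error("config", "ld_blocks cover more SNPs than nsnp"))
  structure(as.list(environment()), class = "mr_scenario")
}

.nonpal_pairs <- matrix(c("A", "C",  "A", "G",  "C", "A",  "C", "T",
                          "G", "A",  "G", "T",  "T", "C",  "T", "G"),
                        ncol = 2, byrow = TRUE)

# Block id per SNP: covered blocks first (contiguous), then singletons.
.block_ids <- function(sc) {
  sizes <- if (is.null(sc$ld_blocks)) integer(0)
           else vapply(sc$ld_blocks, `[`, numeric(1), 1)
  ids <- rep(seq_along(sizes), sizes)
  c(ids, seq_len(sc$nsnp - length(ids)) + length(sizes))
}

#' Generate a paired exposure/outcome summary-statistic set
#'
#' @param scenario an [mr_scenario()].
#' @return list with `exposure` and `outcome` (canonical summary-statistic
#'   data.frames; the outcome carries the scenario's corruptions) and
#'   `truth` (per-SNP latent values: true and observed betas on the
#'   exposure's effect allele, pleiotropy draws, corruption and LD-block
#'   membership flags) plus the scenario itself.
#' @export
generate_pair <- function(scenario) {
  sc <- scenario
  withr_seed(sc$seed, {
    n <- sc$nsnp
    block <- .block_ids(sc)
    # one block per "locus", loci striped across the 22 autosomes and placed
    # 20 Mb apart within a chromosome (outside the default 10 Mb clump
    # window); members of a block sit within 100 kb of each other
    chrom <- as.character(((block - 1) %% 22) + 1)
    pos <- as.integer(((block - 1) %/% 22) * 2e7 +
                        stats::ave(seq_len(n), block, FUN = seq_along) * 1e4)
    pal <- stats::runif(n) < sc$frac_palindromic
    ea <- oa <- character(n)
    pal_pairs <- matrix(c("A", "T", "T", "A", "G", "C", "C", "G"),
                        ncol = 2, byrow = TRUE)
    pick_pal <- sample(nrow(pal_pairs), sum(pal), replace = TRUE)
    ea[pal] <- pal_pairs[pick_pal, 1]; oa[pal] <- pal_pairs[pick_pal, 2]
    pick_np <- sample(nrow(.nonpal_pairs), sum(!pal), replace = TRUE)
    ea[!pal] <- .nonpal_pairs[pick_np, 1]; oa[!pal] <- .nonpal_pairs[pick_np, 2]

    f <- stats::runif(n, sc$maf_range[1], sc$maf_range[2])
    # force a share of palindromic SNPs into the non-inferable band
    hi <- pal & stats::runif(n) < sc$frac_palindromic_high
    f[hi] <- stats::runif(sum(hi), 0.421, 0.579)
    f[pal & !hi & pmin(f, 1 - f) > 0.42] <-
      stats::runif(sum(pal & !hi & pmin(f, 1 - f) > 0.42), 0.1, 0.4)

    bx_true <- stats::rnorm(n, 0, sc$beta_x_sd)
    alpha <- if (sc$pleiotropy_sd > 0 || sc$pleiotropy_mean != 0)
      stats::rnorm(n, sc$pleiotropy_mean, sc$pleiotropy_sd) else numeric(n)
    by_true <- sc$theta * bx_true + alpha
    se_x <- 1 / sqrt(2 * sc$n_exp * f * (1 - f))
    se_y <- 1 / sqrt(2 * sc$n_out * f * (1 - f))
    bx <- stats::rnorm(n, bx_true, se_x)
    by <- stats::rnorm(n, by_true, se_y)

    snp <- sprintf("rs%06d", seq_len(n))
    exposure <- data.frame(snp = snp, chr = chrom, pos = pos,
                           effect_allele = ea, other_allele = oa,
                           eaf = f, beta = bx, se = se_x,
                           pval = 2 * stats::pnorm(-abs(bx / se_x)),
                           n = sc$n_exp, stringsAsFactors = FALSE)
    outcome <- data.frame(snp = snp, chr = chrom, pos = pos,
                          effect_allele = ea, other_allele = oa,
                          eaf = f, beta = by, se = se_y,
                          pval = 2 * stats::pnorm(-abs(by / se_y)),
                          n = sc$n_out, stringsAsFactors = FALSE)

    # corruptions: allele swap (same variant reported on the other allele),
    # strand complement (non-palindromic only; undetectable otherwise)
    swapped <- stats::runif(n) < sc$frac_allele_swapped
    outcome$effect_allele[swapped] <- oa[swapped]
    outcome$other_allele[swapped] <- ea[swapped]
    outcome$beta[swapped] <- -outcome$beta[swapped]
    outcome$eaf[swapped] <- 1 - outcome$eaf[swapped]
    flipped <- !pal & stats::runif(n) < sc$frac_strand_flipped
    outcome$effect_allele[flipped] <-
      unname(.complement[outcome$effect_allele[flipped]])
    outcome$other_allele[flipped] <-
      unname(.complement[outcome$other_allele[flipped]])

    truth <- data.frame(snp = snp, block = block, eaf = f,
                        beta_x_true = bx_true, beta_y_true = by_true,
                        pleiotropy = alpha,
                        beta_x_obs = bx, beta_y_obs = by,
                        se_x = se_x, se_y = se_y,
                        palindromic = pal, swapped = swapped,
                        flipped = flipped, stringsAsFactors = FALSE)
    list(exposure = exposure, outcome = outcome, truth = truth,
         scenario = sc)
  })
}

#' Generate the block-diagonal LD matrix of a scenario
#'
#' Within-block squared correlation as stated per block, 0 across blocks,
#' 1 on the diagonal.
#'
#' @param scenario an [mr_scenario()].
#' @return an [ld_matrix()].
#' @export
generate_ld_matrix <- function(scenario) {
  n <- scenario$nsnp
  block <- .block_ids(scenario)
  r2_of_block <- rep(0, max(block))
  if (!is.null(scenario$ld_blocks))
    r2_of_block[seq_along(scenario$ld_blocks)] <-
      vapply(scenario$ld_blocks, `[`, numeric(1), 2)
  m <- outer(block, block, function(a, b) ifelse(a == b, r2_of_block[a], 0))
  diag(m) <- 1
  ld_matrix(m, sprintf("rs%06d", seq_len(n)))
}
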