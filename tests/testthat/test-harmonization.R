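one <- function(ea, oa, beta = 0.1, eaf = 0.3, snp = "rs1", se = 0.02) {
  make_stats(snp, beta = beta, se = se, effect_allele = ea,
             other_allele = oa, eaf = eaf)
}

test_that("harmonize resolves each orientation case with the right algebra", {
  exp_ag <- one("A", "G", beta = 0.10, eaf = 0.25)

  # (a) aligned: identity
  h <- harmonize(exp_ag, one("A", "G", beta = -0.05, eaf = 0.25))
  expect_equal(h$status, "aligned")
  expect_equal(h$beta_out, -0.05)

  # (b) swapped orientation: negate beta, 1 - eaf
  h <- harmonize(exp_ag, one("G", "A", beta = -0.05, eaf = 0.70))
  expect_equal(h$status, "flipped")
  expect_equal(h$beta_out, 0.05)
  expect_equal(h$eaf_out, 0.30)

  # (c) strand flip, non-palindromic: complement then align
  h <- harmonize(exp_ag, one("T", "C", beta = -0.05, eaf = 0.25))
  expect_equal(h$status, "strand_corrected")
  expect_equal(h$beta_out, -0.05)
  # strand flip + swap
  h <- harmonize(exp_ag, one("C", "T", beta = -0.05, eaf = 0.75))
  expect_equal(h$status, "strand_corrected")
  expect_equal(h$beta_out, 0.05)
  expect_equal(h$eaf_out, 0.25)

  # (e) irreconcilable
  h <- harmonize(exp_ag, one("A", "C", beta = -0.05))
  expect_false(h$kept)
  expect_equal(h$reason, "incompatible alleles")

  expect_error(harmonize(exp_ag, one("A", "G", snp = "rs2")),
               class = "mr_config_error")
})

test_that("palindromic SNPs are frequency-inferred or discarded at the MAF limit", {
  # opposite sides of 0.5, both inferable -> flipped
  h <- harmonize(one("A", "T", beta = 0.1, eaf = 0.10),
                 one("A", "T", beta = 0.2, eaf = 0.88))
  expect_equal(h$status, "frequency_inferred_flipped")
  expect_equal(h$beta_out, -0.2)
  expect_equal(h$eaf_out, 0.12)

  # same side -> inferred aligned
  h <- harmonize(one("G", "C", beta = 0.1, eaf = 0.10),
                 one("G", "C", beta = 0.2, eaf = 0.15))
  expect_equal(h$status, "frequency_inferred")
  expect_equal(h$beta_out, 0.2)

  # MAF above the limit on either side -> non-inferable
  h <- harmonize(one("G", "C", eaf = 0.50), one("G", "C", eaf = 0.10))
  expect_false(h$kept)
  expect_equal(h$reason, "non-inferable palindromic")
  h <- harmonize(one("A", "T", eaf = 0.10), one("A", "T", eaf = 0.45))
  expect_false(h$kept)

  # boundary: MAF exactly at the limit stays inferable
  h <- harmonize(one("A", "T", eaf = 0.42), one("A", "T", eaf = 0.42))
  expect_true(h$kept)

  # missing frequency on a palindromic SNP is a discard
  h <- harmonize(one("A", "T", eaf = NA), one("A", "T", eaf = 0.2))
  expect_false(h$kept)
  expect_equal(h$reason, "missing frequency")

  # non-palindromic SNPs proceed without frequency
  h <- harmonize(one("A", "G", eaf = NA), one("A", "G", eaf = NA))
  expect_true(h$kept)
})

test_that("involution and sign-consistency invariants hold", {
  set.seed(3)
  for (i in 1:20) {
    ea <- sample(c("A", "C", "G", "T"), 1)
    oa <- sample(setdiff(c("A", "C", "G", "T"),
                         c(ea, switch(ea, A = "T", T = "A", C = "G", G = "C"))), 1)
    e <- one(ea, oa, beta = rnorm(1), eaf = runif(1, 0.05, 0.95))
    o <- one(ea, oa, beta = rnorm(1), eaf = e$eaf)
    h <- harmonize(e, o)
    expect_equal(h$status, "aligned")

    # flipping both outcome alleles and the beta sign leaves the result fixed
    o2 <- o
    o2$effect_allele <- o$other_allele; o2$other_allele <- o$effect_allele
    o2$beta <- -o$beta; o2$eaf <- 1 - o$eaf
    h2 <- harmonize(e, o2)
    expect_equal(h2$beta_out, h$beta_out)
    expect_equal(h2$eaf_out, h$eaf_out)
  }
})

test_that("harmonize_all joins on rsID and tallies discards", {
  expos <- make_stats(sprintf("rs%d", 1:5), beta = 0.1, se = 0.01)
  outs <- make_stats(sprintf("rs%d", 3:5), beta = 0.2, se = 0.02)
  h <- harmonize_all(expos, outs)
  expect_equal(nrow(h$instruments), 3)
  expect_equal(sort(h$absent), c("rs1", "rs2"))
  expect_equal(h$instruments$beta_out, rep(0.2, 3))  # already aligned

  # one of each case (a)-(e)
  e5 <- rbind(one("A", "G", snp = "s1"), one("A", "G", snp = "s2"),
              one("A", "G", snp = "s3"),
              one("A", "T", snp = "s4", eaf = 0.1),
              one("A", "T", snp = "s5", eaf = 0.5))
  o5 <- rbind(one("A", "G", snp = "s1"), one("G", "A", snp = "s2"),
              one("T", "C", snp = "s3"),
              one("A", "T", snp = "s4", eaf = 0.9),
              one("A", "T", snp = "s5", eaf = 0.5))
  h5 <- harmonize_all(e5, o5)
  expect_setequal(h5$instruments$status,
                  c("aligned", "flipped", "strand_corrected",
                    "frequency_inferred_flipped"))
  expect_equal(nrow(h5$discarded), 1)
  expect_equal(unname(h5$tally["non-inferable palindromic"]), 1L)

  expect_error(harmonize_all(expos, make_stats("rsZ", beta = 1, se = 1)),
               class = "mr_degenerate_error")
})

test_that("no kept palindromic instrument exceeds the MAF limit", {
  set.seed(9)
  sim <- generate_pair(mr_scenario(nsnp = 120, frac_palindromic = 0.5,
                                   frac_palindromic_high = 0.5,
                                   frac_allele_swapped = 0.3, seed = 21))
  h <- harmonize_all(sim$exposure, sim$outcome)
  pal <- h$instruments$status %in% c("frequency_inferred",
                                     "frequency_inferred_flipped")
  maf <- pmin(h$instruments$eaf_exp, 1 - h$instruments$eaf_exp)
  expect_true(all(maf[pal] <= 0.42))
})
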