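make_dataset <- function(calls, phenotype,
                         snp_ids = sprintf("rs%d", seq_len(ncol(calls)))) {
  samples <- data.frame(sample_id = sprintf("S%d", seq_len(nrow(calls))),
                        phenotype = phenotype, stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = snp_ids,
                     chromosome = "1",
                     position = seq_len(ncol(calls)) * 1000L,
                     allele_ref = "A", allele_alt = "G",
                     stringsAsFactors = FALSE)
  m <- matrix(as.integer(calls), nrow = nrow(calls))
  gwashub:::.new_genotype_dataset(samples, snps, m)
}

test_that("genotype counts partition each group exhaustively", {
  ds <- make_dataset(matrix(c(0, 1, 1, NA, 2, 2, 0, 1), ncol = 2),
                     c("control", "control", "control", "control"))
  expect_equal(genotype_counts(ds, "rs1", "control"),
               c(n_AA = 1, n_Aa = 2, n_aa = 0, n_missing = 1))
  expect_equal(sum(genotype_counts(ds, "rs2", "all")), 4)
  # empty group
  expect_equal(unname(genotype_counts(ds, "rs1", "case")), c(0, 0, 0, 0))
  expect_error(genotype_counts(ds, "nope"), "unknown snp_id")
})

test_that("HWE chi-square matches hand computation and handles edge cases", {
  expect_equal(hwe_test(25, 50, 25), list(chi2 = 0, p = 1))
  # all-homozygote extreme: expected (25, 50, 25) -> 25 + 50 + 25 = 100
  h <- hwe_test(50, 0, 50)
  expect_equal(h$chi2, 100)
  # independent re-derivation of the formula for an arbitrary table
  bf_hwe <- function(aa, ab, bb) {
    n <- aa + ab + bb
    p <- (2 * aa + ab) / (2 * n)
    e <- c(n * p^2, 2 * n * p * (1 - p), n * (1 - p)^2)
    sum((c(aa, ab, bb) - e)^2 / e)
  }
  h2 <- hwe_test(30, 40, 30)
  expect_equal(h2$chi2, bf_hwe(30, 40, 30))
  expect_equal(h2$p, pchisq(bf_hwe(30, 40, 30), 1, lower.tail = FALSE))
  # monomorphic SNP: chi2 = 0, p = 1
  expect_equal(hwe_test(10, 0, 0), list(chi2 = 0, p = 1))
  expect_error(hwe_test(-1, 5, 5), "negative")
  # label-swap invariance
  set.seed(1)
  for (i in 1:20) {
    cnt <- sample(0:30, 3, replace = TRUE)
    if (sum(cnt) == 0) next
    expect_equal(hwe_test(cnt[1], cnt[2], cnt[3])$chi2,
                 hwe_test(cnt[3], cnt[2], cnt[1])$chi2)
  }
})

test_that("allelic test reproduces the closed-form 2x2 chi-square and OR", {
  # case alleles alt 60 / ref 40, control alt 40 / ref 60
  r <- allelic_test(c(10, 20, 20), c(20, 20, 10))
  expect_equal(r$chi2, 8)
  expect_equal(r$odds_ratio, 2.25)
  expect_equal(r$p, pchisq(8, 1, lower.tail = FALSE))
  # identical groups: no association
  r0 <- allelic_test(c(10, 10, 10), c(10, 10, 10))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$odds_ratio, 1)
  # degenerate: one group monomorphic both groups -> zero marginal
  rd <- allelic_test(c(10, 0, 0), c(7, 0, 0))
  expect_equal(rd$chi2, 0)
  expect_equal(rd$p, 1)
  expect_error(allelic_test(c(-1, 0, 0), c(1, 1, 1)), "negative")
  # p equals the 1-df upper tail via the erfc identity, and the
  # case/control swap maps chi2 to itself and OR to 1/OR
  set.seed(42)
  for (i in 1:30) {
    ca <- sample(0:50, 3, replace = TRUE)
    co <- sample(0:50, 3, replace = TRUE)
    if (sum(ca) == 0 || sum(co) == 0) next
    r1 <- allelic_test(ca, co)
    erfc <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)
    expect_equal(r1$p, erfc(sqrt(r1$chi2 / 2)), tolerance = 1e-10)
    r2 <- allelic_test(co, ca)
    expect_equal(r1$chi2, r2$chi2)
    expect_equal(r1$odds_ratio, 1 / r2$odds_ratio)
  }
})

test_that("QC filter excludes SNPs with the first failing criterion named", {
  # three SNPs: low MAF, high missingness, clean
  calls <- cbind(
    c(rep(0, 97), 1, 1, 1),            # maf = 3/200 < 0.05
    c(rep(NA, 6), rep(1, 44), rep(0, 50)),  # missingness 0.06
    c(rep(0, 50), rep(1, 40), rep(2, 10))   # passes everything
  )
  ds <- make_dataset(calls, rep(c("case", "control"), each = 50))
  res <- qc_filter(ds)
  expect_equal(res$report$reason, c("maf", "missingness", ""))
  expect_equal(res$dataset$snps$snp_id, "rs3")
  assoc <- snp_association(ds)
  expect_equal(assoc$qc_pass, c(FALSE, FALSE, TRUE))
  # HWE is computed on controls only: a case-only distortion passes
  calls2 <- cbind(c(rep(0, 25), rep(2, 25),                 # cases: all hom
                    rep(0, 13), rep(1, 24), rep(2, 13)))    # controls: ~HWE
  ds2 <- make_dataset(calls2, rep(c("case", "control"), each = 50))
  expect_true(snp_association(ds2)$qc_pass)
})

test_that("optional quality filter only applies when configured", {
  calls <- cbind(c(rep(0, 8), 1, 1), c(rep(0, 8), 1, 1))
  ds <- make_dataset(calls, rep(c("case", "control"), each = 5))
  q <- c(0.9, 0.5)
  none <- qc_filter(ds, qc_thresholds(maf_min = 0), quality = q)
  expect_equal(sum(none$report$qc_pass), 2L)
  some <- qc_filter(ds, qc_thresholds(maf_min = 0, quality_min = 0.8),
                    quality = q)
  expect_equal(some$report$reason, c("", "quality"))
})

test_that("risk-SNP screen uses a strict cutoff and orders by p", {
  assoc <- data.frame(snp_id = c("b", "a", "c"),
                      p = c(0.005, 0.01, 0.02),
                      qc_pass = TRUE, stringsAsFactors = FALSE)
  out <- screen_risk_snps(assoc, 0.01)
  expect_equal(out$snp_id, "b")   # 0.01 boundary excluded
  expect_equal(nrow(screen_risk_snps(assoc[0, ], 0.01)), 0L)
  # ties in p order by snp_id
  assoc2 <- data.frame(snp_id = c("z", "y"), p = c(0.001, 0.001),
                       qc_pass = TRUE, stringsAsFactors = FALSE)
  expect_equal(screen_risk_snps(assoc2, 0.01)$snp_id, c("y", "z"))
})
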