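#' Quality-control and screening thresholds
#'
#' Defaults follow standard case/control GWAS practice: SNPs failing the
#' Hardy-Weinberg equilibrium test in controls at p < 5e-7, with missingness
#' above 5\% or minor allele frequency below 5\% are excluded, and risk SNPs
#' are screened at an association p-value strictly below 0.01.  `quality_min`
#' optionally thresholds a user-supplied per-SNP quality score (e.g. an
#' imputation info score); it is off (`NULL`) by default.
#'
#' @param hwe_p_min minimum Hardy-Weinberg p-value in controls.
#' @param miss_max maximum per-SNP missingness fraction (all samples).
#' @param maf_min minimum pooled minor allele frequency.
#' @param quality_min optional minimum per-SNP quality score.
#' @param assoc_p_max screening p-value cutoff (strict inequality).
#' @return list of thresholds with class `qc_thresholds`.
#' @export
qc_thresholds <- function(hwe_p_min = 5e-7, miss_max = 0.05, maf_min = 0.05,
                          quality_min = NULL, assoc_p_max = 0.01) {
  stopifnot(hwe_p_min >= 0, hwe_p_min <= 1,
            miss_max >= 0, miss_max <= 1,
            maf_min >= 0, maf_min <= 1,
            assoc_p_max >= 0, assoc_p_max <= 1)
  structure(list(hwe_p_min = hwe_p_min, miss_max = miss_max,
                 maf_min = maf_min, quality_min = quality_min,
                 assoc_p_max = assoc_p_max),
            class = "qc_thresholds")
}

#' Genotype counts for one SNP within a phenotype group
#'
#' @param dataset a `genotype_dataset`.
#' @param snp_id SNP identifier.
#' @param group one of `"case"`, `"control"`, `"all"`.
#' @return named integer vector `(n_AA, n_Aa, n_aa, n_missing)` where AA is
#'   the reference homozygote and aa the alternate (minor) homozygote.
#' @export
genotype_counts <- function(dataset, snp_id, group = c("all", "case", "control")) {
  group <- match.arg(group)
  j <- match(snp_id, dataset$snps$snp_id)
  if (is.na(j)) stop("unknown snp_id: ", snp_id)
  rows <- switch(group,
                 all = rep(TRUE, nrow(dataset$samples)),
                 case = dataset$samples$phenotype == "case",
                 control = dataset$samples$phenotype == "control")
  g <- dataset$calls[rows, j]
  c(n_AA = sum(g == 0L, na.rm = TRUE),
    n_Aa = sum(g == 1L, na.rm = TRUE),
    n_aa = sum(g == 2L, na.rm = TRUE),
    n_missing = sum(is.na(g)))
}

# counts for all SNPs at once: 4 x n_snps matrix per group
.count_all <- function(calls, rows) {
  m <- calls[rows, , drop = FALSE]
  rbind(n_AA = colSums(m == 0L, na.rm = TRUE),
        n_Aa = colSums(m == 1L, na.rm = TRUE),
        n_aa = colSums(m == 2L, na.rm = TRUE),
        n_missing = colSums(is.na(m)))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Goodness-of-fit chi-square over the three genotype classes against the
#' expected proportions p^2, 2pq, q^2 at the observed allele frequency, with
#' one degree of freedom.  A monomorphic SNP (allele frequency 0 or 1)
#' returns chi2 = 0, p = 1.  Vectorized over equal-length count vectors.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (reference hom, het, alternate hom).
#' @return list with numeric vectors `chi2` and `p`.
#' @examples
#' hwe_test(25, 50, 25)  # perfect proportions: chi2 = 0
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  if (any(n_AA < 0 | n_Aa < 0 | n_aa < 0)) stop("negative genotype count")
  n <- n_AA + n_Aa + n_aa
  if (any(n < 1)) stop("hwe_test requires at least one genotype")
  p <- (2 * n_AA + n_Aa) / (2 * n)   # reference allele frequency
  q <- 1 - p
  exp_AA <- n * p^2
  exp_Aa <- 2 * n * p * q
  exp_aa <- n * q^2
  chi2 <- numeric(length(n))
  poly <- p > 0 & p < 1
  chi2[poly] <- (n_AA[poly] - exp_AA[poly])^2 / exp_AA[poly] +
    (n_Aa[poly] - exp_Aa[poly])^2 / exp_Aa[poly] +
    (n_aa[poly] - exp_aa[poly])^2 / exp_aa[poly]
  pval <- rep(1, length(n))
  pval[poly] <- stats::pchisq(chi2[poly], df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p = pval)
}

#' Allelic (2x2, 1 df) chi-square association test
#'
#' Forms per-group allele counts (ref = 2 n_AA + n_Aa, alt = 2 n_aa + n_Aa)
#' and computes the Pearson chi-square statistic of the 2x2 allele-by-
#' phenotype table without continuity correction.  The odds ratio is
#' (alt_case * ref_control) / (ref_case * alt_control); 0.5 is added to
#' every cell only when some cell is zero (Haldane-Anscombe).  A degenerate
#' table with a zero marginal yields chi2 = 0, p = 1.  Vectorized: the count
#' arguments may be 3-column matrices `(n_AA, n_Aa, n_aa)`.
#'
#' @param case_counts,control_counts genotype counts per group: length-3
#'   vectors or 3-column matrices `(n_AA, n_Aa, n_aa)`.
#' @return list with numeric vectors `chi2`, `p`, `odds_ratio`.
#' @examples
#' # case alleles alt = 60 / ref = 40 vs control 40 / 60:
#' allelic_test(c(10, 20, 20), c(20, 20, 10))
#' @export
allelic_test <- function(case_counts, control_counts) {
  as_mat <- function(x) {
    if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  }
  ca <- as_mat(case_counts); co <- as_mat(control_counts)
  if (any(ca < 0) || any(co < 0)) stop("negative genotype count")
  ref_case <- 2 * ca[, 1] + ca[, 2]
  alt_case <- 2 * ca[, 3] + ca[, 2]
  ref_ctrl <- 2 * co[, 1] + co[, 2]
  alt_ctrl <- 2 * co[, 3] + co[, 2]
  a <- alt_case; b <- ref_case; c_ <- alt_ctrl; d <- ref_ctrl
  n <- a + b + c_ + d
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  denom <- r1 * r2 * c1 * c2
  chi2 <- numeric(length(n))
  ok <- denom > 0
  chi2[ok] <- n[ok] * (a[ok] * d[ok] - b[ok] * c_[ok])^2 / denom[ok]
  p <- rep(1, length(n))
  p[ok] <- stats::pchisq(chi2[ok], df = 1, lower.tail = FALSE)
  zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  aa <- a + 0.5 * zero; bb <- b + 0.5 * zero
  cc <- c_ + 0.5 * zero; dd <- d + 0.5 * zero
  or <- (aa * dd) / (bb * cc)
  list(chi2 = chi2, p = p, odds_ratio = or)
}

# Full per-SNP statistics table (internal; exported wrappers add QC flags).
.snp_stats <- function(dataset) {
  is_case <- dataset$samples$phenotype == "case"
  ca <- .count_all(dataset$calls, is_case)
  co <- .count_all(dataset$calls, !is_case)
  all_cnt <- ca[1:3, , drop = FALSE] + co[1:3, , drop = FALSE]
  nonmiss <- colSums(all_cnt)
  n_samples <- nrow(dataset$samples)
  missingness <- 1 - nonmiss / n_samples
  alt_freq <- ifelse(nonmiss > 0,
                     (2 * all_cnt[3, ] + all_cnt[2, ]) / (2 * nonmiss), 0)
  maf <- pmin(alt_freq, 1 - alt_freq)
  # HWE on controls only; SNPs with no control genotypes get chi2 0, p 1
  co_n <- colSums(co[1:3, , drop = FALSE])
  hwe_chi2 <- numeric(ncol(ca)); hwe_p <- rep(1, ncol(ca))
  has <- co_n >= 1
  if (any(has)) {
    h <- hwe_test(co[1, has], co[2, has], co[3, has])
    hwe_chi2[has] <- h$chi2; hwe_p[has] <- h$p
  }
  at <- allelic_test(t(ca[1:3, , drop = FALSE]), t(co[1:3, , drop = FALSE]))
  data.frame(
    snp_id = dataset$snps$snp_id,
    chromosome = dataset$snps$chromosome,
    position = dataset$snps$position,
    allele_ref = dataset$snps$allele_ref,
    allele_alt = dataset$snps$allele_alt,
    case_AA = ca[1, ], case_Aa = ca[2, ], case_aa = ca[3, ],
    case_missing = ca[4, ],
    control_AA = co[1, ], control_Aa = co[2, ], control_aa = co[3, ],
    control_missing = co[4, ],
    maf = maf, missingness = missingness,
    hwe_chi2 = hwe_chi2, hwe_p = hwe_p,
    chi2 = at$chi2, p = at$p, odds_ratio = at$odds_ratio,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

.qc_flags <- function(stats, thresholds, quality = NULL) {
  pass_hwe <- stats$hwe_p >= thresholds$hwe_p_min
  pass_miss <- stats$missingness <= thresholds$miss_max
  pass_maf <- stats$maf >= thresholds$maf_min
  pass_qual <- rep(TRUE, nrow(stats))
  if (!is.null(thresholds$quality_min) && !is.null(quality)) {
    pass_qual <- quality >= thresholds$quality_min
  }
  reason <- rep("", nrow(stats))
  reason[!pass_qual] <- "quality"
  reason[!pass_maf] <- "maf"
  reason[!pass_miss] <- "missingness"
  reason[!pass_hwe] <- "hwe"
  list(pass = pass_hwe & pass_miss & pass_maf & pass_qual, reason = reason)
}

#' Per-SNP association and QC statistics
#'
#' Computes for every SNP: genotype counts per phenotype group, pooled minor
#' allele frequency and missingness, the Hardy-Weinberg test on controls
#' only, the allelic chi-square test with odds ratio, and QC pass flags
#' against the supplied thresholds.
#'
#' @param dataset a `genotype_dataset`.
#' @param thresholds a [qc_thresholds()] object.
#' @param quality optional numeric vector of per-SNP quality scores (same
#'   order as `dataset$snps`), used only when `thresholds$quality_min` is set.
#' @return data frame with one row per SNP, including `qc_pass` and
#'   `qc_reason` (the first failed filter, in the order hwe, missingness,
#'   maf, quality; empty when passing).
#' @export
snp_association <- function(dataset, thresholds = qc_thresholds(),
                            quality = NULL) {
  stats <- .snp_stats(dataset)
  fl <- .qc_flags(stats, thresholds, quality)
  stats$qc_pass <- fl$pass
  stats$qc_reason <- fl$reason
  stats
}

#' Filter SNPs on quality-control criteria
#'
#' A SNP survives iff Hardy-Weinberg p (controls) >= `hwe_p_min`,
#' missingness <= `miss_max`, pooled MAF >= `maf_min`, and (when configured)
#' quality >= `quality_min`.
#'
#' @inheritParams snp_association
#' @return list with `dataset` (surviving SNPs only) and `report` (data
#'   frame `snp_id`, `qc_pass`, `reason`).
#' @export
qc_filter <- function(dataset, thresholds = qc_thresholds(), quality = NULL) {
  stats <- .snp_stats(dataset)
  fl <- .qc_flags(stats, thresholds, quality)
  keep <- fl$pass
  filtered <- .new_genotype_dataset(
    dataset$samples,
    dataset$snps[keep, , drop = FALSE],
    dataset$calls[, keep, drop = FALSE]
  )
  list(dataset = filtered,
       report = data.frame(snp_id = stats$snp_id, qc_pass = fl$pass,
                           reason = fl$reason, stringsAsFactors = FALSE))
}

#' Screen risk SNPs at a p-value cutoff
#'
#' Retains QC-passed SNPs with association p strictly below `assoc_p_max`,
#' ordered by ascending p with ties broken by SNP id.
#'
#' @param assoc_results data frame from [snp_association()].
#' @param assoc_p_max screening cutoff (strict inequality; default 0.01).
#' @return data frame of risk SNPs (subset of `assoc_results` rows).
#' @export
screen_risk_snps <- function(assoc_results, assoc_p_max = 0.01) {
  keep <- assoc_results$p < assoc_p_max
  if (!is.null(assoc_results$qc_pass)) keep <- keep & assoc_results$qc_pass
  out <- assoc_results[keep, , drop = FALSE]
  out <- out[order(out$p, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
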