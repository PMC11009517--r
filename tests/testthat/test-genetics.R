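test_that("HWE chi-square against hand-computed expectations", {
  exact <- hwe_chi2(c(25, 50, 25))
  expect_equal(exact$chi2, 0)
  expect_equal(exact$p, 1)

  # allele freq 0.5 -> expected (25, 50, 25); chi2 = 1 + 2 + 1 = 4
  dev <- hwe_chi2(c(30, 40, 30))
  expect_equal(dev$chi2, 4.0, tolerance = 1e-12)
  expect_equal(dev$p, 0.04550026389635847, tolerance = 1e-10)

  mono <- hwe_chi2(c(100, 0, 0))
  expect_equal(mono$chi2, 0)
  expect_error(hwe_chi2(c(0, 0, 0)), "zero")
})

test_that("HWE test holds its nominal size on equilibrium genotypes", {
  set.seed(2024)
  reps <- 1000
  rej <- vapply(seq_len(reps), function(i) {
    g <- stats::rbinom(10000, 2, 0.3)
    hwe_chi2(tabulate(g + 1, 3))$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("genotype coding under dominant and additive models", {
  expect_equal(code_genotype(c(0L, 1L, 2L), "dominant"), c(0L, 1L, 1L))
  expect_equal(code_genotype(c(0L, 1L, 2L), "additive"), c(0L, 1L, 2L))
  expect_equal(code_genotype(c(NA, 2L), "dominant"), c(NA_integer_, 1L))
  expect_error(code_genotype(3L, "dominant"), "0, 1 or 2")
})

test_that("allele-pair calls parse to risk-allele counts", {
  expect_equal(count_risk_alleles(c("TT", "TC", "CC", NA), "C"),
               c(0L, 1L, 2L, NA_integer_))
  expect_error(count_risk_alleles("TG", "C", alleles = c("T", "C")),
               "Unexpected allele")
  specs <- default_snp_specs()
  geno <- tibble::tibble(
    participant_id = 1:2,
    rs1121980 = c("CT", "CC"),
    rs1421085 = c(2, 0),
    rs8050136 = c("AA", "GA"))
  counts <- parse_genotype_table(geno, specs)
  expect_equal(counts$rs1121980, c(1L, 0L))
  expect_equal(counts$rs1421085, c(2L, 0L))
  expect_equal(counts$rs8050136, c(2L, 1L))
})

test_that("per-SNP OR equals the 2x2 cross-product ratio without covariates", {
  # exposed 30/70 events vs unexposed 15/85
  y <- c(rep(1, 30), rep(0, 70), rep(1, 15), rep(0, 85))
  g <- c(rep(1, 100), rep(0, 100))
  fit <- fit_snp_or(y, g)
  expect_equal(fit$or, (30 * 85) / (70 * 15), tolerance = 1e-6)
  expect_error(fit_snp_or(rep(1, 10), rep(0:1, 5)), "both classes")
})

test_that("per-SNP OR recovers a simulated per-allele effect", {
  set.seed(31)
  n <- 20000
  g <- stats::rbinom(n, 2, 0.3)
  y <- stats::rbinom(n, 1, stats::plogis(-0.2 + 0.4 * g))
  fit <- fit_snp_or(y, g)
  expect_equal(fit$log_or, 0.4, tolerance = 0.1)

  set.seed(32)
  y0 <- stats::rbinom(n, 1, 0.5)
  expect_equal(fit_snp_or(y0, g)$or, 1, tolerance = 0.1)
})

test_that("GRS is the OR-weighted risk-allele sum with a median split", {
  geno <- tibble::tibble(participant_id = 1:3,
                         a = c(2L, 0L, 2L), b = c(1L, 0L, 2L),
                         c = c(0L, 0L, 2L))
  w <- c(a = 1.5, b = 1.2, c = 1.1)
  res <- compute_grs(geno, w)
  expect_equal(res$grs, c(4.2, 0, 2 * sum(w)))
  expect_equal(res$high_grs, c(1L, 0L, 1L))  # median itself goes high

  # monotone: adding a risk allele never decreases the score
  res2 <- compute_grs(tibble::tibble(participant_id = 1, a = 1L, b = 1L,
                                     c = 1L), w)
  expect_lt(res2$grs, 2 * sum(w))
  expect_gt(res2$grs, 0)

  geno_na <- geno
  geno_na$b[2] <- NA_integer_
  res_na <- compute_grs(geno_na, w)
  expect_true(is.na(res_na$grs[2]))
  expect_true(is.na(res_na$high_grs[2]))
  expect_no_error(compute_grs(geno, c(a = 1.5)))
  expect_error(compute_grs(geno, c(d = 1.5)), "lacks")
})

test_that("median split imbalance is bounded by ties at the median", {
  set.seed(5)
  geno <- tibble::tibble(participant_id = 1:501)
  for (snp in c("a", "b", "c")) {
    geno[[snp]] <- stats::rbinom(501, 2, 0.4)
  }
  res <- compute_grs(geno, c(a = 1.2, b = 1.1, c = 1.3))
  # with t values tied at the median the >=-median split can be off-balance
  # by at most 2t - 1
  n_ties <- sum(res$grs == stats::median(res$grs))
  expect_lte(abs(sum(res$high_grs) - sum(1 - res$high_grs)),
             2 * n_ties - 1)
})

test_that("a declared risk allele estimated protective triggers a warning", {
  set.seed(8)
  n <- 3000
  geno <- tibble::tibble(participant_id = seq_len(n),
                         snp1 = stats::rbinom(n, 2, 0.4))
  y <- stats::rbinom(n, 1, stats::plogis(0.4 - 0.5 * geno$snp1))
  expect_warning(estimate_grs_weights(geno, y), "OR < 1")
})
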