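test_that("simulated genotypes are in Hardy-Weinberg proportions", {
  set.seed(61)
  g <- simulate_genotypes(1e5, tibble::tibble(
    snp_id = "s", major_allele = "T", minor_allele = "C",
    risk_allele = "C", maf = 0.5))
  freqs <- tabulate(g$counts$s + 1, 3) / 1e5
  # binomial 3-SD bands around (0.25, 0.5, 0.25)
  expect_equal(freqs[1], 0.25, tolerance = 3 * sqrt(0.25 * 0.75 / 1e5) / 0.25)
  expect_equal(freqs[2], 0.50, tolerance = 3 * sqrt(0.5 * 0.5 / 1e5) / 0.5)
  # calls agree with counts
  expect_equal(unname(count_risk_alleles(g$calls$s, "C")),
               unname(g$counts$s))

  set.seed(62)
  g0 <- simulate_genotypes(200, tibble::tibble(
    snp_id = "s", major_allele = "T", minor_allele = "C",
    risk_allele = "C", maf = 1e-6))
  expect_true(all(g0$counts$s == 0))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n = 300, seed = 1234)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$intakes, b$intakes)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$truth$flags, b$truth$flags)
})

test_that("a default synthetic cohort passes the exclusion cascade intact", {
  tabs <- simulate_cohort(sim_config(n = 500, seed = 9))
  cohort <- assemble_cohort(tabs$phenotypes, tabs$intakes, tabs$genotypes,
                            tabs$dna_quality)
  res <- apply_exclusions(cohort)
  expect_equal(sum(res$audit$n_excluded), 0)
  expect_equal(nrow(res$cohort), 500)
})

test_that("zero latent correlation gives near-independent intakes", {
  cfg <- sim_config(n = 4000, seed = 77, intake_correlation = 0)
  tabs <- simulate_cohort(cfg)
  adj <- energy_adjust_intakes(tabs$intakes, cfg$registry)
  pick <- c("fibre", "saturated_fat", "vitamin_c", "total_fat")
  cors <- stats::cor(as.matrix(adj[, pick]))
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.06)

  # with the default positive loading the classic gradient appears:
  # pro-inflammatory SFA rises with DII, anti-inflammatory fibre falls
  cfg2 <- sim_config(n = 4000, seed = 78)
  tabs2 <- simulate_cohort(cfg2)
  adj2 <- energy_adjust_intakes(tabs2$intakes, cfg2$registry)
  dii <- tabs2$truth$dii
  expect_gt(stats::cor(adj2$saturated_fat, dii), 0.2)
  expect_lt(stats::cor(adj2$fibre, dii), -0.2)
})

test_that("generated DII spans all four quartiles even at n = 100", {
  tabs <- simulate_cohort(sim_config(n = 100, seed = 5))
  expect_equal(sort(unique(as.character(
    assign_quartiles(tabs$truth$dii)))), paste0("Q", 1:4))
})

test_that("null effect model gives ~50% outcome prevalence", {
  cfg <- sim_config(
    n = 5000, seed = 21,
    covariate_logor = c(age = 0, male = 0, energy = 0, education_high = 0,
                        pa_moderate = 0, pa_high = 0, smoking_ex = 0,
                        smoking_current = 0),
    grs_per_allele_logor = c(rs1121980 = 0, rs1421085 = 0, rs8050136 = 0))
  tabs <- simulate_cohort(cfg)
  prev <- colMeans(tabs$truth$flags)
  expect_true(all(abs(prev - 0.5) < 0.03))
})

test_that("follow-up anthropometry reproduces the simulated flags exactly", {
  cfg <- sim_config(n = 800, seed = 33, stratifier = "rs8050136",
                    cell_logor = list(
                      wc = cell_logor_from_or(c(1, 1.5, 1.4, 1.3))))
  tabs <- simulate_cohort(cfg)
  built <- suppressWarnings(build_analysis_table(tabs))
  d <- built$data
  truth <- tabs$truth$flags
  expect_equal(d$increased_bmi, truth$increased_bmi)
  expect_equal(d$increased_wc, truth$increased_wc)
  expect_equal(d$increased_whr, truth$increased_whr)
  expect_equal(d$increased_vai, truth$increased_vai)
  # and the analysis quartile is the generative quartile
  expect_equal(as.character(d$dii_quartile),
               as.character(tabs$truth$quartile))
})

test_that("an injected cell OR is recovered from a large cohort", {
  set.seed(88)
  cell <- matrix(0, 4, 2)
  cell[2, 1] <- log(2)
  q <- sample(1:4, 1e5, replace = TRUE)
  s <- rbinom(1e5, 1, 0.5)
  cfg <- sim_config(n = 1e5)
  cfg$cell_logor$wc <- cell
  flags <- simulate_outcomes(cfg, q, s, cov_lp = 0, outcomes = "wc")
  d <- tibble::tibble(
    y = flags$increased_wc,
    dii_quartile = factor(paste0("Q", q), levels = paste0("Q", 1:4)),
    stratum = s)
  tab <- fit_stratified_or_table(d, "y")
  est <- tab$cells$or[tab$cells$stratum == 0 & tab$cells$quartile == "Q2"]
  expect_equal(est, 2, tolerance = 0.1)
})

test_that("configuration validation rejects malformed effect models", {
  expect_error(sim_config(cell_logor = list(wc = matrix(0, 2, 2))), "4 x 2")
  bad <- cell_logor_from_or(c(1, 2, 1, 1))
  bad[1, 1] <- 0.5
  expect_error(sim_config(cell_logor = list(wc = bad)), "Q1")
  expect_error(
    sim_config(stratifier = "grs",
               cell_logor = list(bmi = cell_logor_from_or(c(1, 2, 1, 1)))),
    "GRS weights")
  expect_error(cell_logor_from_or(c(2, 1, 1, 1)), "or_s0")
  expect_error(sim_config(stratifier = "rs999"), "stratifier")
})
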