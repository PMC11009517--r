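test_that("z-score standardization matches hand arithmetic", {
  expect_equal(dii_z_score(50, 40, 5), 2.0)
  expect_equal(dii_z_score(40, 40, 5), 0.0)
  expect_equal(dii_z_score(7.5, 18.8, 4.9), -2.306122448979592, tolerance = 1e-12)
  expect_error(dii_z_score(5, 10, 0), "global_sd")
  expect_error(dii_z_score(Inf, 10, 1), "finite")
})

test_that("centered percentile is the centered normal CDF", {
  expect_equal(centered_percentile(0), 0)
  expect_equal(centered_percentile(1), 0.6826894921370859, tolerance = 1e-12)
  z <- seq(-3, 3, by = 0.37)
  expect_equal(centered_percentile(-z), -centered_percentile(z))
  expect_true(all(abs(centered_percentile(c(-8, 8))) < 1))
})

test_that("per-parameter score is centered percentile times effect score", {
  spec <- list(global_mean = 40, global_sd = 5, effect_score = -0.5)
  z <- dii_z_score(50, 40, 5)
  expect_equal(score_dii_parameter(50, spec), centered_percentile(z) * -0.5)
  expect_equal(score_dii_parameter(40, spec), 0)
  spec0 <- list(global_mean = 40, global_sd = 5, effect_score = 0)
  expect_equal(score_dii_parameter(123, spec0), 0)
})

test_that("density energy adjustment rescales proportionally", {
  reg <- tibble::tibble(name = "fibre", unit = "g", global_mean = 10,
                        global_sd = 3, effect_score = -0.66,
                        energy_adjust = TRUE)
  intakes <- tibble::tibble(participant_id = 1:2, energy = c(2000, 1000),
                            fibre = c(10, 7))
  adj <- energy_adjust_intakes(intakes, reg, method = "density",
                               reference_energy = 1000)
  expect_equal(adj$fibre, c(5, 7))  # identity when energy == reference
  expect_equal(adj$energy, intakes$energy)
  expect_error(
    energy_adjust_intakes(
      tibble::tibble(participant_id = 1, energy = 0, fibre = 1), reg),
    "energy")
  expect_error(
    energy_adjust_intakes(
      tibble::tibble(participant_id = 1, energy = 2000, unknown_thing = 1),
      reg),
    "unknown_thing")
})

test_that("residual adjustment with exact linear intake has zero residuals", {
  reg <- tibble::tibble(name = "fibre", unit = "g", global_mean = 10,
                        global_sd = 3, effect_score = -0.66,
                        energy_adjust = TRUE)
  energy <- seq(1200, 3600, length.out = 40)
  intakes <- tibble::tibble(participant_id = 1:40, energy = energy,
                            fibre = 0.01 * energy)
  adj <- energy_adjust_intakes(intakes, reg, method = "residual",
                               reference_energy = 1000)
  expect_equal(adj$fibre, rep(0.01 * 1000, 40), tolerance = 1e-10)
})

test_that("DII of a cohort eating exactly the global means is zero", {
  reg <- toy_registry()
  intakes <- tibble::tibble(participant_id = 1:5,
                            sfa = 25, fibre = 18, iron = 12)
  res <- compute_dii(intakes, reg, min_parameters = 3)
  expect_equal(res$dii, rep(0, 5))
  expect_equal(res$n_parameters_used, rep(3L, 5))
  expect_true(all(res$scored))
})

test_that("three-parameter total equals the hand-computed sum", {
  reg <- toy_registry()
  intakes <- tibble::tibble(participant_id = 1, sfa = 33, fibre = 9,
                            iron = 15)
  # spreadsheet-style per-parameter arithmetic
  s_sfa <- (2 * pnorm((33 - 25) / 8) - 1) * 0.37
  s_fib <- (2 * pnorm((9 - 18) / 5) - 1) * -0.66
  s_iron <- (2 * pnorm((15 - 12) / 4) - 1) * 0.03
  res <- compute_dii(intakes, reg, min_parameters = 3)
  expect_equal(res$dii, s_sfa + s_fib + s_iron, tolerance = 1e-12)

  one <- compute_dii(intakes[, c("participant_id", "sfa")],
                     reg[reg$name == "sfa", ], min_parameters = 1)
  expect_equal(one$dii, s_sfa, tolerance = 1e-12)
})

test_that("compute_dii matches a straight-line reimplementation", {
  set.seed(421)
  reg <- random_registry(5)
  intakes <- tibble::tibble(participant_id = 1:100)
  for (p in reg$name) {
    intakes[[p]] <- stats::runif(100, 0, 150)
  }
  res <- compute_dii(intakes, reg, min_parameters = 5)
  expect_equal(res$dii, dii_by_hand(intakes, reg), tolerance = 1e-10)
})

test_that("DII is monotone in each parameter and bounded by total weight", {
  set.seed(99)
  reg <- random_registry(6)
  base <- tibble::tibble(participant_id = 1)
  for (p in reg$name) base[[p]] <- stats::runif(1, 5, 100)
  total0 <- compute_dii(base, reg, min_parameters = 6)$dii
  for (j in seq_len(nrow(reg))) {
    bumped <- base
    bumped[[reg$name[j]]] <- bumped[[reg$name[j]]] + 10
    total1 <- compute_dii(bumped, reg, min_parameters = 6)$dii
    if (reg$effect_score[j] > 0) {
      expect_gte(total1, total0)
    } else if (reg$effect_score[j] < 0) {
      expect_lte(total1, total0)
    }
  }
  # boundedness over random profiles
  for (i in 1:20) {
    prof <- tibble::tibble(participant_id = 1)
    for (p in reg$name) prof[[p]] <- stats::runif(1, 0, 1000)
    expect_lt(abs(compute_dii(prof, reg, min_parameters = 6)$dii),
              sum(abs(reg$effect_score)))
  }
})

test_that("participants below the coverage threshold are flagged not scored", {
  reg <- toy_registry()
  intakes <- tibble::tibble(participant_id = 1:2,
                            sfa = c(30, 30), fibre = c(15, NA), iron = 12)
  res <- compute_dii(intakes, reg, min_parameters = 3)
  expect_true(res$scored[1])
  expect_false(res$scored[2])
  expect_true(is.na(res$dii[2]))
  expect_equal(res$n_parameters_used, c(3L, 2L))
})

test_that("quartile assignment partitions at empirical cut points", {
  q <- assign_quartiles(1:8)
  expect_equal(as.character(q),
               c("Q1", "Q1", "Q2", "Q2", "Q3", "Q3", "Q4", "Q4"))

  set.seed(7)
  x <- stats::runif(10000)
  q <- assign_quartiles(x)
  expect_equal(sum(table(q)), 10000)           # partition
  expect_equal(as.numeric(table(q)), rep(2500, 4))

  # ties at a cut point go to the lower quartile
  xt <- c(1, 2, 2, 2, 3, 4, 5, 6)
  qt <- assign_quartiles(xt)
  q25 <- stats::quantile(xt, 0.25, names = FALSE)
  expect_true(all(qt[xt == q25] == "Q1"))

  expect_error(assign_quartiles(c(1, 1, 2, 2)), "distinct")
})
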