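test_that("logistic fit recovers closed forms", {
  # intercept-only at prevalence 0.25: coefficient log(1/3)
  d <- tibble::tibble(y = rep(c(1, 0), c(100, 300)))
  fit <- fit_logistic(y ~ 1, d)
  expect_equal(unname(fit$coefficients), log(1 / 3), tolerance = 1e-8)

  # single binary predictor: OR equals the cross-product ratio
  d2 <- tibble::tibble(
    y = c(rep(1, 30), rep(0, 70), rep(1, 15), rep(0, 85)),
    x = c(rep(1, 100), rep(0, 100)))
  fit2 <- fit_logistic(y ~ x, d2)
  est <- or_contrast(fit2, "x")
  expect_equal(est$or, 2.428571428571428, tolerance = 1e-6)
  expect_true(est$ci_low < est$or && est$or < est$ci_high)

  # predictor independent of outcome: OR near 1, CI covers 1
  set.seed(3)
  d3 <- tibble::tibble(y = rbinom(20000, 1, 0.4), x = rbinom(20000, 1, 0.5))
  est3 <- or_contrast(fit_logistic(y ~ x, d3), "x")
  expect_equal(est3$or, 1, tolerance = 0.1)
  expect_true(est3$ci_low < 1 && 1 < est3$ci_high)
})

test_that("degenerate designs are rejected with diagnostics", {
  d <- tibble::tibble(y = rep(0:1, 20), x = rep(c(0L, 1L, 1L, 0L), 10))
  d$x2 <- d$x
  expect_error(fit_logistic(y ~ x + x2, d), "aliased")
  d4 <- tibble::tibble(y = rep(0:1, each = 25), x = rep(0:1, each = 25))
  suppressWarnings(
    expect_error(fit_logistic(y ~ x, d4), "separation|converge"))
  expect_error(fit_logistic(y ~ x, tibble::tibble(y = rep(1, 10), x = 1:10)),
               "both classes")
})

test_that("eight-group coding enumerates the quartile-by-stratum grid", {
  q <- factor(rep(paste0("Q", 1:4), 2), levels = paste0("Q", 1:4))
  s <- rep(0:1, each = 4)
  g <- build_eight_groups(q, s)
  expect_equal(levels(g), c(paste0("Q", 1:4, ".S0"), paste0("Q", 1:4, ".S1")))
  expect_equal(as.character(g[1]), "Q1.S0")  # the reference level
  expect_equal(nlevels(g), 8)
  expect_equal(sum(table(g)), 8)
  expect_true(is.na(build_eight_groups(factor(NA, levels = levels(q)), 0)))
  expect_error(build_eight_groups(factor("Q5"), 0), "Q1..Q4")
  expect_error(build_eight_groups(q, rep(2, 8)), "binary")
})

test_that("stratified table has 8 cells with fixed within-stratum references", {
  set.seed(41)
  d <- model_frame(3000)
  names(d)[names(d) == "y"] <- "increased_wc"
  tab <- fit_stratified_or_table(d, "increased_wc")
  expect_equal(nrow(tab$cells), 8)
  ref <- tab$cells[tab$cells$quartile == "Q1", ]
  expect_equal(ref$or, c(1, 1))
  expect_true(all(is.na(ref$ci_low)))
  nonref <- tab$cells[tab$cells$quartile != "Q1", ]
  expect_true(all(nonref$ci_low <= nonref$or & nonref$or <= nonref$ci_high))
  expect_equal(sum(tab$cells$n), nrow(d))
  expect_length(tab$p_trend, 2)
  expect_true(tab$p_interaction > 0 && tab$p_interaction <= 1)
})

test_that("stratum-1 cells estimate within-stratum contrasts", {
  set.seed(42)
  cell <- matrix(0, 4, 2)
  cell[, 2] <- c(0, log(2), log(2), log(2))
  d <- model_frame(40000, cell_logor = cell, stratum_logor = 0.5)
  names(d)[names(d) == "y"] <- "increased_wc"
  tab <- fit_stratified_or_table(d, "increased_wc")
  s1 <- tab$cells[tab$cells$stratum == 1 & tab$cells$quartile != "Q1", ]
  expect_equal(s1$or, rep(2, 3), tolerance = 0.15)
  s0 <- tab$cells[tab$cells$stratum == 0 & tab$cells$quartile != "Q1", ]
  expect_equal(s0$or, rep(1, 3), tolerance = 0.15)
})

test_that("trend test finds an ordered slope and reports its direction", {
  set.seed(43)
  n <- 4000
  q <- sample(1:4, n, replace = TRUE)
  y <- rbinom(n, 1, plogis(-0.3 + 0.15 * (q - 1)))
  d <- tibble::tibble(y = y,
                      dii_quartile = factor(paste0("Q", q),
                                            levels = paste0("Q", 1:4)))
  tr <- p_trend(d, "y")
  expect_lt(tr$p, 0.05)
  expect_gt(tr$slope, 0)

  y_dec <- rbinom(n, 1, plogis(0.3 - 0.2 * (q - 1)))
  tr_dec <- p_trend(tibble::tibble(y = y_dec,
                                   dii_quartile = d$dii_quartile), "y")
  expect_lt(tr_dec$slope, 0)
})

test_that("interaction test is symmetric in stratum labels and has power", {
  set.seed(44)
  cell <- matrix(0, 4, 2)
  cell[, 1] <- c(0, 1, 2, 3) * 0.25    # opposite quartile slopes by stratum
  cell[, 2] <- -c(0, 1, 2, 3) * 0.25
  d <- model_frame(4480, cell_logor = cell)
  pi1 <- p_interaction(d, "y")
  expect_lt(pi1$p, 0.01)

  d_swap <- d
  d_swap$stratum <- 1 - d$stratum
  pi2 <- p_interaction(d_swap, "y")
  expect_equal(pi2$p, pi1$p, tolerance = 1e-8)

  # categorical form also detects it
  expect_lt(p_interaction(d, "y", quartile_form = "categorical")$p, 0.01)
})

test_that("baseline linear trends recover stratum-specific slopes", {
  set.seed(45)
  n <- 4480
  dii <- rnorm(n, 0, 1.8)
  s <- rbinom(n, 1, 0.5)
  y <- 25 + (-0.2) * dii * (s == 0) + 0 * dii * (s == 1) + rnorm(n, 0, 1)
  d <- tibble::tibble(bmi_baseline = y, dii = dii, stratum = s)
  res <- baseline_linear_trend(d, "bmi_baseline")
  expect_lt(abs(res$by_stratum$slope[res$by_stratum$stratum == 0] + 0.2),
            0.05)
  expect_lt(abs(res$by_stratum$slope[res$by_stratum$stratum == 1]), 0.05)
  expect_lt(res$p_interaction, 0.001)

  # near-noiseless recovery and permutation invariance
  d2 <- tibble::tibble(bmi_baseline = 2 * dii + rnorm(n, 0, 1e-6),
                       dii = dii, stratum = s)
  res2 <- baseline_linear_trend(d2, "bmi_baseline")
  expect_equal(res2$by_stratum$slope, c(2, 2), tolerance = 1e-4)
  perm <- sample(n)
  res3 <- baseline_linear_trend(d2[perm, ], "bmi_baseline")
  expect_equal(res3$by_stratum$slope, res2$by_stratum$slope,
               tolerance = 1e-8)
})
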