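# The elementary samplers, the cost-per-SVR engine and its analytic oracle.

test_that("SVR sampling covers the range and has the uniform mean", {
  expect_equal(sample_svr(0.959, 0.959, 5), rep(0.959, 5)) # point estimate

  set.seed(11)
  x <- sample_svr(0.38, 0.39, 10000)
  expect_true(all(x >= 0.38 & x <= 0.39))
  se <- 0.01 / sqrt(12 * 10000)
  expect_lt(abs(mean(x) - 0.385), 3 * se)

  # a zero floor is a legal range and can yield draws near zero
  y <- sample_svr(0, 0.08, 1000)
  expect_true(all(y >= 0 & y <= 0.08))

  expect_error(sample_svr(0.5, 0.4), "invalid SVR range")
})

test_that("course-cost sampling hits both response-guided variants", {
  expect_equal(sample_course_cost(45000, NA, 3), rep(45000, 3))

  set.seed(12)
  x <- sample_course_cost(4200, 8400, 10000)
  expect_true(all(x %in% c(4200, 8400)))
  se <- 2100 / sqrt(10000) # Bernoulli(1/2) mixture sd = half-gap
  expect_lt(abs(mean(x) - 6300), 3 * se)

  y <- sample_course_cost(30200, 34300, 500)
  expect_true(all(y %in% c(30200, 34300)))
})

test_that("cost per SVR is the cost/probability ratio with the right monotonicity", {
  expect_equal(cost_per_svr(45000, 0.959), 46923.8790, tolerance = 1e-7)
  expect_equal(cost_per_svr(41900, 0.385), 108831.169, tolerance = 1e-7)
  expect_equal(cost_per_svr(12345, 1), 12345) # perfect efficacy

  # strictly decreasing in svr, strictly increasing in cost
  svr_grid <- seq(0.1, 1, by = 0.05)
  expect_true(all(diff(cost_per_svr(41900, svr_grid)) < 0))
  cost_grid <- seq(1000, 90000, by = 5000)
  expect_true(all(diff(cost_per_svr(cost_grid, 0.5)) > 0))

  expect_equal(cost_per_svr(100, 0), Inf) # guarded downstream
  expect_error(cost_per_svr(-5, 0.5), "positive")
})

test_that("the closed-form mean matches independent numeric integration", {
  # independent oracle: E[cost] * mean of 1/s over the uniform range
  num_mean <- function(cost_mean, lo, hi) {
    cost_mean * integrate(function(s) 1 / s, lo, hi)$value / (hi - lo)
  }
  expect_equal(
    analytic_mean_cost_per_svr(41900, NA, 0.38, 0.39),
    num_mean(41900, 0.38, 0.39),
    tolerance = 1e-9
  )
  expect_equal(analytic_mean_cost_per_svr(41900, NA, 0.38, 0.39),
    108837.3, tolerance = 1e-6)
  expect_equal(
    analytic_mean_cost_per_svr(4200, 8400, 0.35, 0.50),
    num_mean(6300, 0.35, 0.50),
    tolerance = 1e-9
  )
  expect_equal(analytic_mean_cost_per_svr(4200, 8400, 0.35, 0.50),
    14980.35, tolerance = 1e-6)
  # degenerate limit
  expect_equal(analytic_mean_cost_per_svr(45000, NA, 0.959, 0.959), 45000 / 0.959)
  # no closed form at a zero floor
  expect_warning(
    out <- analytic_mean_cost_per_svr(41900, NA, 0, 0.34),
    "no closed-form"
  )
  expect_true(is.na(out))
})

test_that("Monte Carlo cost per SVR agrees with the oracle and collapses when degenerate", {
  fix <- croatia_gt1_therapies()
  boc <- dplyr::filter(fix, therapy == "BOC+pegIFN", history == "null_responder",
    subtype == "GT1a", cirrhosis == "none")

  set.seed(5)
  s <- mc_cost_per_svr(boc, n_runs = 10000)
  target <- analytic_mean_cost_per_svr(41900, NA, 0.38, 0.39)
  expect_lt(abs(s$mean - target), 3 * s$sd / sqrt(s$n_runs))
  expect_true(s$min <= s$mean && s$mean <= s$max)
  expect_equal(s$n_excluded, 0)

  # degenerate cell: exact ratio, zero spread, no RNG consumed
  obv <- dplyr::filter(fix, therapy == "OBV/PTV/r/DSV", history == "naive",
    subtype == "GT1a", cirrhosis == "none")
  d <- mc_cost_per_svr(obv, n_runs = 7)
  expect_equal(d$mean, 45000 / 0.959)
  expect_equal(c(d$min, d$max), rep(45000 / 0.959, 2))
  expect_equal(d$sd, 0)

  # ineligible cells are refused
  peg <- dplyr::filter(fix, therapy == "pegIFN", history == "relapser",
    subtype == "GT1a", cirrhosis == "none")
  expect_error(mc_cost_per_svr(peg), "not an admissible comparator")
})

test_that("the cost-effectiveness table is deterministic and internally consistent", {
  fix <- croatia_gt1_therapies()
  cfg <- ce_config(n_runs = 2000, seed = 99)
  a <- ce_table(fix, cfg)
  b <- ce_table(fix, cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 68) # one row per eligible cell

  # empirical means track the closed form wherever it exists
  with_oracle <- dplyr::filter(a, !is.na(analytic_mean))
  err <- abs(with_oracle$mean_cost_per_svr - with_oracle$analytic_mean)
  expect_true(all(err <= 4 * with_oracle$sd_cost_per_svr / sqrt(cfg$n_runs) + 1e-9))
})

test_that("savings per SVR pairs draws and decomposes into the two means", {
  fix <- croatia_gt1_therapies()
  cfg <- ce_config(n_runs = 4000, seed = 3)
  sav <- savings_table(fix, cfg)

  expect_true(all(sav$savings_min <= sav$savings_mean &
    sav$savings_mean <= sav$savings_max))
  expect_equal(sav$savings_mean, sav$rival_mean - sav$entrant_mean,
    tolerance = 1e-9)

  # entrant vs BOC for non-cirrhotic null responders: savings close to the
  # difference of closed-form means (~ 108837 - 47170 = 61668)
  cell <- dplyr::filter(sav, rival == "BOC+pegIFN", history == "null_responder",
    subtype == "GT1a", cirrhosis == "none")
  target <- analytic_mean_cost_per_svr(41900, NA, 0.38, 0.39) - 45000 / 0.954
  expect_lt(abs(cell$savings_mean - target),
    3 * cell$savings_sd / sqrt(cell$n_runs))

  # self-comparison is identically zero
  entrant <- dplyr::filter(fix, is_new_entrant, history == "null_responder",
    subtype == "GT1a", cirrhosis == "none")
  rival_same <- dplyr::mutate(entrant, therapy = "clone", is_new_entrant = FALSE)
  set.seed(1)
  self <- savings_per_svr(entrant, rival_same, n_runs = 100)
  expect_equal(self$savings_mean, 0)
  expect_equal(self$savings_sd, 0)

  expect_error(
    savings_per_svr(entrant, dplyr::mutate(rival_same, history = "relapser")),
    "same subgroup"
  )
})
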