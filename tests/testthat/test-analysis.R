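test_that("percentage taken is relative to the available stock", {
  expect_equal(percentage_taken(20, 160), 12.5)
  expect_equal(percentage_taken(0, 160), 0)
  expect_equal(percentage_taken(39.5, 160), 24.6875)
  expect_true(is.na(percentage_taken(0, 0)))
})

test_that("window averaging uses periods 1-5 and skips exhausted periods", {
  tr <- data.frame(
    participant = "p1", system = "individual", period = 1:6,
    resource_before = c(100, 100, 100, 100, 100, 100),
    extraction = c(10, 10, 10, 20, 20, 90),
    exhausted = FALSE
  )
  expect_equal(average_percentage(tr)$avg_pct, 14) # period 6 excluded
  tr$resource_before[4:5] <- 0
  tr$exhausted[4:5] <- TRUE
  expect_equal(average_percentage(tr)$avg_pct, 10) # exhausted dropped
  expect_equal(average_percentage(tr, exhausted_policy = "zero")$avg_pct, 6)
  tr$resource_before <- 0
  expect_true(is.na(average_percentage(tr)$avg_pct))
})

test_that("zero-noise simulation recovers the configured rate exactly", {
  cfg <- game_config()
  params <- deterministic_params(12.5)
  d <- run_experiment(experiment_design(2, 2, params), seed = 4)
  ap <- average_percentage(d$trials)
  expect_equal(unique(ap$avg_pct), 12.5)
  pr <- profit_summary(d$trials)
  # 20 units in each of 5 periods at 0.01 EUR
  expect_equal(unique(pr$profit[pr$system == "individual"]), 1)
})

test_that("median sessions give identical profits to all four members", {
  params <- deterministic_params(12.5)
  params$target_rate_sd[] <- 2
  d <- run_experiment(experiment_design(3, 0, params), seed = 21)
  pr <- profit_summary(d$trials)
  med <- pr[pr$system == "median", ]
  for (g in unique(med$group)) {
    expect_equal(length(unique(med$profit[med$group == g])), 1L)
  }
})

test_that("voting success counts elected window periods per group", {
  tr <- expand.grid(group = c("G1", "G2"), member = 1:4, period = 1:6)
  tr$system <- "voting"
  tr$elected <- tr$group == "G1" & tr$period %in% c(1, 3, 5)
  sc <- voting_success_count(tr)
  expect_equal(sc$success_count[sc$group == "G1"], 3L)
  expect_equal(sc$success_count[sc$group == "G2"], 0L)
  tr$elected <- TRUE
  expect_equal(voting_success_count(tr)$success_count, c(5L, 5L))
})

test_that("proposal features: mean rate, deviation from 12.5, spread", {
  f <- proposal_features(c(20, 20, 20, 20), 160)
  expect_equal(unname(f), c(12.5, 0, 0))
  f2 <- proposal_features(c(32, 32, 8, 8), 160)
  expect_equal(f2[["mean_rate"]], 12.5)
  expect_equal(f2[["deviation"]], 0)
  expect_equal(f2[["spread"]], sd(c(20, 20, 5, 5)))
  expect_equal(round(f2[["spread"]], 2), 8.66)
  f3 <- proposal_features(c(40, 40, 40, 40), 160)
  expect_equal(unname(f3), c(25, 12.5, 0))
})

test_that("election logit recovers generating coefficients and ORs", {
  set.seed(123)
  n <- 5000
  feats <- data.frame(mean_rate = rnorm(n, 12.5, 4),
                      spread = abs(rnorm(n, 0, 2)))
  feats$deviation <- abs(feats$mean_rate - 12.5)
  eta <- 1.5 - 0.10 * feats$mean_rate - 0.44 * feats$deviation -
    0.75 * feats$spread
  elected <- runif(n) < plogis(eta)
  fit <- fit_election_logit(feats, elected)
  expect_true(fit$converged)
  expect_false(fit$separation)
  b <- fit$coefficients
  expect_lt(abs(b[["mean_rate"]] + 0.10), 0.1)
  expect_lt(abs(b[["deviation"]] + 0.44), 0.1)
  expect_lt(abs(b[["spread"]] + 0.75), 0.1)
  expect_equal(fit$odds_ratios, exp(b))
  expect_error(fit_election_logit(feats[1:10, ], elected[1:10]),
               "at least 20")
})

test_that("composites average the six items; missing blocks stay missing", {
  expect_equal(composite_rating(rep(5, 6)), 5)
  expect_equal(composite_rating(c(1, 1, 1, 7, 7, 7)), 4)
  expect_equal(composite_rating(c(4, 5, 6, 4, 5, 6)), 5)
  expect_true(is.na(composite_rating(c(4, 5, NA, 4, 5, 6))))
  m <- rbind(rep(5, 6), rep(NA, 6), c(1, 1, 1, 7, 7, 7))
  expect_equal(composite_rating(m), c(5, NA, 4))
  expect_equal(composite_rating(c(4, 4, 4, 4, 4, 2),
                                reverse_greed = TRUE), 4.333333,
               tolerance = 1e-6)
  expect_error(composite_rating(c(0, 5, 5, 5, 5, 5)), "\\[1, 7\\]")
})

test_that("alpha matches the covariance-formula oracle and its limits", {
  set.seed(31)
  # perfectly correlated items
  x <- rnorm(50)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1)
  # independent items at large n: near zero
  ind <- matrix(rnorm(3 * 20000), ncol = 3)
  expect_lt(abs(cronbach_alpha(ind)), 0.05)
  # random 5x3 matrices against the brute-force oracle
  for (i in 1:20) {
    m <- matrix(sample(1:7, 15, replace = TRUE), nrow = 5)
    if (var(rowSums(m)) < 1e-12) next
    expect_equal(cronbach_alpha(m), alpha_oracle(m))
  }
  expect_warning(a0 <- cronbach_alpha(matrix(1, 5, 3)), "zero total")
  expect_true(is.na(a0))
})

test_that("one-way ICC matches the aov oracle and recovers the truth", {
  # zero within-group variance
  g <- rep(1:4, each = 3)
  v <- rep(c(1, 5, 9, 13), each = 3)
  expect_equal(icc(g, v), 1)
  # random small layouts against the aov-based oracle
  set.seed(17)
  for (i in 1:20) {
    gg <- rep(1:5, each = 3)
    vv <- rnorm(15, mean = rep(rnorm(5, sd = 2), each = 3))
    expect_equal(icc(gg, vv), icc_oracle(gg, vv))
  }
  # simulation recovery at 500 groups of 12: sigma_b = 1, sigma_w = 3
  set.seed(170)
  gg <- rep(1:500, each = 12)
  vv <- rnorm(500)[gg] + rnorm(6000, sd = sqrt(3))
  expect_lt(abs(icc(gg, vv) - 0.25), 0.03)
  expect_warning(icc(rep(1, 5), rnorm(5)), "degenerate")
})

test_that("indirect effect is the exact product of the two paths", {
  set.seed(8)
  n <- 80
  x <- rep(c(-0.5, 0.5), n / 2)
  m <- -1.15 * x + rnorm(n)
  y <- 0.38 * m - 0.2 * x + rnorm(n)
  res <- indirect_effect(x, m, y, reps = 500, seed = 2)
  expect_equal(res$indirect, res$a * res$b)
  expect_lt(res$ci[1], res$ci[2])
  # paths agree with lm() fits
  expect_equal(res$a, unname(coef(lm(m ~ x))[2]))
  fit2 <- lm(y ~ m + x)
  expect_equal(res$b, unname(coef(fit2)[2]))
  expect_equal(res$direct, unname(coef(fit2)[3]))
  # condition labels are coded symmetric negative
  lab <- ifelse(x > 0, "asymmetric", "symmetric")
  res2 <- indirect_effect(lab, m, y, reps = 500, seed = 2)
  expect_equal(res2$indirect, res$indirect)
  expect_error(indirect_effect(rep(0.5, n), m, y, reps = 100),
               "degenerate")
  expect_warning(indirect_effect(x, m, y, reps = 50), "fewer than 100")
})

test_that("trajectory projection follows the exact regeneration law", {
  p <- project_trajectory(12.92)
  expect_equal(p$final_rounded, 130)
  expect_equal(p$final, 160 * (2 * (1 - 4 * 0.1292))^6)
  expect_equal(project_trajectory(12.5, n_periods = 50)$final, 160)
  expect_equal(project_trajectory(25, n_periods = 1)$final, 0)
  expect_equal(project_trajectory(30, n_periods = 3)$final, 0) # clipped
  expect_equal(project_trajectory(0)$final, 160) # cap binds throughout
})

test_that("contrast coding matches the reported scheme", {
  df <- expand.grid(system = c("individual", "median", "voting"),
                    condition = c("symmetric", "asymmetric"),
                    role = c("symmetric", "advantaged", "disadvantaged"),
                    stringsAsFactors = FALSE)
  df <- df[(df$condition == "symmetric") == (df$role == "symmetric"), ]
  cc <- contrast_code(df)
  ind <- cc[cc$system == "individual", ]
  expect_true(all(ind$Median == 0 & ind$MVoting == 0))
  row <- cc[cc$system == "median" & cc$role == "advantaged", ]
  expect_equal(row$Median, 1)
  expect_equal(row$Asymmetry, 0.5)
  expect_equal(row$Advantaged, 0.5)
  expect_true(all(cc$Advantaged[cc$condition == "symmetric"] == 0))
  # balanced design: contrasts centre at zero
  bal <- contrast_code(data.frame(
    system = "individual",
    condition = rep(c("symmetric", "asymmetric"), each = 2),
    role = c("symmetric", "symmetric", "advantaged", "disadvantaged")))
  expect_equal(mean(bal$Asymmetry), 0)
  expect_equal(mean(bal$Advantaged), 0)
  expect_error(contrast_code(data.frame(system = "plurality",
                                        condition = "symmetric",
                                        role = "symmetric")),
               "unknown system")
})
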