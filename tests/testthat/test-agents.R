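test_that("population sampling respects roles, seeds and zero spread", {
  cfg <- game_config(condition = "asymmetric")
  params <- deterministic_params(12.5)
  pop <- sample_population(cfg, params, n_groups = 5, seed = 1)
  expect_length(pop, 5)
  roles <- vapply(pop[[1]], `[[`, character(1), "role")
  expect_equal(sum(roles == "advantaged"), 2)
  expect_equal(sum(roles == "disadvantaged"), 2)
  # zero SD: every rate is exactly the cell mean
  rates <- unlist(lapply(pop, function(g)
    lapply(g, function(a) a$rates)))
  expect_true(all(rates == 12.5))
  # reproducible under the same seed
  pop2 <- sample_population(cfg, params, n_groups = 5, seed = 1)
  expect_identical(pop, pop2)
})

test_that("sampled person rates recover the cell mean at large n", {
  cfg <- game_config()
  params <- behavior_params()
  params$target_rate_mean["individual", "symmetric"] <- 13.20
  pop <- sample_population(cfg, params, n_groups = 250, seed = 99)
  rates <- vapply(unlist(pop, recursive = FALSE),
                  function(a) a$rates[["individual"]], numeric(1))
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 13.20), 3 * se)
})

test_that("individual decisions follow rate, caps and the end-game grab", {
  cfg <- game_config()
  params <- deterministic_params(12.5)
  a <- fixed_agents(rep(12.5, 4))[[1]]
  expect_equal(decide_individual(a, 160, 1, cfg, params), 20)

  pgrab <- deterministic_params(12.5)
  pgrab$endgame_exploit_prob <- 1
  expect_equal(decide_individual(a, 160, 6, cfg, pgrab), 40)

  adv <- fixed_agents(rep(30, 4),
                      roles = rep("advantaged", 4))[[1]]
  p30 <- deterministic_params(12.5)
  expect_equal(decide_individual(adv, 160, 1, cfg, p30), 48)
  # cap binds above 1/3
  adv$rates[] <- 33.3
  expect_equal(decide_individual(adv, 160, 1, cfg, p30), 53)
})

test_that("median proposals feed the worked median rule", {
  cfg <- game_config()
  params <- deterministic_params(12.5)
  agents <- fixed_agents(c(6.25, 7.5, 8.75, 10))
  props <- vapply(agents, propose_median, numeric(1),
                  units_available = 160, config = cfg, params = params)
  expect_equal(props, c(10, 12, 14, 16))
  expect_equal(resolve_median(props)$implemented_level, 13)
  # proposer bounded by own cap
  capped <- fixed_agents(rep(33.3, 4), roles = rep("advantaged", 4))[[1]]
  expect_equal(propose_median(capped, 160, cfg, params), 53)
})

test_that("allocation proposals are equal splits or self-favouring", {
  cfg <- game_config()
  params <- deterministic_params(12.5, coop = 1)
  roles <- rep("symmetric", 4)
  a <- fixed_agents(rep(12.5, 4))[[1]]
  expect_equal(propose_allocation(a, roles, 160, cfg, params)$allocation,
               c(20, 20, 20, 20))
  pself <- deterministic_params(12.5, coop = 0)
  set.seed(1)
  alloc <- propose_allocation(a, roles, 160, cfg, pself)$allocation
  expect_equal(which.max(alloc), a$member)
  expect_true(all(alloc[-a$member] < alloc[a$member]))
  expect_lte(sum(alloc), 160)
})

test_that("non-elected proposals vary more between members than elected", {
  cfg <- game_config()
  params <- deterministic_params(12.5, coop = 0.75)
  agents <- fixed_agents(rep(12.5, 4))
  set.seed(7)
  feats <- list()
  for (i in 1:1000) {
    props <- lapply(agents, propose_allocation, roles = group_roles(cfg),
                    units_available = 160, config = cfg, params = params)
    pooled <- pool_identical(props)
    ballots <- vapply(1:4, function(m) cast_vote(m, pooled), integer(1))
    vr <- tally(ballots, pooled)
    for (j in seq_along(props)) {
      f <- proposal_features(props[[j]]$allocation, 160)
      feats[[length(feats) + 1L]] <- data.frame(
        spread = f[["spread"]],
        elected = !vr$fallback &&
          j %in% pooled[[max(vr$elected, 1, na.rm = TRUE)]]$proposers)
    }
  }
  feats <- do.call(rbind, feats)
  expect_true(any(feats$elected) && any(!feats$elected))
  expect_gt(mean(feats$spread[!feats$elected]),
            mean(feats$spread[feats$elected]))
})

test_that("ballots go to the own-payoff-maximising proposal", {
  two <- list(list(allocation = c(20, 20, 20, 20), proposers = 1),
              list(allocation = c(26, 18, 18, 18), proposers = 2))
  expect_equal(cast_vote(1, two), 2L) # 26 beats 20
  expect_equal(cast_vote(3, two), 1L) # 20 beats 18
  # tie on own units: lower spread wins
  tie <- list(list(allocation = c(20, 30, 10, 20), proposers = 1),
              list(allocation = c(20, 20, 20, 20), proposers = 2))
  expect_equal(cast_vote(1, tie), 2L)
  # three identical cooperators + one self-favourer: 3-1 election
  props <- c(lapply(1:3, function(i) list(proposer = i,
                                          allocation = rep(20, 4))),
             list(list(proposer = 4, allocation = c(14, 14, 14, 30))))
  pooled <- pool_identical(props)
  ballots <- vapply(1:4, function(m) cast_vote(m, pooled), integer(1))
  vr <- tally(ballots, pooled)
  expect_equal(vr$vote_counts, c(3, 1))
  expect_equal(vr$elected, 1L)
})

test_that("ratings stay on the 1-7 scale and track the latent mean", {
  params <- deterministic_params(12.5)
  params$rating_model$residual_sd <- 0
  params$rating_model$asym_gap <- 0
  params$rating_model$advantaged_gap <- 0
  a <- fixed_agents(rep(12.5, 4))[[1]]
  expect_equal(sample_ratings(a, "median", "symmetric", params),
               rep(5L, 6)) # latent 5.03 rounds to 5
  params$rating_model$base[] <- 9
  expect_equal(sample_ratings(a, "individual", "symmetric", params),
               rep(7L, 6)) # clamped at the top of the scale
  # Monte-Carlo self-consistency of a cell mean
  p2 <- deterministic_params(12.5)
  p2$rating_model$asym_gap <- 0
  p2$rating_model$advantaged_gap <- 0
  set.seed(5)
  comps <- replicate(2000, {
    ag <- list(role = "symmetric",
               rating_effect = rnorm(1, 0, p2$rating_model$person_sd))
    mean(sample_ratings(ag, "individual", "symmetric", p2))
  })
  se <- sd(comps) / sqrt(length(comps))
  expect_lt(abs(mean(comps) - 4.12), 3 * se + 0.05)
})
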