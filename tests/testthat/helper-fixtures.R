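# Deterministic behaviour parameters: every agent targets `rate` percent
# in every system, no person-level spread, no period noise, no end-game
# grab; `coop` controls the majority-voting proposal style.
deterministic_params <- function(rate = 12.5, coop = 1, missing = 0) {
  roles <- c("symmetric", "advantaged", "disadvantaged")
  m <- matrix(rate, 3, 3,
              dimnames = list(c("individual", "median", "voting"), roles))
  # cell means cannot exceed the role's cap share
  m <- pmin(m, rep(100 * commonpool::role_share(roles), each = 3))
  behavior_params(
    target_rate_mean = m,
    target_rate_sd = m * 0,
    rate_noise_sd = c(individual = 0, median = 0, voting = 0),
    endgame_exploit_prob = 0,
    cooperativeness = c(symmetric = coop, asymmetric = coop),
    missingness_prob = missing
  )
}

# One group of four agents with fixed per-system target rates.
fixed_agents <- function(rates, roles = rep("symmetric", 4)) {
  lapply(seq_along(roles), function(i) {
    list(id = sprintf("T_P%d", i),
         member = i,
         role = roles[i],
         rates = c(individual = rates[i], median = rates[i],
                   voting = rates[i]),
         rating_effect = 0)
  })
}

# Brute-force Cronbach's alpha from the covariance matrix:
# alpha = k/(k-1) * (1 - trace(C) / sum(C)).
alpha_oracle <- function(m) {
  C <- stats::cov(m)
  k <- ncol(m)
  k / (k - 1) * (1 - sum(diag(C)) / sum(C))
}

# One-way ICC oracle via stats::aov mean squares (independent code path
# from the package's hand computation).
icc_oracle <- function(group, values) {
  group <- factor(group)
  fit <- stats::aov(values ~ group)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msb <- ms[1]; msw <- ms[2]
  nj <- table(group)
  N <- length(values); J <- nlevels(group)
  k0 <- (N - sum(nj^2) / N) / (J - 1)
  sb <- max((msb - msw) / k0, 0)
  sb / (sb + msw)
}
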