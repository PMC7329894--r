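#' Behavioural parameters of the synthetic participants
#'
#' The study's participants were human; this generator is a declared
#' synthetic stand-in whose defaults are calibrated so that the simulated
#' cohort reproduces the published cell means and dispersions of the
#' human data. Person-level target extraction rates (percent of the
#' available stock) are drawn per system-by-role cell from a truncated
#' normal; within-person period noise, a Bernoulli end-game cap grab in
#' the final period, a cooperativeness probability governing whether a
#' member proposes the equal sustainable split in majority voting, and a
#' latent-normal rating model for the six 1-7 satisfaction/fairness items
#' complete the behaviour model.
#'
#' Default calibration (all overridable):
#' * `target_rate_mean` / `target_rate_sd` — individual choice: 13.46
#'   (symmetric), 17.44 (advantaged), 12.92 (disadvantaged), SD 5.2;
#'   median proposals: 13.32 everywhere, SD 1.49; voting fallback: 13.0 /
#'   16.5 / 12.5, SD 3.6. The symmetric individual-choice mean is the
#'   value implied by the overall individual-choice mean of 14.46 with
#'   104 symmetric and 144 asymmetric participants.
#' * `cooperativeness` — 0.71 (symmetric) / 0.58 (asymmetric): the
#'   probability that at least 3 of 4 members propose the identical equal
#'   split then matches the observed voting-success means.
#' * `endgame_exploit_prob` — 0.6: probability of extracting at cap in
#'   the final period.
#' * `rating_model` — per-system latent means 4.12 / 5.03 / 4.82, a 0.43
#'   symmetric-vs-asymmetric gap, a 0.27 advantaged-vs-disadvantaged gap,
#'   and for the voting system a slope of 0.38 on the group's voting
#'   success count (centred at 2.69).
#'
#' @param target_rate_mean 3x3 matrix (systems x roles) of cell means, %.
#' @param target_rate_sd 3x3 matrix of person-level SDs, %.
#' @param rate_noise_sd Named numeric: within-person per-period SD, %.
#' @param endgame_exploit_prob Probability of a final-period cap grab.
#' @param cooperativeness Named numeric per condition: probability of
#'   proposing the equal sustainable split in majority voting.
#' @param self_favour_gap Percentage points a self-favouring proposal
#'   adds to the proposer's own rate; the other members are lowered by
#'   half the compensating amount, so such proposals also raise the mean.
#' @param rate_person_cor Weight of the shared person effect in each
#'   system's rate draw (1 = a single effect shared across systems; the
#'   cross-system correlation of rate effects is its square).
#' @param rating_model List: `base` (per-system latent means),
#'   `asym_gap`, `advantaged_gap`, `success_slope`, `success_center`,
#'   `person_sd`, `residual_sd`.
#' @param missingness_prob Probability that a group's voting-system
#'   rating block is lost (emulating technical loss).
#' @return A `behavior_params` object (validated list).
#' @export
behavior_params <- function(
    target_rate_mean = NULL,
    target_rate_sd = NULL,
    rate_noise_sd = c(individual = 2, median = 1, voting = 2),
    endgame_exploit_prob = 0.6,
    cooperativeness = c(symmetric = 0.71, asymmetric = 0.58),
    self_favour_gap = 6,
    rate_person_cor = 0.8,
    rating_model = list(
      base = c(individual = 4.12, median = 5.03, voting = 4.82),
      asym_gap = 0.43,
      advantaged_gap = 0.27,
      success_slope = 0.38,
      success_center = 2.69,
      person_sd = 0.9,
      residual_sd = 1.2
    ),
    missingness_prob = 1 / 62) {
  systems <- c("individual", "median", "voting")
  roles <- c("symmetric", "advantaged", "disadvantaged")
  if (is.null(target_rate_mean)) {
    target_rate_mean <- rbind(
      individual = c(13.46, 17.44, 12.92),
      median     = c(13.32, 13.32, 13.32),
      voting     = c(13.00, 16.50, 12.50)
    )
    colnames(target_rate_mean) <- roles
  }
  if (is.null(target_rate_sd)) {
    target_rate_sd <- rbind(
      individual = c(5.2, 5.2, 5.2),
      median     = c(1.49, 1.49, 1.49),
      voting     = c(3.6, 3.6, 3.6)
    )
    colnames(target_rate_sd) <- roles
  }
  stopifnot(
    all(rownames(target_rate_mean) == systems),
    all(colnames(target_rate_mean) == roles),
    all(dim(target_rate_mean) == c(3, 3)),
    all(dim(target_rate_sd) == c(3, 3)),
    all(target_rate_sd >= 0),
    all(target_rate_mean >= 0),
    all(target_rate_mean <= 100 * rep(role_share(roles), each = 3)),
    all(rate_noise_sd >= 0),
    endgame_exploit_prob >= 0, endgame_exploit_prob <= 1,
    all(cooperativeness >= 0), all(cooperativeness <= 1),
    self_favour_gap >= 0,
    rate_person_cor >= 0, rate_person_cor <= 1,
    missingness_prob >= 0, missingness_prob <= 1
  )
  structure(
    list(target_rate_mean = target_rate_mean,
         target_rate_sd = target_rate_sd,
         rate_noise_sd = rate_noise_sd,
         endgame_exploit_prob = endgame_exploit_prob,
         cooperativeness = cooperativeness,
         self_favour_gap = self_favour_gap,
         rate_person_cor = rate_person_cor,
         rating_model = rating_model,
         missingness_prob = missingness_prob),
    class = "behavior_params"
  )
}

#' Sample a synthetic population
#'
#' Draws `n_groups` groups of four agents for the given condition.
#' Asymmetric groups contain exactly two advantaged and two disadvantaged
#' members. Each agent's person effect is a mixture of one shared
#' standard-normal draw (weight `rate_person_cor`) and a system-specific
#' draw; the person-level target rate in each system cell is the cell
#' mean plus the person effect times the cell SD, clamped to
#' `[0, cap share * 100]`.
#'
#' @param config A [game_config()]; its `condition` decides the roles.
#' @param params A [behavior_params()].
#' @param n_groups Number of groups to draw.
#' @param seed Optional integer seed.
#' @return List of groups; each group is a list of 4 agents with fields
#'   `id`, `member` (position 1-4), `role`, `rates` (named per system),
#'   `rating_effect`.
#' @export
sample_population <- function(config, params, n_groups, seed = NULL) {
  stopifnot(inherits(config, "game_config"),
            inherits(params, "behavior_params"), n_groups >= 1)
  if (!is.null(seed)) set.seed(seed)
  roles <- group_roles(config)
  systems <- rownames(params$target_rate_mean)
  lapply(seq_len(n_groups), function(g) {
    lapply(seq_along(roles), function(i) {
      role <- roles[i]
      # one shared person effect plus a system-specific component, so
      # rates correlate (but not perfectly) across systems
      rho <- params$rate_person_cor
      z <- rho * stats::rnorm(1) +
        sqrt(1 - rho^2) * stats::rnorm(length(systems))
      rates <- params$target_rate_mean[, role] +
        z * params$target_rate_sd[, role]
      rates <- pmin(pmax(rates, 0), 100 * role_share(role))
      list(id = sprintf("g%03d_p%d", g, i),
           member = i,
           role = role,
           rates = stats::setNames(as.numeric(rates), systems),
           rating_effect = stats::rnorm(1, 0,
                                        params$rating_model$person_sd))
    })
  })
}

#' Individual extraction decision
#'
#' Request = the agent's target rate for the current system plus period
#' noise, applied to the current stock, rounded to whole units and
#' clamped to `[0, limit]`. In the final period the agent grabs the full
#' cap with probability `endgame_exploit_prob` (sustaining the stock no
#' longer pays).
#'
#' @param agent An agent from [sample_population()].
#' @param units_available Current stock.
#' @param period Current period index.
#' @param config A [game_config()].
#' @param params A [behavior_params()].
#' @param system Which system's target rate to use (`"individual"` for
#'   individual choice, `"voting"` for the voting fallback).
#' @return Whole-unit extraction request.
#' @export
decide_individual <- function(agent, units_available, period, config, params,
                              system = "individual") {
  limit <- extraction_limit(units_available, agent$role)
  if (period == config$periods_per_system &&
      stats::runif(1) < params$endgame_exploit_prob) {
    return(limit)
  }
  rate <- agent$rates[[system]] +
    stats::rnorm(1, 0, params$rate_noise_sd[[system]])
  req <- round(rate / 100 * units_available)
  min(max(req, 0), limit)
}

#' Median-choice proposal (desired own extraction)
#'
#' Same decision rule as [decide_individual()] under the agent's median
#' -system target rate, without the end-game grab (the implemented level
#' is governed by the whole group's proposals), bounded by the proposer's
#' own cap.
#'
#' @inheritParams decide_individual
#' @return Whole-unit desired own extraction level.
#' @export
propose_median <- function(agent, units_available, config, params) {
  limit <- extraction_limit(units_available, agent$role)
  rate <- agent$rates[["median"]] +
    stats::rnorm(1, 0, params$rate_noise_sd[["median"]])
  req <- round(rate / 100 * units_available)
  min(max(req, 0), limit)
}

#' Majority-voting allocation proposal
#'
#' With probability `cooperativeness` the agent proposes an equal split
#' at the sustainable rate (feasible for every role, since 12.5% is below
#' even the disadvantaged cap of 1/6); otherwise a self-favouring
#' allocation that raises the proposer's own rate by `self_favour_gap`
#' percentage points and lowers each other member's by a third of it,
#' with all amounts clamped to the targets' caps.
#'
#' @param agent Proposing agent.
#' @param roles Role vector of the group.
#' @param units_available Current stock.
#' @param config A [game_config()].
#' @param params A [behavior_params()].
#' @return Proposal list: `proposer` (member index), `allocation`.
#' @export
propose_allocation <- function(agent, roles, units_available, config,
                               params) {
  n <- length(roles)
  srate <- sustainable_rate(config)
  coop_p <- params$cooperativeness[[config$condition]]
  if (stats::runif(1) < coop_p) {
    rates <- rep(srate, n)
  } else {
    # self-favouring proposals only half-compensate the other members,
    # so they are also greedier on average (higher mean rate)
    rates <- rep(srate - params$self_favour_gap / (2 * (n - 1)), n)
    rates[agent$member] <- srate + params$self_favour_gap
  }
  units <- round(rates / 100 * units_available)
  if (config$enforce_caps_in_proposals) {
    limits <- vapply(roles, function(r)
      extraction_limit(units_available, r), numeric(1))
    units <- pmin(pmax(units, 0), limits)
  }
  # total at most ~50% of the stock by construction, but guard anyway
  if (sum(units) > units_available) {
    units <- floor(units * units_available / sum(units))
  }
  list(proposer = agent$member, allocation = as.numeric(units))
}

#' Cast a ballot over pooled proposals
#'
#' Votes for the pooled proposal that maximises the member's own
#' allocated units; ties are broken by the lower between-member standard
#' deviation of the allocation, then by earliest submission.
#'
#' @param member Member position (1-4).
#' @param pooled Pooled proposals from [pool_identical()].
#' @return Index of the chosen pooled proposal.
#' @export
cast_vote <- function(member, pooled) {
  stopifnot(length(pooled) >= 1)
  own <- vapply(pooled, function(p) p$allocation[member], numeric(1))
  spread <- vapply(pooled, function(p) stats::sd(p$allocation), numeric(1))
  best <- which(own == max(own))
  if (length(best) > 1L) {
    best <- best[spread[best] == min(spread[best])]
  }
  as.integer(best[1])
}

#' Sample the six satisfaction/fairness items after a system
#'
#' Six items are drawn from a latent normal whose mean is the system base
#' shifted by condition (+/- half the symmetric-asymmetric gap), role
#' (+/- half the advantaged-disadvantaged gap within asymmetric groups),
#' the agent's person effect, and — for the voting system — the group's
#' voting success count times `success_slope`. Items are rounded and
#' clamped to the 1-7 response scale.
#'
#' @param agent Agent (for role and person effect).
#' @param system System just played.
#' @param condition `"symmetric"` or `"asymmetric"`.
#' @param params A [behavior_params()].
#' @param success_count Voting success count of the group (used only for
#'   the voting system; ignored otherwise).
#' @return Integer vector of six items in 1..7.
#' @export
sample_ratings <- function(agent, system, condition, params,
                           success_count = NA_integer_) {
  rm <- params$rating_model
  latent <- rm$base[[system]] + agent$rating_effect
  latent <- latent + if (condition == "asymmetric") -rm$asym_gap / 2 else
    rm$asym_gap / 2
  if (agent$role == "advantaged") latent <- latent + rm$advantaged_gap / 2
  if (agent$role == "disadvantaged") latent <- latent - rm$advantaged_gap / 2
  if (system == "voting" && !is.na(success_count)) {
    latent <- latent + rm$success_slope * (success_count - rm$success_center)
  }
  items <- round(stats::rnorm(6, latent, rm$residual_sd))
  as.integer(pmin(pmax(items, 1), 7))
}
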