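#' Configuration of the common-pool resource game
#'
#' Bundles the parameters of the resource environment: a stock that starts
#' at `initial_units`, is harvested by `group_size` members each period,
#' and regenerates by `growth_factor` up to a ceiling of `cap_units`.
#' Members are paid `unit_value` money units per extracted unit at the end
#' of a session. The `condition` decides the cap structure: in a symmetric
#' group every member may take up to 1/4 of the current stock; in an
#' asymmetric group two advantaged members may take up to 1/3 and two
#' disadvantaged members up to 1/6.
#'
#' @param initial_units Stock size at the start of each choice system.
#' @param growth_factor Multiplier applied to the remaining stock after
#'   extraction (2 = doubling).
#' @param cap_units Ceiling the stock can never exceed; defaults to
#'   `initial_units`.
#' @param periods_per_system Number of periods played under each choice
#'   system.
#' @param group_size Number of members per group.
#' @param unit_value Money paid per extracted unit (EUR).
#' @param condition `"symmetric"` or `"asymmetric"` cap structure.
#' @param enforce_caps_in_proposals Should per-member allocations inside
#'   majority-voting proposals respect each target member's cap?
#'
#' @return An object of class `game_config` (a validated list).
#' @examples
#' cfg <- game_config()
#' sustainable_rate(cfg) # 12.5
#' @export
game_config <- function(initial_units = 160,
                        growth_factor = 2,
                        cap_units = initial_units,
                        periods_per_system = 6,
                        group_size = 4,
                        unit_value = 0.01,
                        condition = c("symmetric", "asymmetric"),
                        enforce_caps_in_proposals = TRUE) {
  condition <- match.arg(condition)
  stopifnot(
    is.numeric(initial_units), length(initial_units) == 1L, initial_units > 0,
    is.numeric(growth_factor), length(growth_factor) == 1L, growth_factor > 0,
    is.numeric(cap_units), length(cap_units) == 1L,
    cap_units >= initial_units,
    is.numeric(periods_per_system), periods_per_system >= 1,
    periods_per_system == as.integer(periods_per_system),
    is.numeric(group_size), group_size >= 2,
    group_size == as.integer(group_size),
    is.numeric(unit_value), unit_value >= 0,
    is.logical(enforce_caps_in_proposals)
  )
  structure(
    list(
      initial_units = as.numeric(initial_units),
      growth_factor = as.numeric(growth_factor),
      cap_units = as.numeric(cap_units),
      periods_per_system = as.integer(periods_per_system),
      group_size = as.integer(group_size),
      unit_value = as.numeric(unit_value),
      condition = condition,
      enforce_caps_in_proposals = isTRUE(enforce_caps_in_proposals)
    ),
    class = "game_config"
  )
}

#' @export
print.game_config <- function(x, ...) {
  cat("Common-pool resource game configuration\n")
  cat(sprintf("  initial stock %g, growth factor %g, cap %g\n",
              x$initial_units, x$growth_factor, x$cap_units))
  cat(sprintf("  %d members, %d periods per system, %s caps\n",
              x$group_size, x$periods_per_system, x$condition))
  cat(sprintf("  unit value %.2f EUR\n", x$unit_value))
  invisible(x)
}

# Cap shares by role: symmetric 1/4, advantaged 1/3, disadvantaged 1/6.
.role_shares <- c(symmetric = 1 / 4, advantaged = 1 / 3, disadvantaged = 1 / 6)

#' Extraction-cap share of a role
#'
#' @param role Character vector of roles (`"symmetric"`, `"advantaged"`,
#'   `"disadvantaged"`).
#' @return Numeric vector of cap fractions (1/4, 1/3, 1/6).
#' @export
role_share <- function(role) {
  bad <- setdiff(unique(role), names(.role_shares))
  if (length(bad) > 0) {
    stop("unknown role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(.role_shares[role])
}

#' Role composition of a group
#'
#' A symmetric group has four symmetric members; an asymmetric group has
#' exactly two advantaged and two disadvantaged members.
#'
#' @param config A [game_config()].
#' @return Character vector of length `group_size`.
#' @export
group_roles <- function(config) {
  if (config$condition == "symmetric") {
    rep("symmetric", config$group_size)
  } else {
    if (config$group_size != 4L) {
      stop("asymmetric condition is defined for groups of 4", call. = FALSE)
    }
    c("advantaged", "advantaged", "disadvantaged", "disadvantaged")
  }
}

#' Resource state at the start of a period
#'
#' @param units_available Non-negative stock size.
#' @param period_index Current period (1-based).
#' @return A `resource_state` list with fields `units_available`,
#'   `period_index` and `exhausted` (stock below one unit).
#' @export
resource_state <- function(units_available, period_index = 1L) {
  stopifnot(is.numeric(units_available), units_available >= 0,
            period_index >= 1)
  structure(
    list(units_available = as.numeric(units_available),
         period_index = as.integer(period_index),
         exhausted = units_available < 1),
    class = "resource_state"
  )
}

#' Per-period extraction limit of a member
#'
#' The limit is the member's cap share of the current stock. Requests are
#' in whole units, so fractional limits (1/3 or 1/6 of the stock) are
#' floored; an exact integer share is kept as is. An exhausted stock
#' (below one unit) gives a limit of zero.
#'
#' @param units_available Current stock (scalar) or a `resource_state`.
#' @param role Role name(s), recycled against nothing: vectorised over
#'   `role` for a single stock value.
#' @return Non-negative numeric vector of limits (whole units).
#' @examples
#' extraction_limit(160, "symmetric")    # 40
#' extraction_limit(160, "advantaged")   # 53
#' extraction_limit(12, "disadvantaged") # 2
#' @export
extraction_limit <- function(units_available, role) {
  if (inherits(units_available, "resource_state")) {
    units_available <- units_available$units_available
  }
  stopifnot(is.numeric(units_available), length(units_available) == 1L,
            units_available >= 0)
  if (units_available < 1) {
    return(rep(0, length(role)))
  }
  s <- role_share(role) * units_available
  ifelse(abs(s - round(s)) < 1e-9, round(s), floor(s))
}

#' Regenerate the stock after extraction
#'
#' The remaining units are multiplied by the growth factor and capped:
#' `min(growth_factor * (before - extracted), cap_units)`. Taking exactly
#' half of the stock therefore leaves it unchanged under doubling.
#'
#' @param resource_before Stock at the start of the period.
#' @param total_extracted Total units taken this period.
#' @param config A [game_config()].
#' @return Stock available in the next period.
#' @examples
#' cfg <- game_config()
#' regenerate(160, 80, cfg)  # 160
#' regenerate(160, 0, cfg)   # capped at 160
#' regenerate(100, 60, cfg)  # 80
#' @export
regenerate <- function(resource_before, total_extracted, config) {
  stopifnot(inherits(config, "game_config"),
            is.numeric(resource_before), resource_before >= 0,
            is.numeric(total_extracted), total_extracted >= 0)
  if (total_extracted > resource_before + 1e-9) {
    stop("total_extracted (", total_extracted,
         ") exceeds the available resource (", resource_before, ")",
         call. = FALSE)
  }
  min(config$growth_factor * (resource_before - total_extracted),
      config$cap_units)
}

#' Apply one period of extraction to the resource
#'
#' Validates the extraction vector against the members' current limits
#' (unless `override` is set, as under the median rule, whose common level
#' may exceed a disadvantaged member's cap), removes the units, and
#' regenerates the remainder.
#'
#' @param state A [resource_state()].
#' @param extractions Numeric vector of per-member extractions.
#' @param config A [game_config()].
#' @param roles Role vector, defaults to [group_roles()] of the config.
#' @param override If `TRUE`, per-member cap checks are skipped (the total
#'   must still not exceed the stock).
#' @return A list with `result` (a `period_result`: extractions, total,
#'   resource before/after, override flag, period index) and `state`
#'   (the `resource_state` for the next period).
#' @export
apply_period <- function(state, extractions, config,
                         roles = group_roles(config), override = FALSE) {
  stopifnot(inherits(state, "resource_state"),
            inherits(config, "game_config"),
            length(extractions) == config$group_size,
            length(roles) == config$group_size)
  if (any(extractions < 0)) {
    stop("negative extraction for member ",
         which(extractions < 0)[1], call. = FALSE)
  }
  if (!override) {
    limits <- vapply(roles, function(r)
      extraction_limit(state$units_available, r), numeric(1))
    over <- which(extractions > limits + 1e-9)
    if (length(over) > 0) {
      stop(sprintf(
        "member %d requested %g units, above the limit of %g",
        over[1], extractions[over[1]], limits[over[1]]), call. = FALSE)
    }
  }
  total <- sum(extractions)
  if (total > state$units_available + 1e-9) {
    stop("total extraction ", total, " exceeds the available resource ",
         state$units_available, call. = FALSE)
  }
  after <- regenerate(state$units_available, total, config)
  result <- structure(
    list(period_index = state$period_index,
         extractions = as.numeric(extractions),
         override = isTRUE(override),
         total_extracted = total,
         resource_before = state$units_available,
         resource_after = after),
    class = "period_result"
  )
  list(result = result,
       state = resource_state(after, state$period_index + 1L))
}

#' Sustainable equal per-member extraction rate
#'
#' The constant percentage of the current stock that each of the
#' `group_size` members can take every period while leaving the stock
#' unchanged: regeneration exactly offsets the harvest when the group
#' removes `1 - 1/growth_factor` of the stock, i.e. each member takes
#' `100 * (1 - 1/growth_factor) / group_size` percent. With doubling and
#' four members this is 12.5%.
#'
#' @param config A [game_config()].
#' @return The sustainable per-member rate in percent.
#' @export
sustainable_rate <- function(config = game_config()) {
  100 * (1 - 1 / config$growth_factor) / config$group_size
}

#' Session payoffs
#'
#' Money earned by each member over a session: `unit_value` times the
#' member's summed extraction, rounded half-up to cents at the final step
#' only.
#'
#' @param session A `session_result` from [run_system()].
#' @param config A [game_config()].
#' @return Numeric vector of payoffs (EUR) per member.
#' @examples
#' # a member who extracted 124 units in total earns 1.24 EUR
#' @export
payoff <- function(session, config) {
  stopifnot(inherits(session, "session_result"))
  totals <- session$cumulative_units
  round_half_up(config$unit_value * totals, 2L)
}

# round half away from zero at `digits` decimals (base round() is banker's)
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Play all periods of one choice system
#'
#' Runs `periods_per_system` periods of the given mechanism for one group
#' of synthetic agents. The stock is reset to `initial_units` at the start
#' of the system. Once the stock is exhausted (below one unit), remaining
#' periods are recorded with all-zero extractions. Under majority voting,
#' each period collects one allocation proposal per member, pools
#' identical proposals, tallies one mandatory ballot per member, and
#' implements the elected allocation (at least three of four votes) or
#' falls back to individual extraction.
#'
#' @param agents List of agents from [sample_population()] (one group).
#' @param system `"individual"`, `"median"` or `"voting"`.
#' @param config A [game_config()].
#' @param params A [behavior_params()].
#' @param seed Optional integer seed (sets the RNG before the session).
#' @return A `session_result`: `periods` (list of `period_result`),
#'   `trials` (long data frame, one row per member-period), `proposals`
#'   and `ballots` data frames (voting only), `cumulative_units`,
#'   `payoffs`, `success_count` (voting).
#' @export
run_system <- function(agents, system = c("individual", "median", "voting"),
                       config, params, seed = NULL) {
  system <- match.arg(system)
  stopifnot(inherits(config, "game_config"),
            length(agents) == config$group_size)
  if (!is.null(seed)) set.seed(seed)
  roles <- vapply(agents, `[[`, character(1), "role")
  n <- config$group_size
  state <- resource_state(config$initial_units, 1L)

  periods <- vector("list", config$periods_per_system)
  trial_rows <- vector("list", config$periods_per_system)
  proposal_rows <- list()
  ballot_rows <- list()
  success_count <- if (system == "voting") 0L else NA_integer_

  for (t in seq_len(config$periods_per_system)) {
    if (state$exhausted) {
      # stock is gone: the group clicks through, extracting nothing
      trial_rows[[t]] <- data.frame(
        member = seq_len(n), period = t,
        resource_before = state$units_available,
        extraction = 0, elected = if (system == "voting") FALSE else NA,
        exhausted = TRUE
      )
      periods[[t]] <- structure(
        list(period_index = t, extractions = rep(0, n), override = FALSE,
             total_extracted = 0, resource_before = state$units_available,
             resource_after = state$units_available),
        class = "period_result"
      )
      state <- resource_state(state$units_available, t + 1L)
      next
    }

    elected_flag <- NA
    override <- FALSE
    if (system == "individual") {
      ev <- vapply(agents, decide_individual, numeric(1),
                   units_available = state$units_available, period = t,
                   config = config, params = params, system = "individual")
    } else if (system == "median") {
      props <- vapply(agents, propose_median, numeric(1),
                      units_available = state$units_available,
                      config = config, params = params)
      md <- resolve_median(props)
      ev <- rep(md$implemented_level, n)
      override <- TRUE
    } else {
      props <- lapply(agents, propose_allocation,
                      roles = roles, units_available = state$units_available,
                      config = config, params = params)
      pooled <- pool_identical(props)
      ballots <- vapply(seq_len(n), function(i) cast_vote(i, pooled),
                        integer(1))
      vr <- tally(ballots, pooled)
      if (!vr$fallback) {
        ev <- pooled[[vr$elected]]$allocation
        elected_flag <- TRUE
        success_count <- success_count +
          if (t <= config$periods_per_system - 1L) 1L else 0L
        override <- !config$enforce_caps_in_proposals
      } else {
        ev <- vapply(agents, decide_individual, numeric(1),
                     units_available = state$units_available, period = t,
                     config = config, params = params, system = "voting")
        elected_flag <- FALSE
      }
      for (i in seq_len(n)) {
        proposal_rows[[length(proposal_rows) + 1L]] <- data.frame(
          period = t, proposer = i,
          resource_before = state$units_available,
          t(stats::setNames(props[[i]]$allocation, paste0("m", seq_len(n)))),
          elected = if (vr$fallback) FALSE else
            i %in% pooled[[vr$elected]]$proposers
        )
        ballot_rows[[length(ballot_rows) + 1L]] <- data.frame(
          period = t, voter = i, choice = ballots[i]
        )
      }
    }

    step <- apply_period(state, ev, config, roles, override = override)
    periods[[t]] <- step$result
    trial_rows[[t]] <- data.frame(
      member = seq_len(n), period = t,
      resource_before = state$units_available,
      extraction = as.numeric(ev),
      elected = elected_flag,
      exhausted = FALSE
    )
    state <- step$state
  }

  trials <- do.call(rbind, trial_rows)
  cumulative <- vapply(seq_len(n), function(i)
    sum(trials$extraction[trials$member == i]), numeric(1))
  session <- structure(
    list(system = system,
         periods = periods,
         trials = trials,
         proposals = if (length(proposal_rows) > 0)
           do.call(rbind, proposal_rows) else NULL,
         ballots = if (length(ballot_rows) > 0)
           do.call(rbind, ballot_rows) else NULL,
         cumulative_units = cumulative,
         success_count = success_count),
    class = "session_result"
  )
  session$payoffs <- payoff(session, config)
  session
}
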