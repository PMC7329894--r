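#' Resolve a median-choice period
#'
#' Each of the four members states how many units they would like to
#' extract; the median of the proposals — for four members, the mean of
#' the two middle order statistics — is extracted for every member
#' identically. The common level is flagged as an override because it may
#' exceed a disadvantaged member's own cap.
#'
#' @param proposals Numeric vector of 4 non-negative desired extractions.
#' @return A `median_decision` list: `proposals`, `implemented_level`,
#'   `override` (always `TRUE`).
#' @examples
#' resolve_median(c(10, 12, 12, 16))$implemented_level # 12
#' resolve_median(c(10, 12, 14, 16))$implemented_level # 13
#' @export
resolve_median <- function(proposals) {
  if (length(proposals) != 4L) {
    stop("median choice is defined for exactly 4 proposals, got ",
         length(proposals), call. = FALSE)
  }
  if (any(!is.finite(proposals)) || any(proposals < 0)) {
    stop("proposals must be finite and non-negative", call. = FALSE)
  }
  s <- sort(proposals)
  structure(
    list(proposals = as.numeric(proposals),
         implemented_level = (s[2] + s[3]) / 2,
         override = TRUE),
    class = "median_decision"
  )
}

#' Pool identical allocation proposals
#'
#' Majority-voting proposals with component-wise identical allocation
#' vectors (under the stable internal member ordering) are merged into a
#' single ballot option, in order of first submission.
#'
#' @param proposals List of proposals, each a list with `proposer`
#'   (member index) and `allocation` (numeric vector, units per member).
#' @return List of pooled entries: `allocation`, `proposers` (member
#'   indices that submitted it), `n_identical`.
#' @export
pool_identical <- function(proposals) {
  stopifnot(length(proposals) >= 1)
  pooled <- list()
  keys <- character(0)
  for (p in proposals) {
    key <- paste(format(p$allocation, digits = 15), collapse = "|")
    j <- match(key, keys)
    if (is.na(j)) {
      keys <- c(keys, key)
      pooled[[length(pooled) + 1L]] <- list(
        allocation = as.numeric(p$allocation),
        proposers = p$proposer,
        n_identical = 1L
      )
    } else {
      pooled[[j]]$proposers <- c(pooled[[j]]$proposers, p$proposer)
      pooled[[j]]$n_identical <- pooled[[j]]$n_identical + 1L
    }
  }
  pooled
}

#' Tally ballots over pooled proposals
#'
#' Each member casts exactly one mandatory ballot. A pooled proposal is
#' elected when it receives a majority of at least three of the four
#' votes; with four single votes at most one option can reach that
#' threshold, so no tie-break is needed. With no majority the group falls
#' back to individual extraction.
#'
#' @param ballots Integer vector, one pooled-proposal index per member.
#' @param pooled Pooled proposals from [pool_identical()].
#' @param n_members Group size (default 4).
#' @param threshold Votes needed for election (default 3).
#' @return A `voting_result` list: `vote_counts`, `elected` (pooled index
#'   or `NA`), `fallback`.
#' @export
tally <- function(ballots, pooled, n_members = 4L, threshold = 3L) {
  if (length(ballots) != n_members) {
    stop("expected one ballot per member (", n_members, "), got ",
         length(ballots), call. = FALSE)
  }
  if (any(is.na(ballots)) || any(ballots < 1) ||
      any(ballots > length(pooled))) {
    stop("ballots must reference pooled proposals 1..", length(pooled),
         call. = FALSE)
  }
  counts <- tabulate(ballots, nbins = length(pooled))
  winner <- which(counts >= threshold)
  structure(
    list(vote_counts = counts,
         elected = if (length(winner) == 1L) winner else NA_integer_,
         fallback = length(winner) != 1L),
    class = "voting_result"
  )
}

#' Resolve an individual-choice period
#'
#' Decisions are implemented exactly as stated, validated against each
#' member's current extraction limit.
#'
#' @param decisions Numeric vector of per-member extraction requests.
#' @param units_available Current stock.
#' @param roles Role vector.
#' @return The validated extraction vector.
#' @export
resolve_individual <- function(decisions, units_available, roles) {
  stopifnot(length(decisions) == length(roles))
  limits <- vapply(roles, function(r)
    extraction_limit(units_available, r), numeric(1))
  over <- which(decisions > limits + 1e-9 | decisions < 0)
  if (length(over) > 0) {
    stop(sprintf("member %d requested %g units, outside [0, %g]",
                 over[1], decisions[over[1]], limits[over[1]]),
         call. = FALSE)
  }
  as.numeric(decisions)
}

#' Resolve a majority-voting period
#'
#' If a pooled proposal is elected, its allocation is implemented exactly;
#' otherwise every member's individual fallback decision is implemented,
#' exactly as under individual choice.
#'
#' @param proposals List of allocation proposals (see [pool_identical()]).
#' @param ballots Integer vector of ballots (pooled indices).
#' @param fallback_decisions Per-member individual decisions used when no
#'   proposal is elected.
#' @param units_available Current stock.
#' @param roles Role vector.
#' @return List with `extractions`, `voting_result`, `pooled`.
#' @export
resolve_majority <- function(proposals, ballots, fallback_decisions,
                             units_available, roles) {
  pooled <- pool_identical(proposals)
  vr <- tally(ballots, pooled, n_members = length(roles))
  extr <- if (!vr$fallback) {
    pooled[[vr$elected]]$allocation
  } else {
    resolve_individual(fallback_decisions, units_available, roles)
  }
  list(extractions = as.numeric(extr), voting_result = vr, pooled = pooled)
}
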