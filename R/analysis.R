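#' Percentage of the available resource taken
#'
#' The core behavioural statistic: an individual's extraction divided by
#' the stock available that period, times 100. Undefined (missing) when
#' no resource was available.
#'
#' @param extraction Units extracted (vectorised).
#' @param resource_available Stock available at the start of the period.
#' @return Percentage in `[0, 100]`, `NA` where `resource_available < 1`.
#' @examples
#' percentage_taken(20, 160) # 12.5
#' @export
percentage_taken <- function(extraction, resource_available) {
  out <- ifelse(resource_available >= 1,
                100 * extraction / resource_available, NA_real_)
  as.numeric(out)
}

#' Average percentage taken per participant and system
#'
#' Averages the percentage taken over the analysis window (periods 1-5 by
#' default: the final period is a different situation in which sustaining
#' the stock no longer pays). Periods in which the group's stock was
#' exhausted yield missing percentages and are excluded (`exhausted_policy
#' = "exclude"`) or scored as zero (`"zero"`).
#'
#' @param trials Long trials data frame (see [run_experiment()]): columns
#'   `participant`, `system`, `period`, `resource_before`, `extraction`,
#'   plus any grouping columns to carry through (`group`, `condition`,
#'   `role`, `order_pos`).
#' @param periods Periods included in the window.
#' @param exhausted_policy `"exclude"` or `"zero"`.
#' @return Data frame, one row per participant x system, with column
#'   `avg_pct`; carries `group`, `condition`, `role`, `order_pos` when
#'   present.
#' @export
average_percentage <- function(trials, periods = 1:5,
                               exhausted_policy = c("exclude", "zero")) {
  exhausted_policy <- match.arg(exhausted_policy)
  w <- trials[trials$period %in% periods, , drop = FALSE]
  pct <- percentage_taken(w$extraction, w$resource_before)
  if (exhausted_policy == "zero") pct[is.na(pct)] <- 0
  w$pct <- pct
  agg <- stats::aggregate(pct ~ participant + system, data = w,
                          FUN = function(x) mean(x, na.rm = TRUE),
                          na.action = stats::na.pass)
  agg$pct[is.nan(agg$pct)] <- NA_real_
  names(agg)[names(agg) == "pct"] <- "avg_pct"
  .carry_keys(agg, trials)
}

#' Profit per participant and system
#'
#' Money earned over the analysis window: `unit_value` times the summed
#' extraction.
#'
#' @inheritParams average_percentage
#' @param unit_value Money per unit.
#' @return Data frame, one row per participant x system, column `profit`.
#' @export
profit_summary <- function(trials, unit_value = 0.01, periods = 1:5) {
  w <- trials[trials$period %in% periods, , drop = FALSE]
  agg <- stats::aggregate(extraction ~ participant + system, data = w, sum)
  agg$profit <- unit_value * agg$extraction
  agg$extraction <- NULL
  .carry_keys(agg, trials)
}

# re-attach participant-level key columns present in the trials table
.carry_keys <- function(agg, trials) {
  keys <- intersect(c("group", "condition", "role", "order_pos"),
                    names(trials))
  if (length(keys) == 0) return(agg)
  u <- unique(trials[, c("participant", "system", keys), drop = FALSE])
  merge(agg, u, by = c("participant", "system"), all.x = TRUE, sort = FALSE)
}

#' Voting success count per group
#'
#' Number of majority-voting periods in the analysis window in which a
#' proposal was elected: 0 (the group extracted individually in every
#' window period) to 5 (a common decision in every window period).
#'
#' @param trials Long trials data frame with an `elected` flag on voting
#'   rows.
#' @param periods Window (default 1-5).
#' @return Data frame with `group` and `success_count`.
#' @export
voting_success_count <- function(trials, periods = 1:5) {
  v <- trials[trials$system == "voting" & trials$period %in% periods,
              c("group", "period", "elected")]
  v <- unique(v)
  v$elected <- as.logical(v$elected)
  v$elected[is.na(v$elected)] <- FALSE
  agg <- stats::aggregate(elected ~ group, data = v, FUN = sum)
  names(agg)[2] <- "success_count"
  agg$success_count <- as.integer(agg$success_count)
  agg
}

#' Features of an allocation proposal
#'
#' Converts a per-member allocation to extraction rates (percent of the
#' available stock) and returns the election-relevant features: the mean
#' rate, its absolute deviation from the sustainable rate, and the sample
#' standard deviation of the four members' rates.
#'
#' @param allocation Numeric vector of allocated units per member.
#' @param resource_available Stock the proposal refers to.
#' @param sustainable Sustainable per-member rate in percent.
#' @return Named numeric: `mean_rate`, `deviation`, `spread`.
#' @examples
#' proposal_features(c(32, 32, 8, 8), 160) # mean 12.5, dev 0, spread 8.66
#' @export
proposal_features <- function(allocation, resource_available,
                              sustainable = 12.5) {
  stopifnot(resource_available >= 1)
  rates <- 100 * allocation / resource_available
  m <- mean(rates)
  c(mean_rate = m,
    deviation = abs(m - sustainable),
    spread = stats::sd(rates))
}

#' Feature table for a proposals data frame
#'
#' Vectorised [proposal_features()] over the proposals table produced by
#' [run_experiment()] (member columns `m1..m4`).
#'
#' @param proposals Proposals data frame with columns `resource_before`
#'   and `m1`..`m4`.
#' @param sustainable Sustainable rate in percent.
#' @return The input with `mean_rate`, `deviation`, `spread` appended.
#' @export
proposal_feature_table <- function(proposals, sustainable = 12.5) {
  mcols <- grep("^m[0-9]+$", names(proposals), value = TRUE)
  rates <- 100 * as.matrix(proposals[, mcols, drop = FALSE]) /
    proposals$resource_before
  proposals$mean_rate <- rowMeans(rates)
  proposals$deviation <- abs(proposals$mean_rate - sustainable)
  proposals$spread <- apply(rates, 1, stats::sd)
  proposals
}

#' Logistic regression of election on proposal features
#'
#' Maximum-likelihood logistic fit (IRLS, convergence tolerance 1e-8, at
#' most 100 iterations) of the elected flag on the three proposal
#' features, intercept included, features untransformed. Odds ratios are
#' `exp(b)`. Perfect or quasi-perfect separation is flagged rather than
#' silently reported.
#'
#' @param features Data frame with columns `mean_rate`, `deviation`,
#'   `spread`.
#' @param elected Logical/0-1 vector of election outcomes.
#' @return An `election_logit` list: `coefficients`, `odds_ratios`,
#'   `se`, `z`, `converged`, `separation`, `n`, `fit` (the glm object).
#' @export
fit_election_logit <- function(features, elected) {
  stopifnot(all(c("mean_rate", "deviation", "spread") %in% names(features)))
  elected <- as.integer(as.logical(elected))
  if (length(elected) < 20 || length(unique(elected)) < 2) {
    stop("need at least 20 proposals with both outcomes present",
         call. = FALSE)
  }
  d <- data.frame(elected = elected,
                  mean_rate = features$mean_rate,
                  deviation = features$deviation,
                  spread = features$spread)
  fit <- suppressWarnings(
    stats::glm(elected ~ mean_rate + deviation + spread,
               family = stats::binomial(), data = d,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  mu <- stats::fitted(fit)
  separation <- any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE) ||
    all(mu > 0.999 | mu < 0.001)
  b <- stats::coef(fit)
  sm <- summary(fit)$coefficients
  structure(
    list(coefficients = b,
         odds_ratios = exp(b),
         se = sm[, "Std. Error"],
         z = sm[, "z value"],
         converged = fit$converged,
         separation = separation,
         n = nrow(d),
         fit = fit),
    class = "election_logit"
  )
}

#' @export
print.election_logit <- function(x, ...) {
  cat("Election logit (n =", x$n, ")\n")
  tab <- cbind(b = x$coefficients, OR = x$odds_ratios, z = x$z)
  print(round(tab, 3))
  if (x$separation) cat("warning: separation suspected\n")
  invisible(x)
}

#' Composite satisfaction/fairness rating
#'
#' Arithmetic mean of the six 1-7 items (three outcome-satisfaction,
#' three fairness-perception items; a single common factor justifies one
#' composite). Optionally reverse-codes the greed item (item 6) before
#' averaging; the default is no reverse-coding. A missing block yields a
#' missing composite.
#'
#' @param items Numeric vector (6 items) or matrix/data frame with 6
#'   columns (one row per respondent).
#' @param reverse_greed Reverse-code item 6 as `8 - x` before averaging?
#' @return Composite mean(s) in `[1, 7]`, `NA` for missing blocks.
#' @export
composite_rating <- function(items, reverse_greed = FALSE) {
  m <- if (is.null(dim(items))) matrix(items, nrow = 1) else as.matrix(items)
  if (ncol(m) != 6L) stop("expected six items", call. = FALSE)
  complete <- stats::complete.cases(m)
  if (any(m[complete, ] < 1 | m[complete, ] > 7)) {
    stop("items must lie in [1, 7]", call. = FALSE)
  }
  if (reverse_greed) m[, 6] <- 8 - m[, 6]
  out <- rowMeans(m)
  out[!complete] <- NA_real_
  as.numeric(out)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a multi-item scale:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sums))`, with
#' sample (n-1) variances.
#'
#' @param items Matrix or data frame, respondents in rows, items in
#'   columns; incomplete rows are dropped.
#' @return Alpha, or `NA` with a warning when the total variance is zero.
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 2 || nrow(m) < 3) {
    stop("need at least 2 items and 3 respondents", call. = FALSE)
  }
  total_var <- stats::var(rowSums(m))
  if (total_var < .Machine$double.eps) {
    warning("zero total variance: alpha undefined")
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' One-way random-effects intraclass correlation
#'
#' Share of variance attributable to the grouping level, estimated from
#' the one-way ANOVA decomposition: `sigma2_b = (MSB - MSW) / k0` with
#' `k0` the (un)balanced average group size, and
#' `ICC = sigma2_b / (sigma2_b + MSW)`, truncated at zero.
#'
#' @param group Grouping labels (e.g. participant ids).
#' @param values Numeric outcome values.
#' @return The ICC estimate, or `NA` with a warning for degenerate
#'   groupings.
#' @export
icc <- function(group, values) {
  ok <- !is.na(values) & !is.na(group)
  group <- factor(group[ok])
  values <- values[ok]
  nj <- table(group)
  if (nlevels(group) < 2 || all(nj < 2)) {
    warning("degenerate grouping: ICC undefined")
    return(NA_real_)
  }
  N <- length(values)
  J <- nlevels(group)
  gm <- mean(values)
  mj <- tapply(values, group, mean)
  ssb <- sum(nj * (mj - gm)^2)
  ssw <- sum((values - mj[group])^2)
  msb <- ssb / (J - 1)
  msw <- ssw / (N - J)
  k0 <- (N - sum(nj^2) / N) / (J - 1)
  sigma_b <- max((msb - msw) / k0, 0)
  sigma_b / (sigma_b + msw)
}

#' Bootstrap mediation: asymmetry -> voting success -> ratings
#'
#' Simple two-path mediation. Path `a` regresses the mediator (voting
#' success count) on the condition contrast; path `b` regresses the
#' outcome (rating composite) on the mediator adjusting for the condition
#' (partial mediation: the direct path is retained). The indirect effect
#' is `a * b` exactly; its confidence interval is the percentile interval
#' over case-resampled bootstrap replicates.
#'
#' @param condition Condition per case: `"symmetric"`/`"asymmetric"`
#'   labels or a numeric contrast (symmetric negative).
#' @param success Mediator values (voting success counts).
#' @param composite Outcome values (rating composites). Incomplete cases
#'   are dropped.
#' @param reps Bootstrap replicates (default 5000).
#' @param seed Optional integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A `mediation_result`: `a`, `b`, `direct`, `indirect`,
#'   `ci` (percentile bounds), `reps`, `seed`, `n`.
#' @export
indirect_effect <- function(condition, success, composite, reps = 5000,
                            seed = NULL, conf = 0.95) {
  if (reps < 100) warning("fewer than 100 bootstrap replicates")
  if (is.character(condition) || is.factor(condition)) {
    condition <- ifelse(as.character(condition) == "asymmetric", 0.5, -0.5)
  }
  ok <- stats::complete.cases(condition, success, composite)
  x <- condition[ok]; m <- success[ok]; y <- composite[ok]
  n <- length(x)
  if (stats::var(x) < .Machine$double.eps ||
      stats::var(m) < .Machine$double.eps) {
    stop("degenerate variance in condition or mediator", call. = FALSE)
  }
  paths <- .mediation_paths(x, m, y)
  if (!is.null(seed)) set.seed(seed)
  boot <- matrix(NA_real_, nrow = reps, ncol = 1)
  for (r in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    p <- tryCatch(.mediation_paths(x[idx], m[idx], y[idx]),
                  error = function(e) NULL)
    boot[r, 1] <- if (is.null(p)) NA_real_ else p["a"] * p["b"]
  }
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boot[, 1], c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  structure(
    list(a = unname(paths["a"]),
         b = unname(paths["b"]),
         direct = unname(paths["direct"]),
         indirect = unname(paths["a"] * paths["b"]),
         ci = ci, conf = conf, reps = reps, seed = seed, n = n,
         boot = boot[, 1]),
    class = "mediation_result"
  )
}

# OLS paths via normal equations: a from m ~ x, (b, direct) from
# y ~ m + x. Small fixed designs, so direct algebra is used for speed in
# the bootstrap loop.
.mediation_paths <- function(x, m, y) {
  X1 <- cbind(1, x)
  a <- unname(solve(crossprod(X1), crossprod(X1, m))[2, 1])
  X2 <- cbind(1, m, x)
  b2 <- unname(solve(crossprod(X2), crossprod(X2, y)))
  c(a = a, b = b2[2, 1], direct = b2[3, 1])
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "Mediation (n = %d, %d bootstrap reps)\n  a = %.3f, b = %.3f, direct = %.3f\n  indirect = a x b = %.3f [%.3f, %.3f] (%.0f%% percentile CI)\n",
    x$n, x$reps, x$a, x$b, x$direct, x$indirect, x$ci[1], x$ci[2],
    100 * x$conf))
  invisible(x)
}

#' Deterministic resource-trajectory projection
#'
#' Projects the stock under a constant, equal per-member extraction rate
#' using the exact regeneration law each period (no intermediate
#' rounding): `R <- min(g * R * (1 - n * rate/100), cap)`, clipped at
#' full depletion when the group rate reaches 100%.
#'
#' @param rate Per-member extraction rate, percent of the current stock.
#' @param config A [game_config()].
#' @param n_periods Projection horizon (default `periods_per_system`).
#' @return List: `final` (exact), `final_rounded` (nearest integer),
#'   `path` (stock after each period).
#' @examples
#' project_trajectory(12.92)$final_rounded # 130
#' project_trajectory(12.5)$final          # 160 (fixed point)
#' @export
project_trajectory <- function(rate, config = game_config(),
                               n_periods = config$periods_per_system) {
  stopifnot(rate >= 0)
  frac <- config$group_size * rate / 100
  r <- config$initial_units
  path <- numeric(n_periods)
  for (t in seq_len(n_periods)) {
    taken <- min(frac, 1) * r
    r <- regenerate(r, taken, config)
    path[t] <- r
  }
  list(final = r, final_rounded = round_half_up(r), path = path)
}

#' Model-ready contrast coding
#'
#' Adds the coding columns used in the regression analyses: dummies
#' `Median` and `MVoting` (individual choice as reference), the
#' `Asymmetry` contrast (-0.5 symmetric, +0.5 asymmetric) and the
#' `Advantaged` contrast within asymmetric groups (+0.5 advantaged,
#' -0.5 disadvantaged, 0 for symmetric participants). The coding scheme
#' is attached as the `"coding"` attribute.
#'
#' @param records Data frame with `system`, `condition` and `role`
#'   columns.
#' @return The input with coding columns appended.
#' @export
contrast_code <- function(records) {
  stopifnot(all(c("system", "condition", "role") %in% names(records)))
  bad_sys <- setdiff(unique(records$system),
                     c("individual", "median", "voting"))
  if (length(bad_sys) > 0) {
    stop("unknown system level(s): ", paste(bad_sys, collapse = ", "),
         call. = FALSE)
  }
  bad_cond <- setdiff(unique(records$condition),
                      c("symmetric", "asymmetric"))
  if (length(bad_cond) > 0) {
    stop("unknown condition level(s): ", paste(bad_cond, collapse = ", "),
         call. = FALSE)
  }
  bad_role <- setdiff(unique(records$role),
                      c("symmetric", "advantaged", "disadvantaged"))
  if (length(bad_role) > 0) {
    stop("unknown role level(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  records$Median <- as.integer(records$system == "median")
  records$MVoting <- as.integer(records$system == "voting")
  records$Asymmetry <- ifelse(records$condition == "asymmetric", 0.5, -0.5)
  records$Advantaged <- ifelse(records$role == "advantaged", 0.5,
                               ifelse(records$role == "disadvantaged",
                                      -0.5, 0))
  attr(records, "coding") <- list(
    Median = "1 = median choice, 0 otherwise (individual = reference)",
    MVoting = "1 = majority voting, 0 otherwise (individual = reference)",
    Asymmetry = "-0.5 symmetric, +0.5 asymmetric",
    Advantaged = "+0.5 advantaged, -0.5 disadvantaged, 0 symmetric"
  )
  records
}
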