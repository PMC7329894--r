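#' Design of a full experiment run
#'
#' Each group plays all three choice systems (six periods each, 18
#' periods in total) in an order drawn uniformly from the six
#' permutations. The default group counts reproduce the study cohort:
#' 26 symmetric groups (104 participants) and 36 asymmetric groups (144
#' participants), 248 participants in all.
#'
#' @param n_groups_symmetric Number of symmetric-condition groups.
#' @param n_groups_asymmetric Number of asymmetric-condition groups.
#' @param params A [behavior_params()].
#' @return An `experiment_design` list.
#' @export
experiment_design <- function(n_groups_symmetric = 26,
                              n_groups_asymmetric = 36,
                              params = behavior_params()) {
  stopifnot(n_groups_symmetric >= 0, n_groups_asymmetric >= 0,
            n_groups_symmetric + n_groups_asymmetric >= 1,
            inherits(params, "behavior_params"))
  structure(
    list(n_groups_symmetric = as.integer(n_groups_symmetric),
         n_groups_asymmetric = as.integer(n_groups_asymmetric),
         params = params),
    class = "experiment_design"
  )
}

.SYSTEMS <- c("individual", "median", "voting")
.SCHEMA_VERSION <- "1.0"

#' Run the full experiment end to end
#'
#' Simulates every group of the design through all three choice systems
#' and collects the four tidy tables: `trials` (one row per
#' participant-period), `proposals` and `ballots` (majority-voting
#' records), and `ratings` (six items per participant-system, with a
#' group's voting block possibly missing). Deterministic given the seed.
#'
#' @param design An [experiment_design()].
#' @param config Base [game_config()]; its `condition` field is
#'   overridden per group.
#' @param seed Integer seed for the whole run.
#' @return A `cpr_dataset` list: `trials`, `proposals`, `ballots`,
#'   `ratings` data frames and `meta` (seed, schema version, config
#'   hash, group counts).
#' @export
run_experiment <- function(design, config = game_config(), seed = 1L) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(config, "game_config"))
  set.seed(seed)
  params <- design$params
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

  conditions <- c(rep("symmetric", design$n_groups_symmetric),
                  rep("asymmetric", design$n_groups_asymmetric))
  n_groups <- length(conditions)

  trials <- list(); proposals <- list(); ballots <- list(); ratings <- list()

  for (g in seq_len(n_groups)) {
    cond <- conditions[g]
    cfg <- config
    cfg$condition <- cond
    group_id <- sprintf("G%03d", g)
    agents <- sample_population(cfg, params, n_groups = 1)[[1]]
    # keep ids globally unique
    for (i in seq_along(agents)) {
      agents[[i]]$id <- sprintf("%s_P%d", group_id, i)
    }
    order_idx <- perms[[sample.int(6, 1)]]
    drop_voting_ratings <- stats::runif(1) < params$missingness_prob

    for (pos in seq_along(order_idx)) {
      system <- .SYSTEMS[order_idx[pos]]
      session <- run_system(agents, system, cfg, params)
      tr <- session$trials
      tr$group <- group_id
      tr$participant <- sprintf("%s_P%d", group_id, tr$member)
      tr$condition <- cond
      tr$role <- vapply(agents, `[[`, character(1), "role")[tr$member]
      tr$system <- system
      tr$order_pos <- pos
      trials[[length(trials) + 1L]] <- tr

      if (!is.null(session$proposals)) {
        pr <- session$proposals
        pr$group <- group_id
        pr$condition <- cond
        proposals[[length(proposals) + 1L]] <- pr
        bl <- session$ballots
        bl$group <- group_id
        ballots[[length(ballots) + 1L]] <- bl
      }

      missing_block <- system == "voting" && drop_voting_ratings
      for (i in seq_along(agents)) {
        items <- if (missing_block) rep(NA_integer_, 6) else
          sample_ratings(agents[[i]], system, cond, params,
                         success_count = session$success_count)
        ratings[[length(ratings) + 1L]] <- data.frame(
          group = group_id,
          participant = agents[[i]]$id,
          condition = cond,
          role = agents[[i]]$role,
          system = system,
          order_pos = pos,
          t(stats::setNames(items, paste0("item", 1:6)))
        )
      }
    }
  }

  trials <- do.call(rbind, trials)
  trials <- trials[, c("group", "participant", "condition", "role",
                       "system", "order_pos", "period", "resource_before",
                       "extraction", "elected", "exhausted", "member")]
  dataset <- structure(
    list(trials = trials,
         proposals = if (length(proposals) > 0)
           do.call(rbind, proposals) else NULL,
         ballots = if (length(ballots) > 0)
           do.call(rbind, ballots) else NULL,
         ratings = do.call(rbind, ratings),
         meta = list(seed = seed,
                     schema_version = .SCHEMA_VERSION,
                     config_hash = config_hash(config),
                     n_groups_symmetric = design$n_groups_symmetric,
                     n_groups_asymmetric = design$n_groups_asymmetric)),
    class = "cpr_dataset"
  )
  dataset
}

# polynomial rolling hash of the deparsed configuration (stable
# fingerprint for metadata; not cryptographic)
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.required_cols <- list(
  trials = c("group", "participant", "condition", "role", "system",
             "order_pos", "period", "resource_before", "extraction",
             "elected", "exhausted", "member"),
  proposals = c("group", "condition", "period", "proposer",
                "resource_before", "m1", "m2", "m3", "m4", "elected"),
  ballots = c("group", "period", "voter", "choice"),
  ratings = c("group", "participant", "condition", "role", "system",
              "order_pos", paste0("item", 1:6))
)

#' Write a dataset to a directory of CSV files
#'
#' Writes `trials.csv`, `proposals.csv`, `ballots.csv`, `ratings.csv`
#' (UTF-8, header row, RFC-4180 quoting, missing values as empty fields)
#' and `meta.json`.
#'
#' @param dataset A `cpr_dataset` from [run_experiment()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cpr_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tab in c("trials", "proposals", "ballots", "ratings")) {
    df <- dataset[[tab]]
    if (is.null(df)) df <- stats::setNames(
      data.frame(matrix(ncol = length(.required_cols[[tab]]), nrow = 0)),
      .required_cols[[tab]])
    utils::write.csv(df, file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE, na = "")
  }
  jsonlite::write_json(dataset$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' Validates the schema (presence of the required columns and a known
#' schema version) and restores column types.
#'
#' @param dir Directory containing the CSV tables and `meta.json`.
#' @return A `cpr_dataset`.
#' @export
read_dataset <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) {
    stop("not a dataset directory (meta.json missing): ", dir,
         call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(as.character(meta$schema_version), .SCHEMA_VERSION)) {
    stop("unsupported schema version: ", meta$schema_version,
         " (expected ", .SCHEMA_VERSION, ")", call. = FALSE)
  }
  tabs <- list()
  for (tab in c("trials", "proposals", "ballots", "ratings")) {
    path <- file.path(dir, paste0(tab, ".csv"))
    if (!file.exists(path)) stop("missing table: ", tab, call. = FALSE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(.required_cols[[tab]], names(df))
    if (length(missing) > 0) {
      stop("schema mismatch in ", tab, ".csv: missing column(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    tabs[[tab]] <- df
  }
  if (nrow(tabs$proposals) == 0) tabs$proposals <- NULL
  if (nrow(tabs$ballots) == 0) tabs$ballots <- NULL
  structure(
    list(trials = tabs$trials, proposals = tabs$proposals,
         ballots = tabs$ballots, ratings = tabs$ratings, meta = meta),
    class = "cpr_dataset"
  )
}

#' Check the in-text worked values against the implementation
#'
#' Recomputes the hand-checkable quantities of the resource game from
#' the package's own functions — the sustainable rate, the median-rule
#' worked example, the regeneration cap, the extraction caps, the
#' trajectory projection at the disadvantaged individual-choice rate,
#' and the odds-ratio/coefficient correspondence — and prints a pass or
#' fail line for each.
#'
#' @param quiet Suppress printing?
#' @return Invisibly, `TRUE` when all checks pass.
#' @export
worked_examples <- function(quiet = FALSE) {
  cfg <- game_config()
  checks <- list(
    list("sustainable per-member rate is 12.5%",
         isTRUE(all.equal(sustainable_rate(cfg), 12.5))),
    list("sustainable rate is a fixed point of the dynamics",
         isTRUE(all.equal(regenerate(160, 4 * 0.125 * 160, cfg), 160))),
    list("median of proposals (10, 12, 12, 16) is 12",
         resolve_median(c(10, 12, 12, 16))$implemented_level == 12),
    list("median of proposals (10, 12, 14, 16) is 13",
         resolve_median(c(10, 12, 14, 16))$implemented_level == 13),
    list("regeneration is capped at 160 after zero extraction",
         regenerate(160, 0, cfg) == 160),
    list("caps at a 160-unit stock are 40 / 53 / 26",
         identical(extraction_limit(160, c("symmetric", "advantaged",
                                           "disadvantaged")),
                   c(40, 53, 26))),
    list("constant 12.92% leaves 130 units after six periods",
         project_trajectory(12.92, cfg)$final_rounded == 130),
    list("reported logit coefficients match reported odds ratios",
         all(round(exp(c(-0.10, -0.44, -0.75)), 2) ==
               c(0.90, 0.64, 0.47)))
  )
  ok <- vapply(checks, function(ch) isTRUE(ch[[2]]), logical(1))
  if (!quiet) {
    for (i in seq_along(checks)) {
      cat(sprintf("[%s] %s\n", if (ok[i]) "PASS" else "FAIL",
                  checks[[i]][[1]]))
    }
    cat(sprintf("%d/%d worked examples pass\n", sum(ok), length(ok)))
  }
  invisible(all(ok))
}
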