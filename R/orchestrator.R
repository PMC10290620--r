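#' Simulation run configuration
#'
#' Bundles everything one scenario run needs: the data-generating
#' parameters, the missingness scenarios with their arm odds multipliers,
#' the strategies to compare, and the replication count and master seed.
#' The default arm odds multipliers follow the study design: subjects in the
#' intervention arm are 4, 2 and 1 times more likely to drop out than
#' controls in the 10, 25 and 50 percent scenarios.
#'
#' @param datagen a \code{\link{gen_params}} object.
#' @param scenarios character vector drawn from \code{"complete"} and
#'   numeric-string missingness proportions such as \code{"0.10"}.
#' @param strategies_run strategies to run on incomplete data (subset of
#'   \code{\link{strategies}()}).
#' @param complete_strategies reference models fitted on the complete data
#'   when the \code{"complete"} scenario is requested.
#' @param n_sims number of replications (at least 2).
#' @param master_seed master seed; every random ingredient (generation,
#'   dropout, imputation) draws its own substream seed from it.
#' @param arm_odds named numeric mapping scenario labels to odds
#'   multipliers.
#' @param covariate_effect_scale passed to
#'   \code{\link{calibrate_missingness}}.
#' @param knn donor-pool size for the MI strategies.
#' @param auc area-under-the-curve convention for QALYs.
#' @param out_dir optional directory for CSV outputs.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(datagen = gen_params(),
                       scenarios = c("complete", "0.10", "0.25", "0.50"),
                       strategies_run = strategies(),
                       complete_strategies = c("LLM", "SUR-CCA"),
                       n_sims = 500L,
                       master_seed = 1L,
                       arm_odds = c("0.10" = 4, "0.25" = 2, "0.50" = 1),
                       covariate_effect_scale = 1,
                       knn = 5L,
                       auc = "rectangle",
                       out_dir = NULL) {
  if (n_sims < 2L) stop("n_sims must be at least 2", call. = FALSE)
  if (!length(scenarios)) stop("scenarios must be non-empty", call. = FALSE)
  bad <- setdiff(strategies_run, strategies())
  if (length(bad)) stop("unknown strategies: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  validate_gen_params(datagen)
  cfg <- list(datagen = datagen, scenarios = scenarios,
              strategies_run = strategies_run,
              complete_strategies = complete_strategies,
              n_sims = as.integer(n_sims),
              master_seed = as.integer(master_seed), arm_odds = arm_odds,
              covariate_effect_scale = covariate_effect_scale,
              knn = as.integer(knn), auc = auc, out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

# substream seeds: deterministic function of (master, n), caller RNG
# untouched; replication r gets the same seeds whether run alone or in batch
substream_seeds <- function(master_seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# mix (master, counter) into a well-separated 31-bit key, so that adjacent
# master seeds do not share replication substreams; multipliers keep every
# intermediate product exactly representable in doubles
mix_seed <- function(master_seed, counter) {
  m <- 2147483647
  x <- as.numeric(master_seed) %% m
  x <- (x * 69069 + 1) %% m
  x <- (x * 69069 + as.numeric(counter)) %% m
  x <- (x * 69069 + 1) %% m
  as.integer(x)
}

scenario_proportion <- function(scenario) {
  if (scenario == "complete") return(NA_real_)
  p <- suppressWarnings(as.numeric(scenario))
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop("scenario must be 'complete' or a proportion in (0,1): got ",
         scenario, call. = FALSE)
  p
}

#' Run a full simulation scenario
#'
#' For each replication: generate a complete trial, analyse it with the
#' reference models if the complete scenario is requested, impose calibrated
#' monotone MAR dropout for each missingness scenario, and run every
#' requested strategy. Multiple-imputation strategies within one replication
#' and scenario share the same imputation seed, so MI-LLM and MI-SUR see
#' identical completed datasets. Replications whose model fits fail to
#' converge are recorded and excluded from the performance summaries; the
#' run aborts if more than 5 percent fail.
#'
#' @param config a \code{\link{run_config}}.
#' @param verbose print progress every 100 replications.
#' @return list with \code{estimates} (per-replication data.frame),
#'   \code{performance} (from \code{\link{performance_table}}),
#'   \code{specs} (calibrated dropout specs) and \code{truths}.
#' @export
run_scenario <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  miss_scens <- setdiff(config$scenarios, "complete")
  run_complete <- "complete" %in% config$scenarios
  n_sims <- config$n_sims

  specs <- list()
  m_by_scen <- list()
  for (s in miss_scens) {
    p <- scenario_proportion(s)
    mult <- if (s %in% names(config$arm_odds)) config$arm_odds[[s]] else 1
    specs[[s]] <- calibrate_missingness(
      config$datagen, p, arm_odds_multiplier = mult,
      covariate_effect_scale = config$covariate_effect_scale,
      seed = mix_seed(config$master_seed, 0L))
    m_by_scen[[s]] <- as.integer(choose_m(p))
  }

  # per-replication seed table: generation, then (dropout, imputation) per
  # missingness scenario; row r depends only on (master_seed, r), so a
  # replication reproduces identically whether run alone or in a batch
  n_cols <- 1L + 2L * length(miss_scens)
  seed_mat <- matrix(unlist(lapply(seq_len(n_sims), function(r)
    substream_seeds(mix_seed(config$master_seed, r), n_cols))),
    nrow = n_sims, ncol = n_cols, byrow = TRUE)

  rows <- list()
  add_row <- function(scenario, rep, est) {
    rows[[length(rows) + 1L]] <<- data.frame(
      scenario = scenario, rep = rep, strategy = est$strategy,
      dc = est$dc, var_dc = est$var_dc, dq = est$dq, var_dq = est$var_dq,
      cov_dcdq = est$cov_dcdq, cov_available = est$cov_available,
      ci_dc_lo = est$ci_dc[1], ci_dc_hi = est$ci_dc[2],
      ci_dq_lo = est$ci_dq[1], ci_dq_hi = est$ci_dq[2],
      n = est$n, m = est$m, converged = est$converged,
      stringsAsFactors = FALSE)
  }

  n_failed <- 0L
  for (r in seq_len(n_sims)) {
    trial <- generate_complete_trial(config$datagen, seed_mat[r, 1L])
    if (run_complete) {
      for (strat in config$complete_strategies) {
        est <- run_strategy(trial, strat, auc = config$auc)
        if (!est$converged) n_failed <- n_failed + 1L
        add_row("complete", r, est)
      }
    }
    for (si in seq_along(miss_scens)) {
      s <- miss_scens[si]
      inc <- impose_dropout(trial, specs[[s]], seed_mat[r, 2L * si])
      icfg <- imputation_config(m = m_by_scen[[s]], knn = config$knn,
                                seed = seed_mat[r, 2L * si + 1L])
      for (strat in config$strategies_run) {
        est <- tryCatch(
          run_strategy(inc, strat, impute_config = icfg, auc = config$auc),
          error = function(e) make_estimate(strat, NA_real_, NA_real_,
                                            NA_real_, NA_real_, 0, FALSE,
                                            c(NA, NA), c(NA, NA),
                                            nrow(inc), converged = FALSE))
        if (!est$converged) n_failed <- n_failed + 1L
        add_row(s, r, est)
      }
    }
    if (verbose && r %% 100L == 0L)
      message(sprintf("replication %d / %d", r, n_sims))
  }

  estimates <- do.call(rbind, rows)
  n_cells <- nrow(estimates)
  if (n_failed > 0.05 * n_cells)
    stop(sprintf("too many failed fits: %d of %d strategy runs", n_failed,
                 n_cells), call. = FALSE)

  truths <- true_effects(config$datagen)
  perf <- performance_table(estimates, truths)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in unique(estimates$scenario)) {
      utils::write.csv(estimates[estimates$scenario == s, ],
                       file.path(config$out_dir,
                                 paste0("estimates_", gsub("\\.", "", s), ".csv")),
                       row.names = FALSE, na = "")
    }
    utils::write.csv(perf, file.path(config$out_dir, "performance.csv"),
                     row.names = FALSE, na = "")
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      manifest <- list(n_sims = n_sims, master_seed = config$master_seed,
                       scenarios = config$scenarios,
                       strategies = config$strategies_run,
                       truths = truths,
                       package_version = as.character(utils::packageVersion("cemisim")))
      jsonlite::write_json(manifest,
                           file.path(config$out_dir, "run_manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
  }

  list(estimates = estimates, performance = perf, specs = specs,
       truths = truths, n_failed = n_failed)
}

#' Write a trial to wide-format CSV
#'
#' Columns \code{id,trt,age,gender,cT0..cT4,uT0..uT4}; missing values are
#' written as empty fields.
#'
#' @param trial a trial table.
#' @param path output file.
#' @export
write_trial_csv <- function(trial, path) {
  utils::write.csv(trial, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trial from wide-format CSV
#'
#' @param path input file with a mandatory header; empty fields become
#'   missing values.
#' @return a \code{trial_data} data.frame.
#' @export
read_trial_csv <- function(path) {
  out <- utils::read.csv(path, header = TRUE,
                         na.strings = "", stringsAsFactors = FALSE)
  needed <- c("id", "trt", "age", "gender", "cT0", "uT0")
  if (!all(needed %in% names(out)))
    stop("CSV lacks required columns: ",
         paste(setdiff(needed, names(out)), collapse = ", "), call. = FALSE)
  class(out) <- c("trial_data", "data.frame")
  out
}

#' Build a run configuration from a YAML file
#'
#' The file may contain \code{datagen:}, \code{missingness:} and
#' \code{run:} blocks; entries override the defaults of
#' \code{\link{gen_params}} and \code{\link{run_config}}.
#'
#' @param path YAML file.
#' @return a \code{run_config}.
#' @export
run_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read configuration files",
         call. = FALSE)
  y <- yaml::read_yaml(path)
  dg <- do.call(gen_params, as.list(y$datagen))
  run_args <- as.list(y$run)
  if (!is.null(y$missingness$arm_odds))
    run_args$arm_odds <- unlist(y$missingness$arm_odds)
  if (!is.null(y$missingness$scenarios))
    run_args$scenarios <- as.character(y$missingness$scenarios)
  do.call(run_config, c(list(datagen = dg), run_args))
}
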