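#' Configuration of one experimental scenario
#'
#' Scenario 1: grid-cell input only.  Scenario 2: grid cells plus weakly
#' spatial cells.  Scenario 3: the trained scenario-2 model with all
#' grid-cell rows of the dictionary zeroed (columns renormalized, learning
#' off).  Defaults follow the full-scale study conditions: 100 modelled
#' hippocampal cells, 900 grid cells, 400 weakly spatial cells (scenarios
#' 2-3), 3600 s training and 1200 s test trajectories.
#'
#' @param scenario 1, 2 or 3.
#' @param n_hippocampal modelled hippocampal cells (default 100).
#' @param n_grid MEC grid cells (default 900).
#' @param n_weak EC weakly spatial cells (default 0 for scenario 1,
#'   400 otherwise).
#' @param train_duration,test_duration trajectory durations, s.
#' @param master_seed master seed; independent sub-seeds are spawned per
#'   stage (trajectory, EC sampling, dictionary init, test trajectory,
#'   measurement trajectories).
#' @param modules grid-module table (see [default_grid_modules()]).
#' @param arena_size arena side length, m.
#' @param n_bins rate-map bins per side (default 40).
#' @param trajectory,model named lists of overrides passed to
#'   [trajectory_params()] and [sparse_coding_model()].
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(scenario, n_hippocampal = 100, n_grid = 900,
                            n_weak = if (scenario == 1) 0 else 400,
                            train_duration = 3600, test_duration = 1200,
                            master_seed = 1,
                            modules = default_grid_modules(),
                            arena_size = 1, n_bins = 40,
                            trajectory = list(), model = list()) {
  if (!scenario %in% 1:3) stop("scenario must be 1, 2 or 3")
  if (scenario == 1 && n_weak != 0)
    stop("scenario 1 uses no weakly spatial cells")
  if (scenario != 1 && n_weak <= 0)
    stop("scenarios 2 and 3 require weakly spatial cells")
  structure(list(scenario = scenario, n_hippocampal = n_hippocampal,
                 n_grid = n_grid, n_weak = n_weak,
                 train_duration = train_duration,
                 test_duration = test_duration, master_seed = master_seed,
                 modules = modules, arena_size = arena_size, n_bins = n_bins,
                 trajectory = trajectory, model = model),
            class = "scenario_config")
}

.make_traj <- function(config, duration, seed, extra = list()) {
  args <- c(list(duration = duration, arena_size = config$arena_size,
                 seed = seed), config$trajectory, extra)
  args <- args[!duplicated(names(args))]
  simulate_trajectory(do.call(trajectory_params, args))
}

#' Run one scenario end to end
#'
#' Builds the EC population, trains the dictionary along the training
#' trajectory (scenarios 1-2) or inactivates the grid rows of a trained
#' scenario-2 model (scenario 3), recovers rate maps along the test
#' trajectory, fits the spatial field model, selects place cells, and
#' (optionally) measures phase precession for every analyzable cell (place
#' cells whose entire fitted field lies inside the arena).
#'
#' The same master seed gives the same training/test trajectories across
#' scenarios 1 and 2, as in the study design; scenario 3 reuses the
#' scenario-2 population and model from `base`.
#'
#' @param config a [scenario_config()].
#' @param base for scenario 3: the report returned by a scenario-2 run.
#' @param measure_precession whether to run the (expensive) per-cell
#'   precession measurement.
#' @param progress print training progress (one line per chunk).
#' @return an object of class `scenario_report`: list with `config`,
#'   `population`, `model`, `train_error` (per-sample squared
#'   reconstruction error during training; NULL for scenario 3), `maps`,
#'   `fits`, `place_cells`, `fully_inside`, `radius_stats` (mean/median
#'   fitted radius over place cells, cm), and `precession` (named list of
#'   `precession_summary`, if measured).
#' @export
run_scenario <- function(config, base = NULL, measure_precession = FALSE,
                         progress = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  seeds <- lapply(c(trajectory = "trajectory", ec = "ec", init = "init",
                    test = "test", measure = "measure"),
                  function(s) spawn_seed(config$master_seed, s))
  if (config$scenario == 3) {
    if (is.null(base) || !inherits(base, "scenario_report") ||
        base$config$scenario != 2)
      stop("scenario 3 requires the report of a trained scenario-2 run")
    population <- base$population
    grid_rows <- population$n_weak + seq_len(population$n_grid)
    model <- inactivate_inputs(base$model, grid_rows)
    train_error <- NULL
  } else {
    grid <- sample_grid_population(config$n_grid, modules = config$modules,
                                   arena_size = config$arena_size,
                                   seed = seeds$ec)
    weak <- if (config$n_weak > 0)
      make_weakly_spatial_cells(config$n_weak,
                                arena_size = config$arena_size,
                                seed = seeds$ec + 1L)
    population <- ec_population(grid, weak)
    margs <- c(list(n_inputs = population$n_inputs,
                    n_cells = config$n_hippocampal, seed = seeds$init),
               config$model)
    margs <- margs[!duplicated(names(margs))]
    model <- do.call(sparse_coding_model, margs)
    train_error <- NULL
    if (config$train_duration > 0) {
      train_traj <- .make_traj(config, config$train_duration,
                               seeds$trajectory)
      ses <- run_session(model, population, train_traj, learn = TRUE,
                         progress = progress)
      model <- ses$model
      train_error <- ses$recon_error
    }
  }
  test_traj <- .make_traj(config, config$test_duration, seeds$test)
  maps <- recover_rate_maps(model, population, test_traj,
                            n_bins = config$n_bins)
  fits <- fit_all_spatial(maps)
  sel <- select_place_cells(fits, arena_size = config$arena_size)
  radii <- fits$radius[fits$cell %in% sel$place]
  report <- list(config = config, population = population, model = model,
                 train_error = train_error, maps = maps, fits = fits,
                 place_cells = sel$place, fully_inside = sel$fully_inside,
                 radius_stats = c(mean_cm = mean(radii) * 100,
                                  median_cm = median(radii) * 100,
                                  n = length(radii)),
                 precession = NULL)
  class(report) <- "scenario_report"
  if (measure_precession && length(sel$fully_inside) > 0) {
    prec <- list()
    for (k in sel$fully_inside) {
      prec[[as.character(k)]] <- tryCatch(
        measure_precession(model, population, k, fits[fits$cell == k, ],
                           seed = seeds$measure + k),
        error = function(e) NULL)
    }
    report$precession <- prec
  }
  report
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("Scenario", x$config$scenario, "report\n")
  cat(sprintf("  %d / %d cells pass the place-cell criteria\n",
              length(x$place_cells), x$config$n_hippocampal))
  cat(sprintf("  %d place fields lie entirely inside the arena\n",
              length(x$fully_inside)))
  cat(sprintf("  mean fitted radius over place cells: %.2f cm\n",
              x$radius_stats[["mean_cm"]]))
  if (!is.null(x$precession)) {
    cors <- vapply(x$precession, function(p)
      if (is.null(p)) NA_real_ else p$correlation, numeric(1))
    cat(sprintf("  median phase/pdcd correlation: %.3f (%d cells)\n",
                median(cors, na.rm = TRUE), sum(!is.na(cors))))
  }
  invisible(x)
}

#' Compare place fields before and after grid-input inactivation
#'
#' @param report2 the scenario-2 report.
#' @param report3 the scenario-3 report derived from it.
#' @return a list with `table` (one row per scenario-3 place cell: fitted
#'   radii before/after in cm, radius change, center shift in m),
#'   `mean_radius_before_cm`, `mean_radius_after_cm`, and `subset_ok`
#'   (whether every scenario-3 place cell was a scenario-2 place cell).
#' @export
compare_scenarios <- function(report2, report3) {
  stopifnot(inherits(report2, "scenario_report"),
            inherits(report3, "scenario_report"))
  if (report2$config$n_hippocampal != report3$config$n_hippocampal)
    stop("reports describe different hippocampal populations")
  common <- report3$place_cells
  f2 <- report2$fits[match(common, report2$fits$cell), ]
  f3 <- report3$fits[match(common, report3$fits$cell), ]
  tab <- data.frame(cell = common,
                    radius_before_cm = f2$radius * 100,
                    radius_after_cm = f3$radius * 100,
                    radius_change_cm = (f3$radius - f2$radius) * 100,
                    center_shift_m = sqrt((f3$cx - f2$cx)^2 +
                                            (f3$cy - f2$cy)^2))
  list(table = tab,
       mean_radius_before_cm = report2$radius_stats[["mean_cm"]],
       mean_radius_after_cm = report3$radius_stats[["mean_cm"]],
       subset_ok = all(report3$place_cells %in% report2$place_cells))
}
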