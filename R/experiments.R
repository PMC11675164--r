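#' Run the repeated-reactivation transformation protocol
#'
#' Simulates memory evolution: for each of `runs` independent repetitions a
#' fresh segregated network is built (unless `resample_network = FALSE`) and
#' subjected to `reactivations` successive reactivation events; the degree of
#' integration `Z`, network entropy `H`, malleability `deltaL`, spreading
#' statistics and (optionally) one community's tightness are recorded after
#' every reactivation, then averaged across runs.
#'
#' The whole protocol is reproducible from `seed`: per-run seeds are derived
#' deterministically from it, and runs are mutually independent, so results
#' are identical whatever the execution order.
#'
#' @param N,C,Z0,k_int network construction, as in
#'   [build_segregated_network()].
#' @param Int,theta,turn_on_sd,target_communities,turn_on_select reactivation
#'   event parameters, as in [reactivation_params()].
#' @param reactivations number of successive reactivations per run.
#' @param runs number of independent repetitions.
#' @param seed base seed for the whole protocol.
#' @param track_community optional community id whose tightness `T` is
#'   recorded after every reactivation (`NA` when undefined).
#' @param resample_network if `TRUE` (default) each run starts from a fresh
#'   random network; if `FALSE` all runs share one initial network and only
#'   the turn-on randomness varies.
#' @return A `sit_ensemble`: list with `trajectories` (tibble with one row
#'   per run x reactivation), `summary` (tibble of per-reactivation mean and
#'   SD for each metric), `config` and `n_runs`.
#' @examples
#' ens <- run_transformation(N = 16, C = 4, Z0 = 0.3, reactivations = 3,
#'                           runs = 2, seed = 1)
#' ens$summary
#' @export
run_transformation <- function(N = 128, C = 4, Z0 = 0.01,
                               Int = 0.3, theta = 0.4, turn_on_sd = 0.05,
                               reactivations = 10, runs = 25, seed = 1,
                               target_communities = NULL,
                               track_community = NULL,
                               resample_network = TRUE,
                               k_int = NULL,
                               turn_on_select = "draws") {
  if (runs < 1 || reactivations < 1) {
    abort_invalid_config("runs and reactivations must be at least 1")
  }
  params <- reactivation_params(
    Int = Int, theta = theta, turn_on_sd = turn_on_sd,
    target_communities = target_communities, turn_on_select = turn_on_select)

  set.seed(seed)
  net_seed <- sample.int(.Machine$integer.max - 1L, 1)
  run_seeds <- sample.int(.Machine$integer.max - 1L, runs)
  shared_net <- if (!resample_network) {
    build_segregated_network(N, C, Z0, seed = net_seed, k_int = k_int)
  }

  rows <- vector("list", runs)
  for (i in seq_len(runs)) {
    set.seed(run_seeds[i])
    net <- if (resample_network) {
      build_segregated_network(N, C, Z0, k_int = k_int)
    } else {
      shared_net
    }
    rec <- vector("list", reactivations)
    for (r in seq_len(reactivations)) {
      if (edge_count(net) == 0) {
        warning(sprintf("run %d aborted at reactivation %d: network became edgeless", i, r))
        break
      }
      res <- reactivate(net, params)
      net <- res$net
      out <- res$outcome
      rec[[r]] <- tibble(
        run = i, seed = run_seeds[i], reactivation = r,
        Z = if (edge_count(net) > 0) compute_Z(net) else NA_real_,
        H = network_entropy(net),
        deltaL = malleability(out),
        spreading_iters = out$spreading_iters,
        converged = out$converged,
        edges = edge_count(net),
        T = if (!is.null(track_community)) {
          tryCatch(tightness(net, track_community), sitnet_undefined_metric = function(e) NA_real_)
        } else {
          NA_real_
        })
    }
    rows[[i]] <- bind_rows(rec)
  }
  trajectories <- bind_rows(rows)
  if (is.null(track_community)) trajectories$T <- NULL

  structure(
    list(trajectories = trajectories,
         summary = summarise_trajectories(trajectories),
         config = list(N = N, C = C, Z0 = Z0, Int = Int, theta = theta,
                       turn_on_sd = turn_on_sd, reactivations = reactivations,
                       runs = runs, seed = seed,
                       target_communities = target_communities,
                       track_community = track_community,
                       resample_network = resample_network,
                       turn_on_select = turn_on_select),
         n_runs = runs),
    class = "sit_ensemble")
}

summarise_trajectories <- function(trajectories) {
  metrics <- intersect(c("Z", "H", "deltaL", "spreading_iters", "edges", "T"),
                       names(trajectories))
  long <- do.call(bind_rows, lapply(metrics, function(m) {
    tibble(reactivation = trajectories$reactivation, metric = m,
           value = as.numeric(trajectories[[m]]))
  }))
  long %>%
    group_by(.data$reactivation, .data$metric) %>%
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sd = sd(.data$value, na.rm = TRUE),
              n = sum(!is.na(.data$value)), .groups = "drop") %>%
    arrange(.data$metric, .data$reactivation)
}

#' Per-reactivation mean of one metric
#'
#' @param ensemble a `sit_ensemble` from [run_transformation()] or
#'   [run_single_community()].
#' @param metric one of the recorded metric names (`"Z"`, `"H"`, `"deltaL"`,
#'   `"T"`, ...).
#' @return Numeric vector ordered by reactivation index (1-based).
#' @export
ensemble_series <- function(ensemble, metric) {
  stopifnot(inherits(ensemble, "sit_ensemble"))
  s <- ensemble$summary[ensemble$summary$metric == metric, ]
  if (nrow(s) == 0) abort_invalid_config(paste0("metric not recorded: ", metric))
  s$mean[order(s$reactivation)]
}

#' @export
print.sit_ensemble <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<sit_ensemble> N=%d C=%d Z0=%g Int=%g theta=%g | %d reactivations x %d runs\n",
    cfg$N, cfg$C, cfg$Z0, cfg$Int, cfg$theta, cfg$reactivations, x$n_runs))
  z <- try(ensemble_series(x, "Z"), silent = TRUE)
  if (!inherits(z, "try-error")) {
    cat(sprintf("  mean Z: %.3f -> %.3f\n", z[1], z[length(z)]))
  }
  if (!is.null(x$slope)) cat(sprintf("  tightness slope (r3..9): %.4f\n", x$slope))
  invisible(x)
}

#' Single-community reactivation protocol (preserved identity)
#'
#' Repeatedly reactivates only one community of the network and tracks that
#' community's tightness `T` after every reactivation, measuring whether a
#' memory can stay (or become again) discrete and identifiable while the
#' rest of the network is left alone. Also fits the tightness decay slope
#' over reactivations 3 to 9 of the run-averaged series.
#'
#' @inheritParams run_transformation
#' @param community community id receiving every cue (default 0).
#' @return A `sit_ensemble` with a `T` metric in the trajectories and an
#'   extra `slope` element.
#' @export
run_single_community <- function(N = 128, C = 4, Z0 = 0.01,
                                 Int = 0.3, theta = 0.4, turn_on_sd = 0.05,
                                 community = 0, reactivations = 15, runs = 25,
                                 seed = 1, resample_network = TRUE,
                                 k_int = NULL, turn_on_select = "draws") {
  ens <- run_transformation(
    N = N, C = C, Z0 = Z0, Int = Int, theta = theta, turn_on_sd = turn_on_sd,
    reactivations = reactivations, runs = runs, seed = seed,
    target_communities = community, track_community = community,
    resample_network = resample_network, k_int = k_int,
    turn_on_select = turn_on_select)
  ens$config$protocol <- "single-community"
  ens$slope <- if (reactivations >= 9) {
    tightness_slope(ensemble_series(ens, "T"))
  }
  ens
}

#' Sweep configuration
#'
#' Describes a grid of simulation conditions for [run_sweep()]. By default
#' the grid is the Cartesian product of the supplied `N`, `Z0`, `Int` and
#' `theta` values; pass a data frame as `grid` instead to run explicitly
#' paired conditions (e.g. one designated `Z0` per network size).
#'
#' @param N,Z0,Int,theta vectors of condition values. `Int` and `theta`
#'   default to the standard scan grids (0.1 to 0.7 and 0.1 to 0.6, step
#'   0.02).
#' @param C communities per network (default 4).
#' @param reactivations,runs,seed as in [run_transformation()].
#' @param protocol `"full"` (every community cued) or `"single-community"`.
#' @param community cued community for the single-community protocol.
#' @param grid optional data frame with columns among `N`, `C`, `Z0`, `Int`,
#'   `theta`; missing columns are filled from the scalar defaults.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(N = 128, C = 4, Z0 = 0.01,
                         Int = seq(0.1, 0.7, by = 0.02),
                         theta = seq(0.1, 0.6, by = 0.02),
                         reactivations = 10, runs = 25, seed = 1,
                         protocol = c("full", "single-community"),
                         community = 0, grid = NULL) {
  protocol <- match.arg(protocol)
  if (is.null(grid)) {
    grid <- expand.grid(N = N, C = C, Z0 = Z0, Int = Int, theta = theta,
                        KEEP.OUT.ATTRS = FALSE)
  } else {
    grid <- as.data.frame(grid)
    defaults <- list(N = N[1], C = C[1], Z0 = Z0[1], Int = Int[1], theta = theta[1])
    for (col in names(defaults)) {
      if (!col %in% names(grid)) grid[[col]] <- defaults[[col]]
    }
  }
  if (nrow(grid) == 0) abort_invalid_config("the sweep grid is empty")
  if (runs < 1) abort_invalid_config("runs must be at least 1")
  structure(
    list(grid = as_tibble(grid), reactivations = reactivations, runs = runs,
         seed = seed, protocol = protocol, community = community),
    class = "sweep_config")
}

#' Run a parameter sweep
#'
#' Executes [run_transformation()] (or [run_single_community()]) at every
#' grid point of a [sweep_config()], with independent seeds derived
#' deterministically from the base seed, and gathers per-point summaries:
#' the malleability nonlinearity amplitude ([amp_deltaL()]), the
#' reactivation index at which `deltaL` and `H` peak, the final mean `Z`,
#' and (single-community protocol) the tightness slope.
#'
#' @param config a [sweep_config()].
#' @return A `sit_sweep`: list with `results` (long tibble of
#'   per-reactivation means and SDs for every grid point) and `points`
#'   (tibble with one row of summary statistics per grid point).
#' @export
run_sweep <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  grid <- config$grid
  set.seed(config$seed)
  point_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))

  results <- vector("list", nrow(grid))
  points <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ens <- if (config$protocol == "full") {
      run_transformation(N = g$N, C = g$C, Z0 = g$Z0, Int = g$Int,
                         theta = g$theta, reactivations = config$reactivations,
                         runs = config$runs, seed = point_seeds[i])
    } else {
      run_single_community(N = g$N, C = g$C, Z0 = g$Z0, Int = g$Int,
                           theta = g$theta, community = config$community,
                           reactivations = config$reactivations,
                           runs = config$runs, seed = point_seeds[i])
    }
    results[[i]] <- mutate(ens$summary, point = i, N = g$N, C = g$C,
                           Z0 = g$Z0, Int = g$Int, theta = g$theta)
    dl <- ensemble_series(ens, "deltaL")
    hh <- ensemble_series(ens, "H")
    zz <- ensemble_series(ens, "Z")
    points[[i]] <- tibble(
      point = i, N = g$N, C = g$C, Z0 = g$Z0, Int = g$Int, theta = g$theta,
      seed = point_seeds[i],
      amp_deltaL = if (length(dl) >= 6) amp_deltaL(dl) else NA_real_,
      argmax_deltaL = which.max(dl), argmax_H = which.max(hh),
      final_Z = zz[length(zz)],
      slope = if (!is.null(ens$slope)) ens$slope else NA_real_)
  }
  structure(
    list(results = bind_rows(results), points = bind_rows(points),
         config = config),
    class = "sit_sweep")
}

#' @export
print.sit_sweep <- function(x, ...) {
  cat(sprintf("<sit_sweep> %d grid points, protocol = %s\n",
              nrow(x$points), x$config$protocol))
  print(x$points, n = 10)
  invisible(x)
}

#' Export results as tidy CSV
#'
#' Writes a long-format table, one row per run x reactivation x metric for
#' an ensemble, or per grid point x reactivation x metric for a sweep.
#'
#' @param x a `sit_ensemble` or `sit_sweep`.
#' @param path output CSV path.
#' @return Invisibly, the path written.
#' @export
export_results <- function(x, path) {
  tab <- if (inherits(x, "sit_ensemble")) {
    metrics <- intersect(c("Z", "H", "deltaL", "spreading_iters", "converged", "edges", "T"),
                         names(x$trajectories))
    do.call(bind_rows, lapply(metrics, function(m) {
      tibble(protocol = if (is.null(x$config$protocol)) "full" else x$config$protocol,
             N = x$config$N, C = x$config$C, Z0 = x$config$Z0,
             Int = x$config$Int, theta = x$config$theta,
             run = x$trajectories$run, reactivation = x$trajectories$reactivation,
             metric = m, value = as.numeric(x$trajectories[[m]]))
    }))
  } else if (inherits(x, "sit_sweep")) {
    mutate(x$results, protocol = x$config$protocol)
  } else {
    abort_invalid_config("export_results handles sit_ensemble and sit_sweep objects")
  }
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
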