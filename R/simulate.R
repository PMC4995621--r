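#' Initialize a simulation
#'
#' Builds the world in the scenario's initial configuration: one tumor cell
#' at the centre (unless disabled), initial vessels as straight chains of
#' quiescent endothelial cells, fibroblasts scattered in a shell around the
#' centre, a uniform oxygen background and empty VEGF/FGF/HGF fields.
#'
#' @param scen a [scenario()] or [scenario_preset()].
#' @return An object of class `"tumor_sim"` holding the compiled simulation
#'   state; advance it with [sim_step()].
#' @examples
#' s <- sim_init(scenario_preset("baseline", dims = c(21, 21, 21),
#'                               n_fibroblasts = 5, seed = 1))
#' sim_tick(s)
#' @export
sim_init <- function(scen) {
  stopifnot(inherits(scen, "tumor_scenario"))
  ptr <- .sim_create_cpp(unclass(scen$params), list(
    dims = scen$dims, seed = scen$seed, angiogenesis = scen$angiogenesis,
    proliferative = scen$proliferative, tumor = scen$tumor,
    vessel_mode = scen$vessel_mode, n_vessels = scen$n_vessels,
    vessel_length = scen$vessel_length,
    n_fibroblasts = scen$n_fibroblasts,
    fibroblast_shell = scen$fibroblast_shell))
  structure(list(ptr = ptr, scenario = scen), class = "tumor_sim")
}

#' Advance a simulation
#'
#' Each tick: (1) all four molecular fields diffuse one step; (2) the
#' living agents act in a freshly drawn random permutation; (3) population
#' and mass metrics are appended to the time series and events to the log.
#'
#' @param sim a [sim_init()] object.
#' @param n number of ticks.
#' @return `sim`, advanced in place (the compiled state is a reference).
#' @export
sim_step <- function(sim, n = 1L) {
  stopifnot(inherits(sim, "tumor_sim"), n >= 0)
  if (n > 0) .sim_step_cpp(sim$ptr, as.integer(n))
  invisible(sim)
}

#' Current tick of a simulation
#' @param sim a [sim_init()] object.
#' @return Integer tick (0 after initialization).
#' @export
sim_tick <- function(sim) .sim_tick_cpp(sim$ptr)

#' Per-tick population and mass metrics
#'
#' @param sim a [sim_init()] object, or a [sim_run()] result.
#' @return A data frame with one row per tick (including tick 0): living,
#'   hypoxic and necrotic tumor cells, endothelial cells (total and
#'   activated), CAFs, fibroblasts, total VEGF and oxygen mass, and branch
#'   events of the tick.
#' @export
sim_timeseries <- function(sim) {
  if (inherits(sim, "tumor_run")) return(sim$timeseries)
  .sim_timeseries_cpp(sim$ptr)
}

#' Per-agent event log
#'
#' @inheritParams sim_timeseries
#' @return A data frame of `tick, event, cell, x, y, z` rows; events are
#'   `activation`, `branch`, `division`, `necrosis`, `anastomosis`,
#'   `caf_conversion` and `ec_death`.
#' @export
sim_events <- function(sim) {
  if (inherits(sim, "tumor_run")) return(sim$events)
  .sim_events_cpp(sim$ptr)
}

#' Full spatial snapshot of the current state
#'
#' @inheritParams sim_timeseries
#' @return An object of class `"tumor_snapshot"`: `tick`, `dims`, a `cells`
#'   data frame (id, kind, state, 0-based position, vessel id), per-species
#'   3D field arrays plus the ECM, and the vessel topology (ordered member
#'   ids and parent lineage from branching; anastomosis junction pairs).
#' @export
sim_snapshot <- function(sim) {
  if (inherits(sim, "tumor_run")) return(sim$snapshot)
  structure(list(
    tick = sim_tick(sim),
    dims = sim$scenario$dims,
    cells = .sim_cells_cpp(sim$ptr),
    fields = .sim_fields_cpp(sim$ptr),
    vessels = .sim_vessels_cpp(sim$ptr)
  ), class = "tumor_snapshot")
}

#' @export
print.tumor_snapshot <- function(x, ...) {
  cat("<tumor_snapshot> tick ", x$tick, ", ",
      paste(x$dims, collapse = "x"), " world, ", nrow(x$cells),
      " cells\n", sep = "")
  invisible(x)
}

#' Per-species mass ledger
#'
#' Exact bookkeeping of every species: initial mass plus deposits minus
#' consumption must equal the mass remaining on the lattice (diffusion
#' conserves mass).
#'
#' @param sim a [sim_init()] object.
#' @return A data frame with `initial`, `deposited`, `consumed`, the
#'   running `tracked` total and the actual `in_field` sum.
#' @export
sim_mass_ledger <- function(sim) .sim_ledger_cpp(sim$ptr)

#' @export
print.tumor_sim <- function(x, ...) {
  cat("<tumor_sim> '", x$scenario$name, "' at tick ", sim_tick(x), "\n",
      sep = "")
  invisible(x)
}

#' Run a scenario
#'
#' Initializes and advances a scenario to its horizon, returning the full
#' recorded trajectory.
#'
#' @param scen a [scenario()] or [scenario_preset()], or a preset name.
#' @param horizon override of the scenario horizon (ticks).
#' @param seed override of the scenario seed.
#' @return An object of class `"tumor_run"` with `timeseries`, `events`,
#'   the final `snapshot`, and the `scenario`.
#' @examples
#' r <- sim_run(scenario_preset("baseline", dims = c(21, 21, 21),
#'                              n_fibroblasts = 5), horizon = 10, seed = 1)
#' tail(r$timeseries, 3)
#' @export
sim_run <- function(scen, horizon = NULL, seed = NULL) {
  if (is.character(scen)) scen <- scenario_preset(scen)
  stopifnot(inherits(scen, "tumor_scenario"))
  if (!is.null(horizon)) scen$horizon <- as.integer(horizon)
  if (!is.null(seed)) scen$seed <- as.integer(seed)
  sim <- sim_init(scen)
  sim_step(sim, scen$horizon)
  structure(list(timeseries = sim_timeseries(sim), events = sim_events(sim),
                 snapshot = sim_snapshot(sim), scenario = scen),
            class = "tumor_run")
}

#' @export
print.tumor_run <- function(x, ...) {
  ts <- x$timeseries
  last <- ts[nrow(ts), ]
  cat("<tumor_run> '", x$scenario$name, "', ", nrow(ts) - 1L, " ticks\n",
      "  final: ", last$tumor_living, " living / ", last$tumor_necrotic,
      " necrotic tumor cells, ", last$endothelial, " endothelial cells\n",
      sep = "")
  invisible(x)
}

#' Parameter sweep
#'
#' Runs the model over a grid of values of one parameter, with replicates,
#' and classifies the fate of every run.  Deterministic given `base_seed`:
#' the run at grid point `i`, replicate `r` uses seed
#' `base_seed + 1000 * i + r`.
#'
#' @param scen base scenario (or preset name).
#' @param param name of the parameter to vary.
#' @param values numeric vector of parameter values.
#' @param replicates runs per value.
#' @param horizon override of the scenario horizon.
#' @param base_seed sweep seed.
#' @return A data frame with one row per (value, replicate): the fate from
#'   [classify_fate()], the turning-point tick (`NA` when none), the
#'   time-to-development (first tick with at least ten times the
#'   pre-turning-point maximum of living cells; `NA` when never), final
#'   population counts, and the necrotic fraction of the final snapshot.
#' @export
sim_sweep <- function(scen, param, values, replicates = 1, horizon = NULL,
                      base_seed = 1) {
  if (is.character(scen)) scen <- scenario_preset(scen)
  stopifnot(inherits(scen, "tumor_scenario"))
  rows <- list()
  for (i in seq_along(values)) {
    for (r in seq_len(replicates)) {
      ov <- list()
      ov[[param]] <- values[[i]]
      sc <- scen
      sc$params <- do.call(sim_params, utils::modifyList(
        lapply(unclass(scen$params), identity), ov))
      sc$seed <- as.integer(base_seed + 1000L * i + r)
      if (!is.null(horizon)) sc$horizon <- as.integer(horizon)
      run <- sim_run(sc)
      ts <- run$timeseries
      fate <- classify_fate(ts$tumor_living, horizon = sc$horizon)
      tp <- tryCatch(detect_turning_point(ts$tumor_living),
                     error = function(e) NULL)
      ttd <- time_to_development(ts$tumor_living)
      ncs <- necrotic_core_stats(run$snapshot)
      last <- ts[nrow(ts), ]
      rows[[length(rows) + 1L]] <- data.frame(
        param = param, value = values[[i]], replicate = r, seed = sc$seed,
        fate = fate, turning_point = if (is.null(tp)) NA_integer_ else tp,
        time_to_development = ttd,
        final_living = last$tumor_living,
        final_necrotic = last$tumor_necrotic,
        final_endothelial = last$endothelial,
        necrotic_fraction = ncs$fraction)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
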