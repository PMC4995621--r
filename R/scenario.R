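#' Simulation scenarios
#'
#' A scenario bundles a parameter set with the initial geometry (world
#' dimensions, vessel placement, fibroblast seeding), behavioral switches,
#' a horizon and an RNG seed.  `scenario()` builds a custom scenario;
#' `scenario_preset()` returns one of the shipped presets, which are defined
#' relative to the calibrated defaults (the `low_*` / `high_*` presets scale
#' the named parameter by 1/4 and 4).
#'
#' Shipped presets:
#' \describe{
#'   \item{baseline}{calibrated defaults; vessels 40 sites (200 um) from the
#'     centre.}
#'   \item{no_angiogenesis}{endothelial activation disabled; the initial
#'     vessels sit at the world border (the paper-style alternative
#'     placement), so their oxygen cannot reach the tumor in time.}
#'   \item{non_proliferating}{the seeded cell is non-cancerous: it never
#'     divides, and consumes the quiescent (stromal) oxygen ration rather
#'     than a proliferating cell's.}
#'   \item{far_vessels}{vessels 60 sites (300 um) from the centre, in a
#'     widened world.}
#'   \item{low_oxygen / high_oxygen}{`OxygenSecretionAmount` x 1/4 and x 4.}
#'   \item{low_vegf / high_vegf}{`VEGFSecretionAmount` x 1/4 and x 4.}
#'   \item{low_switch / high_switch}{`AngiogenicSwitchThreshold` (and, to
#'     keep the parameter invariants, `BranchThreshold`) x 1/2 and x 2; the
#'     windowed binding capacity bounds how high a reachable threshold can
#'     be, so the switch presets use a twofold spread.}
#' }
#'
#' @param name scenario label.
#' @param params a [sim_params()] set (or named list of overrides).
#' @param dims world dimensions in sites (default `c(100, 100, 100)`, a
#'   500-um cube).
#' @param vessel_mode `"distance"` (straight chains at
#'   `InitialVesselDistance` lateral sites from the centre axis),
#'   `"border"`, or `"random"`.
#' @param n_vessels number of vessel chains for `"random"` mode.
#' @param n_fibroblasts fibroblasts scattered around the tumor seed.
#' @param fibroblast_shell radial shell (sites from the centre) in which
#'   fibroblasts are placed.
#' @param angiogenesis can endothelial cells activate?
#' @param proliferative does the seeded tumor cell divide?
#' @param tumor place the seed cell at the world centre?
#' @param horizon default run length in ticks.
#' @param seed RNG seed.
#' @return An object of class `"tumor_scenario"`.
#' @examples
#' sc <- scenario_preset("baseline", seed = 1)
#' sc$params$OxygenSecretionAmount
#' @export
scenario <- function(name = "custom", params = sim_params(),
                     dims = c(100, 100, 100), vessel_mode = "distance",
                     n_vessels = 4, vessel_length = 12, n_fibroblasts = 150,
                     fibroblast_shell = c(15, 35), angiogenesis = TRUE,
                     proliferative = TRUE, tumor = TRUE, horizon = 1200,
                     seed = 1) {
  if (!inherits(params, "tumor_params")) params <- sim_params(params)
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 3L))
  vessel_mode <- match.arg(vessel_mode, c("distance", "border", "random"))
  if (vessel_mode == "distance") {
    d <- params$InitialVesselDistance
    ctr <- dims %/% 2L
    if (ctr[1] - d < 0 || ctr[1] + d >= dims[1] ||
        ctr[2] - d < 0 || ctr[2] + d >= dims[2]) {
      stop("initial vessel distance ", d, " sites does not fit in a ",
           paste(dims, collapse = "x"), " world", call. = FALSE)
    }
  }
  stopifnot(length(fibroblast_shell) == 2L,
            fibroblast_shell[1] <= fibroblast_shell[2])
  structure(
    list(name = name, params = params, dims = dims,
         vessel_mode = vessel_mode, n_vessels = as.integer(n_vessels),
         vessel_length = as.integer(vessel_length),
         n_fibroblasts = as.integer(n_fibroblasts),
         fibroblast_shell = as.numeric(fibroblast_shell),
         angiogenesis = isTRUE(angiogenesis),
         proliferative = isTRUE(proliferative), tumor = isTRUE(tumor),
         horizon = as.integer(horizon), seed = as.integer(seed)),
    class = "tumor_scenario")
}

#' @rdname scenario
#' @param preset preset name, see Details.
#' @param ... overrides forwarded to [scenario()] (for example `seed` or
#'   `horizon`).
#' @export
scenario_preset <- function(preset = c("baseline", "no_angiogenesis",
                                       "non_proliferating", "far_vessels",
                                       "low_oxygen", "high_oxygen",
                                       "low_vegf", "high_vegf",
                                       "low_switch", "high_switch"),
                            ...) {
  preset <- match.arg(preset)
  base <- sim_params()
  args <- list(name = preset)
  scale_par <- function(nm, f) {
    ov <- list()
    ov[[nm]] <- base[[nm]] * f
    ov
  }
  args$params <- switch(
    preset,
    baseline = base,
    no_angiogenesis = base,
    # a quiescent non-cancerous cell consumes the stromal maintenance
    # ration, not a proliferating tumor cell's
    non_proliferating = sim_params(OxygenNeedPerStep =
                                     base$FibroblastOxygenNeed),
    far_vessels = sim_params(InitialVesselDistance = 60),
    low_oxygen = sim_params(scale_par("OxygenSecretionAmount", 0.25)),
    high_oxygen = sim_params(scale_par("OxygenSecretionAmount", 4)),
    low_vegf = sim_params(scale_par("VEGFSecretionAmount", 0.25)),
    high_vegf = sim_params(scale_par("VEGFSecretionAmount", 4)),
    low_switch = sim_params(AngiogenicSwitchThreshold =
                              base$AngiogenicSwitchThreshold * 0.5,
                            BranchThreshold = base$BranchThreshold * 0.5),
    high_switch = sim_params(AngiogenicSwitchThreshold =
                               base$AngiogenicSwitchThreshold * 2,
                             BranchThreshold = base$BranchThreshold * 2)
  )
  if (preset == "no_angiogenesis") {
    args$angiogenesis <- FALSE
    args$vessel_mode <- "border"
  }
  if (preset == "non_proliferating") args$proliferative <- FALSE
  if (preset == "far_vessels") args$dims <- c(131L, 131L, 101L)
  do.call(scenario, utils::modifyList(args, list(...)))
}

#' @export
print.tumor_scenario <- function(x, ...) {
  cat("<tumor_scenario> '", x$name, "': ",
      paste(x$dims, collapse = "x"), " world, vessels ", x$vessel_mode,
      ", horizon ", x$horizon, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}
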