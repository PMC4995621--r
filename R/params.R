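#' Model parameters
#'
#' Constructs the full, validated parameter set of the model.  Five parameters
#' carry the names used throughout the tumor-angiogenesis literature on this
#' class of models (`OxygenSecretionAmount`, `VEGFSecretionAmount`,
#' `AngiogenicSwitchThreshold`, `HypoxiaLevel`, `AnoxiaLevel`); the remaining
#' rates and thresholds complete the behavioral rules and carry calibrated
#' defaults.  All molecular amounts are in abstract units; durations are in
#' simulation ticks; one lattice site corresponds to 5 micrometres.
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @details Defaults (the shipped calibration):
#' \describe{
#'   \item{OxygenSecretionAmount}{oxygen units deposited by every endothelial
#'     cell each tick (constant-rate secretion).}
#'   \item{VEGFSecretionAmount}{VEGF units deposited per pulse by a hypoxic
#'     tumor cell (and, scaled by their hypoxia counter, by CAFs).}
#'   \item{AngiogenicSwitchThreshold}{VEGF bound within `ActivationWindow`
#'     ticks needed to activate a quiescent endothelial cell.}
#'   \item{HypoxiaLevel, AnoxiaLevel}{consecutive oxygen-deficit ticks after
#'     which a cell becomes hypoxic, respectively necrotic;
#'     `HypoxiaLevel < AnoxiaLevel` is enforced.}
#'   \item{OxygenNeedPerStep}{oxygen units a tumor cell (or fibroblast) must
#'     consume per tick to avoid a deficit.}
#'   \item{VEGFPulsePeriod}{ticks between VEGF pulses of a hypoxic cell.}
#'   \item{ActivationWindow, BranchThreshold, BranchWindow}{windowed-binding
#'     bookkeeping of endothelial cells; a stalk cell that binds
#'     `BranchThreshold` units within `BranchWindow` ticks sprouts a second
#'     tip (`BranchThreshold > AngiogenicSwitchThreshold`,
#'     `BranchWindow <= ActivationWindow`).}
#'   \item{VEGFBindingCapacity}{maximum VEGF an endothelial cell binds
#'     (consumes) per tick.}
#'   \item{VEGFBindingFloor}{pooled local VEGF below which an endothelial
#'     cell binds nothing (receptor floor).}
#'   \item{VEGFSecretionDeficitLimit}{oxygen-deficit count beyond which a
#'     hypoxic cell is too compromised to keep secreting VEGF.}
#'   \item{FibroblastOxygenNeed}{per-tick oxygen ration of a quiescent
#'     stromal cell.}
#'   \item{EndothelialMaturationAge}{age (ticks) at which a newly formed
#'     endothelial cell becomes an established vessel cell and stops
#'     depending on VEGF for survival.}
#'   \item{SproutPeriod}{mean ticks between elongation steps of a tip
#'     cell.}
#'   \item{CAFVEGFFraction}{a CAF's VEGF pulse as a fraction of a hypoxic
#'     tumor cell's.}
#'   \item{OxygenDecayRate, VEGFDecayRate, FGFDecayRate, HGFDecayRate}{
#'     first-order clearance per tick; sets each species' signalling range
#'     \code{sqrt(D / rate)}.}
#'   \item{OxygenDiffusionSteps, VEGFDiffusionSteps, FGFDiffusionSteps,
#'     HGFDiffusionSteps}{diffusion-kernel applications per tick (relative
#'     diffusivities).}
#'   \item{EndothelialMinVEGF, StarvationLimit}{a newly formed endothelial
#'     cell binding less than `EndothelialMinVEGF` for `StarvationLimit`
#'     consecutive ticks dies together with the cells distal to it.}
#'   \item{ProliferationPeriod, HGFBoost, HGFThreshold}{tumor division clock;
#'     the period is divided by `HGFBoost` where local HGF exceeds
#'     `HGFThreshold`.}
#'   \item{FGFSecretionAmount, HGFSecretionAmount}{per-tick FGF output of
#'     living tumor cells and HGF output of CAFs.}
#'   \item{CAFRadius, CAFBaseProb}{fibroblasts within `CAFRadius` sites of a
#'     living tumor cell convert to CAFs with probability `CAFBaseProb` per
#'     tick (given sufficient oxygen).}
#'   \item{ECMDegradationRate}{per-tick multiplicative ECM degradation by
#'     CAFs in their Moore neighborhood.}
#'   \item{InitialVesselDistance}{lateral distance (sites) of the initial
#'     vessels from the world centre; 40 sites = 200 micrometres.}
#'   \item{BaseMotility}{tumor-cell movement probability per tick, scaled by
#'     `(1 - local ECM density)`.}
#'   \item{OxygenBackground}{initial uniform oxygen amount per lattice site.}
#' }
#'
#' @return A named list of class `"tumor_params"`.
#' @examples
#' p <- sim_params(HypoxiaLevel = 10)
#' p$HypoxiaLevel
#' @export
sim_params <- function(...) {
  p <- list(
    OxygenSecretionAmount     = 8,
    VEGFSecretionAmount       = 8000,
    AngiogenicSwitchThreshold = 100,
    HypoxiaLevel              = 20,
    AnoxiaLevel               = 400,
    OxygenNeedPerStep         = 1,
    FibroblastOxygenNeed      = 0.25,
    VEGFPulsePeriod           = 10,
    ActivationWindow          = 300,
    BranchThreshold           = 190,
    BranchWindow              = 30,
    VEGFBindingCapacity       = 8,
    VEGFBindingFloor          = 0.2,
    VEGFSecretionDeficitLimit = 350,
    EndothelialMinVEGF        = 0.05,
    StarvationLimit           = 40,
    EndothelialMaturationAge  = 100,
    SproutPeriod              = 5,
    ProliferationPeriod       = 15,
    HGFBoost                  = 2,
    HGFThreshold              = 0.5,
    FGFSecretionAmount        = 0.2,
    HGFSecretionAmount        = 0.5,
    CAFRadius                 = 10,
    CAFBaseProb               = 0.01,
    CAFVEGFFraction           = 0.1,
    ECMDegradationRate        = 0.05,
    InitialVesselDistance     = 40,
    BaseMotility              = 0.05,
    OxygenBackground          = 1.2,
    OxygenDecayRate           = 0.006,
    VEGFDecayRate             = 0.05,
    FGFDecayRate              = 0.01,
    HGFDecayRate              = 0.01,
    OxygenDiffusionSteps      = 6,
    VEGFDiffusionSteps        = 6,
    FGFDiffusionSteps         = 1,
    HGFDiffusionSteps         = 1
  )
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]])) {
    over <- over[[1L]]
  }
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           "\nvalid parameters are: ", paste(names(p), collapse = ", "),
           call. = FALSE)
    }
    p[names(over)] <- over
  }
  validate_params(p)
}

#' Validate a parameter set
#'
#' Checks the invariants the behavioral rules rely on:
#' `HypoxiaLevel < AnoxiaLevel`,
#' `BranchThreshold > AngiogenicSwitchThreshold`,
#' `BranchWindow <= ActivationWindow`, non-negative amounts and periods, and
#' probabilities in `[0, 1]`.
#'
#' @param p a named list of parameters (as from [sim_params()]).
#' @return `p`, classed `"tumor_params"`, invisibly usable downstream.
#' @export
validate_params <- function(p) {
  num1 <- function(nm) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop("parameter '", nm, "' must be a single non-missing number",
           call. = FALSE)
    }
    v
  }
  for (nm in setdiff(names(p), character())) num1(nm)
  nonneg <- c("OxygenSecretionAmount", "VEGFSecretionAmount",
              "AngiogenicSwitchThreshold", "HypoxiaLevel", "AnoxiaLevel",
              "OxygenNeedPerStep", "FibroblastOxygenNeed",
              "VEGFPulsePeriod", "ActivationWindow",
              "BranchThreshold", "BranchWindow", "VEGFBindingCapacity",
              "VEGFBindingFloor", "VEGFSecretionDeficitLimit",
              "EndothelialMaturationAge", "SproutPeriod",
              "EndothelialMinVEGF", "StarvationLimit", "ProliferationPeriod",
              "HGFBoost", "HGFThreshold", "FGFSecretionAmount",
              "HGFSecretionAmount", "CAFRadius", "InitialVesselDistance",
              "OxygenBackground")
  for (nm in c("OxygenDiffusionSteps", "VEGFDiffusionSteps",
               "FGFDiffusionSteps", "HGFDiffusionSteps")) {
    if (p[[nm]] < 1) {
      stop("parameter '", nm, "' must be a positive step count", call. = FALSE)
    }
  }
  for (nm in c("OxygenDecayRate", "VEGFDecayRate", "FGFDecayRate",
               "HGFDecayRate")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop("parameter '", nm, "' must be a per-tick fraction in [0, 1]",
           call. = FALSE)
    }
  }
  for (nm in nonneg) {
    if (p[[nm]] < 0) stop("parameter '", nm, "' must be >= 0", call. = FALSE)
  }
  for (nm in c("CAFBaseProb", "CAFVEGFFraction", "ECMDegradationRate",
               "BaseMotility")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop("parameter '", nm, "' must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  if (p$HypoxiaLevel >= p$AnoxiaLevel) {
    stop("invalid parameters: HypoxiaLevel (", p$HypoxiaLevel,
         ") must be strictly below AnoxiaLevel (", p$AnoxiaLevel, ")",
         call. = FALSE)
  }
  if (p$BranchThreshold <= p$AngiogenicSwitchThreshold) {
    stop("invalid parameters: BranchThreshold (", p$BranchThreshold,
         ") must exceed AngiogenicSwitchThreshold (",
         p$AngiogenicSwitchThreshold, ")", call. = FALSE)
  }
  if (p$BranchWindow > p$ActivationWindow) {
    stop("invalid parameters: BranchWindow (", p$BranchWindow,
         ") must not exceed ActivationWindow (", p$ActivationWindow, ")",
         call. = FALSE)
  }
  structure(p, class = "tumor_params")
}

#' @export
print.tumor_params <- function(x, ...) {
  cat("<tumor_params> ", length(x), " parameters\n", sep = "")
  w <- max(nchar(names(x)))
  for (nm in names(x)) {
    cat(sprintf("  %-*s %g\n", w, nm, x[[nm]]))
  }
  invisible(x)
}
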