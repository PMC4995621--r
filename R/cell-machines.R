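#' Statechart machines of the three cell behaviors
#'
#' The behavioral programs of tumor cells, endothelial cells and
#' fibroblasts, declared on the generic statechart engine.  Each machine
#' keeps its per-cell counters (oxygen-deficit ticks, VEGF pulses, bound
#' VEGF window, starvation) in the instance context; the driver feeds it
#' the per-tick sensing events listed below.  The compiled simulation loop
#' executes the same transition rules; unit tests drive single cells
#' through both paths and assert identical state traces.
#'
#' Tumor machine events: `"o2_ok"` / `"o2_low"` (the tick's oxygen
#' consumption met the need, or not), `"vegf_on"` / `"vegf_off"`
#' (secretion-region control derived from the oxygen region).  The oxygen
#' region moves `normal -> hypoxic` after `HypoxiaLevel` consecutive
#' deficit ticks and `hypoxic -> necrotic` after `AnoxiaLevel`; any
#' sufficient tick resets the deficit and returns a hypoxic cell to
#' `normal`.  The secretion region pulses one VEGF unit bundle on entry
#' and then every `VEGFPulsePeriod` ticks while pulsing
#' (`ctx$pulses` counts them).
#'
#' @param params a [sim_params()] parameter set.
#' @return An [sc_machine()].
#' @export
tumor_machine <- function(params = sim_params()) {
  p <- validate_params(params)
  inc <- function(ctx) ctx$deficit <- ctx$deficit + 1L
  clear <- function(ctx) ctx$deficit <- 0L
  sc_machine(
    states = list(
      sc_state("cell", parallel = TRUE),
      sc_state("oxygen", parent = "cell", initial = TRUE),
      sc_state("alive", parent = "oxygen", initial = TRUE),
      sc_state("normal", parent = "alive", initial = TRUE),
      sc_state("hypoxic", parent = "alive"),
      sc_state("necrotic", parent = "oxygen"),
      sc_state("secretion", parent = "cell"),
      sc_state("quiet", parent = "secretion", initial = TRUE),
      sc_state("pulsing", parent = "secretion",
               timer = params$VEGFPulsePeriod,
               on_entry = function(ctx) ctx$pulses <- ctx$pulses + 1L)
    ),
    transitions = list(
      sc_transition("normal", "hypoxic", "o2_low",
                    guard = function(ctx) ctx$deficit + 1L >= p$HypoxiaLevel,
                    action = inc),
      sc_transition("normal", "normal", "o2_low", action = inc),
      sc_transition("hypoxic", "necrotic", "o2_low",
                    guard = function(ctx) ctx$deficit + 1L >= p$AnoxiaLevel,
                    action = inc),
      sc_transition("hypoxic", "hypoxic", "o2_low", action = inc),
      sc_transition("hypoxic", "normal", "o2_ok", action = clear),
      sc_transition("normal", "normal", "o2_ok", action = clear),
      sc_transition("quiet", "pulsing", "vegf_on"),
      sc_transition("pulsing", "quiet", "vegf_off"),
      sc_transition("pulsing", "pulsing", "timeout")
    )
  )
}

#' @rdname tumor_machine
#' @details Endothelial machine events: `"vegf_window"` (re-evaluate the
#'   windowed binding sum in `ctx$window` against the angiogenic switch
#'   threshold; `ctx$inhibited` blocks activation — delta-notch lateral
#'   inhibition), `"elongated"` and `"anastomosis"` (a tip hands its role
#'   on, or fuses with another vessel, becoming a stalk), `"branch"`
#'   (a stalk sprouts a second tip; counted in `ctx$branches`), and
#'   `"starved"` (a newly formed cell fell below the minimum VEGF for
#'   `StarvationLimit` ticks and dies).
#' @export
endothelial_machine <- function(params = sim_params()) {
  p <- validate_params(params)
  sc_machine(
    states = list(
      sc_state("ec", parallel = FALSE),
      sc_state("vessel", parent = "ec", initial = TRUE),
      sc_state("quiescent", parent = "vessel", initial = TRUE),
      sc_state("tip", parent = "vessel"),
      sc_state("stalk", parent = "vessel"),
      sc_state("dead", parent = "ec")
    ),
    transitions = list(
      sc_transition("quiescent", "tip", "vegf_window",
                    guard = function(ctx) {
                      !isTRUE(ctx$inhibited) && ctx$window >= p$AngiogenicSwitchThreshold
                    }),
      sc_transition("tip", "stalk", "elongated"),
      sc_transition("tip", "stalk", "anastomosis"),
      sc_transition("stalk", "stalk", "branch",
                    guard = function(ctx) ctx$branch_window >= p$BranchThreshold,
                    action = function(ctx) ctx$branches <- ctx$branches + 1L),
      sc_transition("vessel", "dead", "starved",
                    guard = function(ctx) isTRUE(ctx$newly_formed))
    )
  )
}

#' @rdname tumor_machine
#' @details Fibroblast machine events: `"near_tumor"` (a living tumor cell
#'   lies within `CAFRadius` and the tick's oxygen was sufficient; the
#'   driver draws the `CAFBaseProb` Bernoulli and passes it as
#'   `ctx$roll`), after which the cell is a CAF for good.
#' @export
fibroblast_machine <- function(params = sim_params()) {
  validate_params(params)
  sc_machine(
    states = list(
      sc_state("fibroblast"),
      sc_state("resting", parent = "fibroblast", initial = TRUE),
      sc_state("caf", parent = "fibroblast")
    ),
    transitions = list(
      sc_transition("resting", "caf", "near_tumor",
                    guard = function(ctx) isTRUE(ctx$roll))
    )
  )
}

#' Drive a tumor-cell machine through a per-tick oxygen trace
#'
#' Reference driver used to compare engine semantics with the compiled
#' stepper: for each tick it dispatches `"o2_ok"` or `"o2_low"`, aligns the
#' secretion region with the oxygen region, and advances the pulse timer.
#'
#' @param machine a [tumor_machine()].
#' @param oxygen_ok logical vector; one entry per tick, `TRUE` when the
#'   cell could consume its full oxygen need that tick.
#' @return A list with per-tick `state` (`"normal"`, `"hypoxic"`,
#'   `"necrotic"`) and the total number of VEGF `pulses`.
#' @export
drive_tumor_machine <- function(machine, oxygen_ok) {
  ctx <- new.env(parent = emptyenv())
  ctx$deficit <- 0L
  ctx$pulses <- 0L
  inst <- sc_instantiate(machine, ctx)
  states <- character(length(oxygen_ok))
  for (i in seq_along(oxygen_ok)) {
    if ("necrotic" %in% sc_active(inst)) {
      states[i] <- "necrotic"
      next
    }
    inst <- sc_tick(inst)  # timers first: a state entered below starts
                           # counting from the next tick, like the stepper
    inst <- sc_dispatch(inst, if (oxygen_ok[i]) "o2_ok" else "o2_low")
    act <- sc_active(inst)
    inst <- sc_dispatch(inst, if ("hypoxic" %in% act) "vegf_on" else "vegf_off")
    act <- sc_active(inst)
    states[i] <- if ("necrotic" %in% act) "necrotic"
      else if ("hypoxic" %in% act) "hypoxic" else "normal"
  }
  list(state = states, pulses = ctx$pulses)
}
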