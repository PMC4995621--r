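# Engine semantics: initial configurations, dispatch priority, timers,
# orthogonal regions, and the configuration invariants.

simple_machine <- function() {
  sc_machine(
    states = list(
      sc_state("root"),
      sc_state("A", parent = "root", initial = TRUE),
      sc_state("B", parent = "root")
    ),
    transitions = list(sc_transition("A", "B", "e"))
  )
}

test_that("instantiation enters the chain of initial children", {
  one <- sc_machine(states = list(sc_state("root")))
  expect_identical(sc_active(sc_instantiate(one)), "root")

  nested <- sc_machine(states = list(
    sc_state("Root"),
    sc_state("A", parent = "Root", initial = TRUE),
    sc_state("B", parent = "Root"),
    sc_state("A1", parent = "A", initial = TRUE)
  ))
  expect_identical(sc_active(sc_instantiate(nested)),
                   sort(c("Root", "A", "A1")))
})

test_that("malformed machines are rejected", {
  expect_error(sc_machine(states = list(
    sc_state("r"),
    sc_state("a", parent = "r", initial = TRUE),
    sc_state("b", parent = "r", initial = TRUE)
  )), "exactly one initial child")
  expect_error(sc_machine(states = list(
    sc_state("r"), sc_state("r", parent = "r")
  )), "duplicate")
  expect_error(sc_machine(states = list(
    sc_state("a", parent = "b"), sc_state("b", parent = "a")
  )), "root|cycle")
  expect_error(sc_machine(
    states = list(sc_state("r"), sc_state("a", parent = "r", initial = TRUE)),
    transitions = list(sc_transition("a", "ghost", "e"))
  ), "unknown state")
})

test_that("dispatch fires the matching transition and ignores others", {
  m <- simple_machine()
  inst <- sc_instantiate(m)
  inst <- sc_dispatch(inst, "e")
  expect_true("B" %in% sc_active(inst))
  expect_false("A" %in% sc_active(inst))
  # no enabled transition: configuration unchanged
  before <- sc_active(inst)
  expect_identical(sc_active(sc_dispatch(inst, "nothing")), before)
})

test_that("deepest enabled source wins over an ancestor transition", {
  m <- sc_machine(
    states = list(
      sc_state("root"),
      sc_state("A", parent = "root", initial = TRUE),
      sc_state("A1", parent = "A", initial = TRUE),
      sc_state("B", parent = "root"),
      sc_state("C", parent = "root")
    ),
    transitions = list(
      sc_transition("A", "B", "e"),   # ancestor (declared first)
      sc_transition("A1", "C", "e")   # deeper source must win
    )
  )
  inst <- sc_dispatch(sc_instantiate(m), "e")
  expect_true("C" %in% sc_active(inst))
  expect_false("B" %in% sc_active(inst))
})

test_that("same-depth ambiguity errors in strict mode, uses order otherwise", {
  m <- sc_machine(
    states = list(
      sc_state("root"),
      sc_state("A", parent = "root", initial = TRUE),
      sc_state("B", parent = "root"),
      sc_state("C", parent = "root")
    ),
    transitions = list(
      sc_transition("A", "B", "e"),
      sc_transition("A", "C", "e")
    )
  )
  inst <- sc_instantiate(m)
  expect_error(sc_dispatch(inst, "e", strict = TRUE), "ambiguous")
  expect_true("B" %in% sc_active(sc_dispatch(inst, "e")))
})

test_that("guards gate transitions through the context", {
  ctx <- new.env()
  ctx$armed <- FALSE
  m <- sc_machine(
    states = list(
      sc_state("root"),
      sc_state("A", parent = "root", initial = TRUE),
      sc_state("B", parent = "root")
    ),
    transitions = list(
      sc_transition("A", "B", "go", guard = function(c) isTRUE(c$armed))
    )
  )
  inst <- sc_instantiate(m, ctx)
  inst <- sc_dispatch(inst, "go")
  expect_true("A" %in% sc_active(inst))
  ctx$armed <- TRUE
  inst <- sc_dispatch(inst, "go")
  expect_true("B" %in% sc_active(inst))
})

timer_machine <- function(dur = 3) {
  sc_machine(
    states = list(
      sc_state("root"),
      sc_state("wait", parent = "root", initial = TRUE, timer = dur),
      sc_state("done", parent = "root")
    ),
    transitions = list(
      sc_transition("wait", "done", "timeout"),
      sc_transition("done", "wait", "reset"),
      sc_transition("wait", "wait", "poke")
    )
  )
}

test_that("a timer of n ticks expires exactly after n ticks", {
  inst <- sc_instantiate(timer_machine(3))
  inst <- sc_tick(inst)
  inst <- sc_tick(inst)
  expect_true("wait" %in% sc_active(inst))
  inst <- sc_tick(inst)
  expect_true("done" %in% sc_active(inst))
})

test_that("timers do not run in inactive states and reset on re-entry", {
  inst <- sc_instantiate(timer_machine(3))
  inst <- sc_tick(inst)                 # 2 remaining
  inst <- sc_dispatch(inst, "poke")     # self-transition re-enters: reset
  inst <- sc_tick(inst)
  inst <- sc_tick(inst)
  expect_true("wait" %in% sc_active(inst))  # would have fired without reset
  inst <- sc_tick(inst)
  expect_true("done" %in% sc_active(inst))
  # 'done' has no timer; ticking is a no-op there
  inst <- sc_tick(inst)
  expect_true("done" %in% sc_active(inst))
  # leave and re-enter: full duration again
  inst <- sc_dispatch(inst, "reset")
  inst <- sc_tick(inst); inst <- sc_tick(inst)
  expect_true("wait" %in% sc_active(inst))
})

test_that("orthogonal regions are all active, one leaf each", {
  m <- sc_machine(
    states = list(
      sc_state("cell", parallel = TRUE),
      sc_state("r1", parent = "cell"),
      sc_state("a", parent = "r1", initial = TRUE),
      sc_state("b", parent = "r1"),
      sc_state("r2", parent = "cell"),
      sc_state("x", parent = "r2", initial = TRUE),
      sc_state("y", parent = "r2")
    ),
    transitions = list(
      sc_transition("a", "b", "e1"),
      sc_transition("x", "y", "e2")
    )
  )
  inst <- sc_instantiate(m)
  expect_setequal(sc_active(inst), c("cell", "r1", "a", "r2", "x"))
  inst <- sc_dispatch(inst, "e2")
  expect_setequal(sc_active(inst), c("cell", "r1", "a", "r2", "y"))
  # cross-region transitions are rejected at build time
  expect_error(sc_machine(
    states = list(
      sc_state("cell", parallel = TRUE),
      sc_state("r1", parent = "cell"),
      sc_state("a", parent = "r1", initial = TRUE),
      sc_state("r2", parent = "cell"),
      sc_state("x", parent = "r2", initial = TRUE)
    ),
    transitions = list(sc_transition("a", "x", "e"))
  ), "orthogonal")
})

test_that("configuration invariants hold under random event sequences", {
  m <- tumor_machine(sim_params())
  events <- c("o2_ok", "o2_low", "vegf_on", "vegf_off")
  parent_closed <- function(inst) {
    all(vapply(sc_active(inst), function(nm) {
      p <- inst$spec$states[[nm]]$parent
      is.null(p) || p %in% inst$active
    }, logical(1)))
  }
  one_leaf_per_region <- function(inst) {
    for (nm in sc_active(inst)) {
      kids <- inst$spec$children[[nm]]
      if (length(kids) == 0L) next
      n_active <- sum(kids %in% inst$active)
      want <- if (inst$spec$states[[nm]]$parallel) length(kids) else 1L
      if (n_active != want) return(FALSE)
    }
    TRUE
  }
  set.seed(42)
  for (rep in 1:5) {
    ctx <- new.env(); ctx$deficit <- 0L; ctx$pulses <- 0L
    inst <- sc_instantiate(m, ctx)
    for (k in 1:60) {
      ev <- sample(events, 1)
      inst <- sc_dispatch(inst, ev)
      inst <- sc_tick(inst)
      expect_true(parent_closed(inst))
      expect_true(one_leaf_per_region(inst))
    }
  }
})

test_that("identical spec and event sequence give identical traces", {
  m <- tumor_machine(sim_params())
  run_trace <- function() {
    ctx <- new.env(); ctx$deficit <- 0L; ctx$pulses <- 0L
    inst <- sc_instantiate(m, ctx)
    trace <- character(0)
    for (ev in rep(c("o2_low", "o2_low", "o2_ok", "vegf_on"), 10)) {
      inst <- sc_dispatch(inst, ev)
      inst <- sc_tick(inst)
      trace <- c(trace, paste(sc_active(inst), collapse = "|"))
    }
    trace
  }
  expect_identical(run_trace(), run_trace())
})

test_that("machine definitions serialize to JSON and carry the topology", {
  js <- sc_to_json(endothelial_machine(sim_params()))
  doc <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_identical(doc$root, "ec")
  nms <- vapply(doc$states, `[[`, "", "name")
  expect_true(all(c("quiescent", "tip", "stalk", "dead") %in% nms))
  expect_true(any(vapply(doc$transitions, function(tr) {
    tr$source == "quiescent" && tr$target == "tip"
  }, logical(1))))
})
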