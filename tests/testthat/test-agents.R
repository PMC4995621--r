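# Cell-agent behavior: hypoxia/anoxia timing against the statechart
# machines, VEGF pulsing, lateral inhibition, causality, CAF conversion
# and chemotaxis, sprout starvation.

# a world with no vessels and no oxygen: the seeded cell starves on schedule
starving_cell_scenario <- function(hypoxia = 15, anoxia = 100, ...) {
  scenario(name = "starve",
           params = sim_params(HypoxiaLevel = hypoxia, AnoxiaLevel = anoxia,
                               OxygenBackground = 0, ...),
           dims = c(15, 15, 15), vessel_mode = "random", n_vessels = 0,
           n_fibroblasts = 0, seed = 1)
}

test_that("hypoxia and necrosis fire after the configured deficit runs", {
  sc <- starving_cell_scenario(hypoxia = 15, anoxia = 100)
  s <- sim_init(sc)
  sim_step(s, 14)
  expect_identical(sim_snapshot(s)$cells$state, "normal")
  sim_step(s, 1)
  expect_identical(sim_snapshot(s)$cells$state, "hypoxic")
  sim_step(s, 84)
  expect_identical(sim_snapshot(s)$cells$state, "hypoxic")
  sim_step(s, 1)
  expect_identical(sim_snapshot(s)$cells$state, "necrotic")
  ev <- sim_events(s)
  expect_identical(ev$tick[ev$event == "necrosis"], 100L)
  # necrotic cells are inert: nothing further happens
  sim_step(s, 50)
  expect_identical(nrow(sim_events(s)), nrow(ev))
})

test_that("the compiled stepper and the statechart machine agree tick by tick", {
  hyp <- 12; anx <- 60
  sc <- starving_cell_scenario(hypoxia = hyp, anoxia = anx)
  s <- sim_init(sc)
  sim_states <- character(anx + 5)
  for (t in seq_along(sim_states)) {
    sim_step(s, 1)
    sim_states[t] <- sim_snapshot(s)$cells$state
  }
  m <- tumor_machine(sim_params(HypoxiaLevel = hyp, AnoxiaLevel = anx,
                                OxygenBackground = 0))
  eng <- drive_tumor_machine(m, oxygen_ok = rep(FALSE, anx + 5))
  expect_identical(sim_states, eng$state)
  # VEGF pulse schedules agree too (via the deposited-mass ledger)
  led <- sim_mass_ledger(s)
  p <- sim_params(HypoxiaLevel = hyp, AnoxiaLevel = anx)
  sim_pulses <- led$deposited[led$species == "vegf"] / p$VEGFSecretionAmount
  expect_equal(sim_pulses, eng$pulses)
})

test_that("a hypoxic spell of 3 pulse periods yields exactly 3 pulses", {
  p <- sim_params()
  m <- tumor_machine(p)
  # the first pulse fires on the hypoxia-onset tick, so a spell of exactly
  # 3 * VEGFPulsePeriod hypoxic ticks contains pulses 1, 1 + p, 1 + 2p
  n_low <- p$HypoxiaLevel - 1 + 3 * p$VEGFPulsePeriod
  eng <- drive_tumor_machine(m, oxygen_ok = rep(FALSE, n_low))
  expect_equal(eng$pulses, 3)
})

test_that("hypoxia is reversible when oxygen returns before anoxia", {
  p <- sim_params(HypoxiaLevel = 10, AnoxiaLevel = 80)
  m <- tumor_machine(p)
  trace <- c(rep(FALSE, 30), rep(TRUE, 5), rep(FALSE, 79), rep(TRUE, 1),
             rep(FALSE, 10))
  eng <- drive_tumor_machine(m, trace)
  expect_identical(eng$state[30], "hypoxic")
  expect_identical(eng$state[31], "normal")    # recovery resets the deficit
  expect_identical(eng$state[114], "hypoxic")  # 79 lows < 80: still alive
  expect_identical(eng$state[115], "normal")
  expect_false(any(eng$state == "necrotic"))
  # and in the simulation: a starving cell rescued by a nearby vessel
  sc <- scenario(name = "rescue",
                 params = sim_params(HypoxiaLevel = 5, AnoxiaLevel = 300,
                                     OxygenBackground = 0.05,
                                     InitialVesselDistance = 8,
                                     OxygenDiffusionSteps = 1,
                                     OxygenSecretionAmount = 150),
                 dims = c(21, 21, 21), n_fibroblasts = 0, seed = 4,
                 horizon = 250)
  r <- sim_run(sc)
  ts <- r$timeseries
  expect_gt(max(ts$tumor_hypoxic[1:80]), 0)       # went hypoxic early
  expect_equal(ts$tumor_hypoxic[251], 0)          # recovered
  expect_gt(ts$tumor_living[251], 1)              # and resumed proliferating
  expect_equal(ts$tumor_necrotic[251], 0)
})

test_that("the necrotic population never shrinks", {
  sc <- scenario_preset("baseline", dims = c(25, 25, 25), seed = 6,
                        n_fibroblasts = 10, horizon = 350,
                        params = sim_params(InitialVesselDistance = 9,
                                            AnoxiaLevel = 120))
  ts <- sim_run(sc)$timeseries
  expect_gt(max(ts$tumor_necrotic), 0)
  expect_true(all(diff(ts$tumor_necrotic) >= 0))
})

test_that("without VEGF secretion and without CAFs no activation ever occurs", {
  sc <- scenario(name = "novegf",
                 params = sim_params(VEGFSecretionAmount = 0,
                                     AngiogenicSwitchThreshold = 1,
                                     BranchThreshold = 2,
                                     InitialVesselDistance = 6),
                 dims = c(21, 21, 21), n_fibroblasts = 0, seed = 2,
                 horizon = 250)
  r <- sim_run(sc)
  expect_equal(sum(r$events$event == "activation"), 0)
  expect_equal(sum(r$events$event == "branch"), 0)
  ts <- r$timeseries
  expect_true(all(ts$endothelial == ts$endothelial[1]))
})

test_that("delta-notch inhibition: no two adjacent cells ever activate", {
  # near vessels + a strongly secreting tumor force many activations
  sc <- scenario(name = "dn",
                 params = sim_params(InitialVesselDistance = 8,
                                     VEGFSecretionAmount = 400,
                                     AngiogenicSwitchThreshold = 20,
                                     BranchThreshold = 40,
                                     OxygenBackground = 0.3),
                 dims = c(31, 31, 31), vessel_length = 21,
                 n_fibroblasts = 0, seed = 8, horizon = 250)
  r <- sim_run(sc)
  act <- r$events[r$events$event == "activation", ]
  expect_gt(nrow(act), 3)
  if (nrow(act) > 1) {
    for (i in seq_len(nrow(act) - 1)) {
      d <- pmax(abs(act$x[(i + 1):nrow(act)] - act$x[i]),
                abs(act$y[(i + 1):nrow(act)] - act$y[i]),
                abs(act$z[(i + 1):nrow(act)] - act$z[i]))
      expect_true(all(d > 1))  # inhibition is permanent, any later tick too
    }
  }
})

test_that("fibroblasts convert near the tumor and CAFs close in on it", {
  sc <- scenario(name = "caf",
                 params = sim_params(CAFRadius = 12, CAFBaseProb = 0.2,
                                     InitialVesselDistance = 13),
                 dims = c(31, 31, 31), n_fibroblasts = 40,
                 fibroblast_shell = c(6, 12), seed = 9, horizon = 200)
  r <- sim_run(sc)
  ev <- r$events
  expect_gt(sum(ev$event == "caf_conversion"), 5)
  cells <- r$snapshot$cells
  fb <- cells[cells$kind == "fibroblast", ]
  ctr <- c(15, 15, 15)
  d_end <- sqrt((fb$x - ctr[1])^2 + (fb$y - ctr[2])^2 + (fb$z - ctr[3])^2)
  # CAFs chemotax up the tumor's FGF gradient: closer than where they began
  caf <- fb[fb$state == "caf", ]
  d_caf <- sqrt((caf$x - ctr[1])^2 + (caf$y - ctr[2])^2 + (caf$z - ctr[3])^2)
  expect_lt(mean(d_caf), 9)  # started uniformly in the 6-12 shell
  # ECM is degraded around CAFs
  expect_lt(min(r$snapshot$fields$ecm), 1)
})

test_that("fibroblasts far from any tumor cell never become CAFs", {
  sc <- scenario(name = "foff",
                 params = sim_params(CAFRadius = 4, CAFBaseProb = 0.5,
                                     InitialVesselDistance = 12),
                 dims = c(31, 31, 31), n_fibroblasts = 30,
                 fibroblast_shell = c(10, 14), seed = 10, horizon = 120)
  r <- sim_run(sc)
  expect_equal(sum(r$events$event == "caf_conversion"), 0)
})

test_that("sprouts that outrun their VEGF supply die back", {
  # strong transient secretion activates sprouting, then the source turns
  # off (anoxia) and the young vessel cells starve
  sc <- scenario(name = "dieback",
                 params = sim_params(InitialVesselDistance = 8,
                                     VEGFSecretionAmount = 400,
                                     AngiogenicSwitchThreshold = 20,
                                     BranchThreshold = 40,
                                     OxygenBackground = 0.2,
                                     AnoxiaLevel = 120,
                                     VEGFDecayRate = 0.05,
                                     EndothelialMinVEGF = 0.2,
                                     StarvationLimit = 25),
                 dims = c(31, 31, 31), vessel_length = 15,
                 n_fibroblasts = 0, seed = 12, horizon = 500)
  r <- sim_run(sc)
  ev <- r$events
  expect_gt(sum(ev$event == "activation"), 0)
  expect_gt(sum(ev$event == "ec_death"), 0)
  ts <- r$timeseries
  expect_lt(ts$endothelial[nrow(ts)], max(ts$endothelial))
})
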