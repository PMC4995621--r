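# Molecular fields: deposits, pooled consumption, the diffusion kernel and
# its Monte-Carlo random-walk oracle, gradient steps, and mass bookkeeping.

test_that("deposits add mass exactly where placed", {
  f <- new_field("vegf", c(9, 9, 9))
  expect_equal(field_mass(field_deposit(f, c(4, 4, 4), 0)), 0)
  f <- field_deposit(f, c(4, 4, 4), 10)
  expect_equal(field_mass(f), 10)
  expect_equal(f$amounts[5, 5, 5], 10)
  f <- field_deposit(f, c(0, 0, 0), 5)
  f <- field_deposit(f, c(8, 8, 8), 5)
  expect_equal(field_mass(f), 20)
  expect_error(field_deposit(f, c(0, 0, 0), -1), "non-negative")
})

test_that("a point mass of 27 spreads one unit onto self and each neighbor", {
  f <- new_field("vegf", c(9, 9, 9))
  f <- field_deposit(f, c(4, 4, 4), 27)
  f <- field_diffuse(f, 1)
  expect_equal(f$amounts[5, 5, 5], 1)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    expect_equal(f$amounts[5 + dx, 5 + dy, 5 + dz], 1)
  }
  expect_equal(f$amounts[7, 5, 5], 0)
  expect_equal(field_mass(f), 27, tolerance = 1e-12)
})

test_that("a uniform field is a fixed point and mass is conserved", {
  f <- new_field("oxygen", c(7, 8, 6), initial = 2.5)
  g <- field_diffuse(f, 5)
  expect_equal(g$amounts, f$amounts, tolerance = 1e-12)
  h <- new_field("vegf", c(11, 11, 11))
  h <- field_deposit(h, c(2, 9, 5), 123.456)
  h <- field_deposit(h, c(10, 0, 0), 1)
  m0 <- field_mass(h)
  h <- field_diffuse(h, 40)  # long enough to hit every boundary
  expect_equal(field_mass(h), m0, tolerance = 1e-9 * m0)
  expect_true(all(h$amounts >= 0))
})

test_that("point-source profiles keep the octahedral lattice symmetry", {
  f <- new_field("vegf", c(11, 11, 11))
  f <- field_deposit(f, c(5, 5, 5), 1000)
  f <- field_diffuse(f, 6)
  a <- f$amounts
  expect_equal(a[8, 6, 6], a[6, 8, 6], tolerance = 1e-12)
  expect_equal(a[8, 6, 6], a[6, 6, 8], tolerance = 1e-12)
  expect_equal(a[8, 6, 6], a[4, 6, 6], tolerance = 1e-12)
  expect_equal(a[7, 7, 6], a[5, 7, 6], tolerance = 1e-12)
  expect_equal(a[7, 7, 6], a[7, 5, 6], tolerance = 1e-12)
})

test_that("kernel matches the Monte-Carlo walker oracle on a 9x9x9 world", {
  dims <- c(9, 9, 9)
  n_walk <- 3e5
  f <- new_field("oxygen", dims)
  f <- field_deposit(f, c(4, 4, 4), n_walk)
  f <- field_diffuse(f, 10)
  set.seed(99)
  mc <- walker_occupancy(dims, c(4, 4, 4), n_walk, 10)
  expect_equal(sum(mc), n_walk)
  rel_l1 <- sum(abs(mc - f$amounts)) / sum(f$amounts)
  expect_lt(rel_l1, 0.05)
})

test_that("second moment of a spreading point mass grows linearly", {
  dims <- c(41, 41, 41)
  f <- new_field("vegf", dims)
  f <- field_deposit(f, c(20, 20, 20), 1)
  co <- as.matrix(expand.grid(x = 0:40, y = 0:40, z = 0:40))
  r2 <- array(rowSums((co - 20)^2), dim = dims)
  moments <- numeric(8)
  for (s in 1:8) {
    f <- field_diffuse(f, 1)
    moments[s] <- sum(f$amounts * r2)
  }
  # per-axis variance is 2/3 per step: E[r^2] = 3 * (2/3) * t = 2t
  expect_equal(moments, 2 * (1:8), tolerance = 1e-6)
})

test_that("pooled consumption grants nearest-first and clips at availability", {
  f <- new_field("oxygen", c(9, 9, 9))
  f <- field_deposit(f, c(4, 4, 4), 10)
  res <- field_consume(f, c(4, 4, 4), 5)
  expect_equal(res$granted, 5)
  expect_equal(field_mass(res$field), 5)
  # available < requested: grant everything that is there
  res2 <- field_consume(res$field, c(4, 4, 4), 50)
  expect_equal(res2$granted, 5)
  expect_equal(field_mass(res2$field), 0)
  # empty centre, one neighbor holds 3: the pooled rule reaches it
  g <- new_field("oxygen", c(9, 9, 9))
  g <- field_deposit(g, c(5, 4, 4), 3)
  res3 <- field_consume(g, c(4, 4, 4), 5)
  expect_equal(res3$granted, 3)
  # nearest-first: the centre site is drained before any neighbor
  h <- new_field("oxygen", c(9, 9, 9))
  h <- field_deposit(h, c(4, 4, 4), 2)
  h <- field_deposit(h, c(5, 4, 4), 2)
  res4 <- field_consume(h, c(4, 4, 4), 2)
  expect_equal(res4$field$amounts[5, 5, 5], 0)
  expect_equal(res4$field$amounts[6, 5, 5], 2)
})

test_that("gradient steps climb ramps and break ties uniformly", {
  dims <- c(9, 9, 9)
  ramp <- new_field("fgf", dims)
  ramp$amounts <- array(rep(seq_len(9), times = 81), dim = dims)
  set.seed(5)
  for (k in 1:10) {
    step <- gradient_direction(ramp, c(4, 4, 4))
    expect_equal(step[1], 1)  # +x dominates on an x-ramp
  }
  # single maximal neighbor -> deterministic
  f <- new_field("vegf", dims)
  f <- field_deposit(f, c(5, 5, 4), 9)
  expect_equal(gradient_direction(f, c(4, 4, 4)), c(1L, 1L, 0L))
  # all-flat: uniform over the 26 directions (chi-squared at n = 5200)
  flat <- new_field("vegf", dims)
  set.seed(17)
  draws <- t(replicate(5200, gradient_direction(flat, c(4, 4, 4))))
  key <- paste(draws[, 1], draws[, 2], draws[, 3])
  tab <- table(key)
  expect_equal(length(tab), 26)
  chi <- sum((tab - 200)^2 / 200)
  expect_lt(chi, qchisq(0.999, df = 25))
})

test_that("the simulation mass ledger balances every species exactly", {
  sc <- scenario_preset("baseline", dims = c(21, 21, 21), seed = 2,
                        n_fibroblasts = 12,
                        params = sim_params(InitialVesselDistance = 8))
  s <- sim_init(sc)
  for (k in 1:4) {
    sim_step(s, 25)
    led <- sim_mass_ledger(s)
    bal <- led$initial + led$deposited - led$consumed - led$decayed
    expect_equal(bal, led$in_field, tolerance = 1e-9)
    expect_equal(led$tracked, led$in_field, tolerance = 1e-9)
    expect_true(all(led$in_field >= 0))
  }
})
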