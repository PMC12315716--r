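# small helper state: one replica, explicit barriers at chosen sites
mini_state <- function(n_sites = 100, extruders = 1, barriers = NULL,
                       leg_speed = 250, seed = 1) {
  cfg <- lattice_config(n_sites = n_sites, n_replicas = 1,
                        extruder_separation = n_sites %/% extruders,
                        tau_E = 1e9, leg_speed = leg_speed, seed = seed)
  if (is.null(barriers)) barriers <- random_layout(n_sites * 250, 0)
  extrusion_state(cfg, barriers, seed = seed)
}

place_extruder <- function(state, left, right) {
  state$extruders$left_leg[1] <- left
  state$extruders$right_leg[1] <- right
  state
}

test_that("a barrier with zero unbound time stays bound forever", {
  bar <- tibble::tibble(tau_b = 100, tau_u = 0, bound = TRUE)
  for (i in 1:50) bar <- step_barriers(bar, dt = 10)
  expect_true(bar$bound)
})

test_that("telegraph matches the exact discrete two-state stationary law", {
  # oracle: two-state chain with flip probs p = q = dt/tau has stationary
  # bound fraction q/(p+q) = 0.5, computed exactly from the chain
  p <- 0.4 / 4
  stationary <- p / (p + p)
  set.seed(99)
  res <- cpp_run_telegraph(rep(4, 50), rep(4, 50), rep(TRUE, 50),
                           dt = 0.4, n_updates = 20000)
  got <- mean(res$bound_fraction)
  se <- stats::sd(res$bound_fraction) / sqrt(50)
  expect_lt(abs(got - stationary), 4 * se)
  expect_gt(min(res$flips), 100)
})

test_that("invalid timesteps are rejected", {
  bar <- tibble::tibble(tau_b = 1, tau_u = 1, bound = TRUE)
  expect_error(step_barriers(bar, dt = 2), "invalid-timestep")
  expect_error(step_barriers(bar, dt = 0), "dt must be")
})

test_that("unimpeded legs grow the loop by two sites per update", {
  st <- mini_state()
  st <- place_extruder(st, 50L, 51L)
  set.seed(1)
  for (k in 1:10) st <- step_extruders(st, dt = 1)  # step prob = 250*1/250 = 1
  expect_equal(st$extruders$left_leg, 40L)
  expect_equal(st$extruders$right_leg, 61L)
})

test_that("a leg advances onto a bound blocking barrier and stalls there", {
  lay <- barrier_layout(tibble::tibble(
    chrom = "r", start = 60L * 250L, end = 61L * 250L, name = "b",
    score = 1, strand = "+", tau_b = 1e9, tau_u = 0))
  st <- mini_state(barriers = lay)
  st$barriers$bound <- TRUE
  st <- place_extruder(st, 50L, 51L)
  set.seed(2)
  for (k in 1:20) st <- step_extruders(st, dt = 1)
  expect_equal(st$extruders$right_leg, 60L)    # resting ON the barrier site
  expect_true(st$extruders$stalled_right)
  expect_equal(st$extruders$left_leg, 30L)     # left leg unimpeded
})

test_that("blocking is unidirectional: non-blocked direction passes freely", {
  # a '+' barrier blocks rightward legs; a leftward-moving leg crosses it
  lay <- barrier_layout(tibble::tibble(
    chrom = "r", start = 40L * 250L, end = 41L * 250L, name = "b",
    score = 1, strand = "+", tau_b = 1e9, tau_u = 0))
  st <- mini_state(barriers = lay)
  st$barriers$bound <- TRUE
  st <- place_extruder(st, 50L, 51L)
  set.seed(3)
  for (k in 1:20) st <- step_extruders(st, dt = 1)
  expect_equal(st$extruders$left_leg, 30L)     # passed through site 40
  expect_false(st$extruders$stalled_left)
})

test_that("facing legs of two extruders cannot bypass each other", {
  st <- mini_state(extruders = 2)
  st$extruders$left_leg <- c(10L, 51L)
  st$extruders$right_leg <- c(50L, 90L)
  set.seed(4)
  for (k in 1:5) st <- step_extruders(st, dt = 1)
  expect_equal(st$extruders$right_leg[1], 50L)
  expect_equal(st$extruders$left_leg[2], 51L)
  expect_equal(st$extruders$left_leg[1], 5L)   # outer legs keep moving
  expect_equal(st$extruders$right_leg[2], 95L)
})

test_that("recycling conserves extruder count and resets legs adjacently", {
  cfg <- lattice_config(n_sites = 1000, n_replicas = 1,
                        extruder_separation = 100, tau_E = 10, seed = 5)
  st <- extrusion_state(cfg, random_layout(250000, 0), seed = 5)
  set.seed(6)
  for (k in 1:50) st <- recycle_extruders(st, dt = 5)
  ex <- st$extruders
  expect_equal(nrow(ex), 10)
  expect_true(all(ex$right_leg - ex$left_leg >= 1))
  expect_true(all(ex$left_leg >= 0 & ex$right_leg < 1000))
})

test_that("steady-state loop sizes follow the exponential-lifetime law", {
  # lone extruder, no barriers: a sampled loop is leg_speed * 2 * age, and
  # the stationary age of an exponential renewal process is exponential
  # with mean tau_E, so the sampled mean loop is 2 * leg_speed * tau_E
  cfg <- lattice_config(n_sites = 40000, n_replicas = 4,
                        extruder_separation = 40000, tau_E = 1320,
                        leg_speed = 250, seed = 8)
  tr <- run_lattice(cfg, random_layout(1e7, 0), duration = 3 * 1320 + 52800,
                    sample_every = 40)
  loops <- (tr$right - tr$left) * 250
  expect_equal(mean(loops), 2 * 250 * 1320, tolerance = 0.2)
})

test_that("run_lattice is deterministic and validates duration", {
  cfg <- lattice_config(n_sites = 1000, n_replicas = 2,
                        extruder_separation = 500, tau_E = 200, seed = 9)
  lay <- random_layout(250000, 5, seed = 2)
  tr1 <- run_lattice(cfg, lay, duration = 2000, sample_every = 50)
  tr2 <- run_lattice(cfg, lay, duration = 2000, sample_every = 50)
  expect_identical(tr1$left, tr2$left)
  expect_identical(tr1$barrier_states, tr2$barrier_states)
  expect_error(run_lattice(cfg, lay, duration = 300, sample_every = 50),
               "empty-trace")
})

test_that("trace invariants hold: leg ranges, ordering, constant count", {
  cfg <- lattice_config(n_sites = 2000, n_replicas = 3,
                        extruder_separation = 400, tau_E = 300, seed = 10)
  lay <- random_layout(500000, 8, tau_b = 300, tau_u = 100, seed = 3)
  tr <- run_lattice(cfg, lay, duration = 9000, sample_every = 20)
  expect_true(all(tr$left >= 0 & tr$right < 2000 * 3))
  expect_true(all(tr$left <= tr$right))
  expect_equal(ncol(tr$left), 15)              # 5 per replica, 3 replicas
  # legs never cross replica boundaries
  expect_true(all((tr$left %/% 2000) == (tr$right %/% 2000)))
  # long-run bound fraction near the stationary law, pooled over barriers
  occ_hat <- colMeans(tr$barrier_states)
  expect_lt(abs(mean(occ_hat) - 0.75), 0.05)
  expect_true(all(abs(occ_hat - 0.75) < 0.35))
})

test_that("transient barriers leave near-uniform leg accumulation", {
  # tau_b far below tau_E: barrier-site occupancy close to background
  lay <- random_layout(2.5e5, 4, tau_b = 2, tau_u = 2, seed = 4)
  cfg <- lattice_config(n_sites = 1000, n_replicas = 2,
                        extruder_separation = 250, tau_E = 600,
                        dt_lattice = 0.2, seed = 11)
  tr <- run_lattice(cfg, lay, duration = 3 * 600 + 6000, sample_every = 5)
  track <- accumulate_track(tr)
  fr <- frip(track, barrier_sites(lay))
  control <- length(barrier_sites(lay)) / 1000
  expect_lt(fr, 3 * control)
})
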