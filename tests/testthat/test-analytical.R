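ref <- function(tau_b, tau_u, tau_E = 1320, delta = 87500, v = 500)
  regime_params(tau_E, tau_b, tau_u, delta, v)

test_that("regime classification follows the lifetime thresholds", {
  p <- ref(600, 100)
  t1 <- p$delta / p$v
  expect_equal(classify_regime(p, t1 / 2), "unimpeded")
  expect_equal(classify_regime(p, t1 + p$tau_b / 2), "blocked-capable")
  expect_equal(classify_regime(p, 2 * (t1 + p$tau_b)), "bypass-capable")
  expect_equal(classify_regime(p, c(t1 / 2, 2 * (t1 + p$tau_b))),
               c("unimpeded", "bypass-capable"))
  expect_error(classify_regime(p, 0), "lifetime_draw")
  expect_error(regime_params(1320, -1, 0, 87500, 500), "invalid parameters")
})

test_that("closed form recovers the limiting loop sizes", {
  # vanishing occupancy: unimpeded exponential mean v * tau_E
  expect_equal(expected_loop_size(ref(10, 1e12)), 500 * 1320,
               tolerance = 1e-6)
  # permanently bound barriers with v*tau_E = 100*delta: the barrier
  # spacing, up to the short-lifetime correction 1 - exp(-1/100)
  p <- regime_params(tau_E = 87500 * 100 / 500, tau_b = Inf, tau_u = 0,
                     delta = 87500, v = 500)
  expect_equal(expected_loop_size(p), 87500, tolerance = 0.01)
})

test_that("closed form matches the event-driven oracle across the grid", {
  tau_E <- 1320
  for (o in c(0.1, 0.5, 0.9)) {
    for (tau_b in c(tau_E / 10, tau_E, 10 * tau_E)) {
      p <- ref(tau_b, tau_b * (1 - o) / o)
      oc <- mc_loop_oracle(p, "midpoint", n_replicates = 3e4, seed = 17)
      expect_lt(abs(expected_loop_size(p) - oc$mean),
                max(0.05 * oc$mean, 4 * oc$se))
    }
  }
})

test_that("oracle is deterministic given a seed and exposes both loadings", {
  p <- ref(660, 660)
  a <- mc_loop_oracle(p, "midpoint", 2000, seed = 3)
  b <- mc_loop_oracle(p, "midpoint", 2000, seed = 3)
  expect_identical(a$mean, b$mean)
  u <- mc_loop_oracle(p, "uniform", 5000, seed = 3)
  expect_true(is.finite(u$mean) && u$mean > 0)
  expect_error(mc_loop_oracle(p, "midpoint", 10), "n_replicates")
})

test_that("transient barriers are effectively transparent to the oracle", {
  p <- ref(tau_b = 5, tau_u = 5)
  oc <- mc_loop_oracle(p, "midpoint", 2e4, seed = 11)
  expect_equal(oc$mean, 500 * 1320, tolerance = 0.05)
})

test_that("loop size is monotone in the barrier timescales", {
  tau_bs <- c(50, 200, 800, 3200, 12800)
  at_fixed_u <- vapply(tau_bs, function(b)
    expected_loop_size(ref(b, 300)), numeric(1))
  expect_true(all(diff(at_fixed_u) <= 0))
  tau_us <- c(10, 100, 1000, 10000)
  at_fixed_b <- vapply(tau_us, function(u)
    expected_loop_size(ref(800, u)), numeric(1))
  expect_true(all(diff(at_fixed_b) >= 0))
})

test_that("equal occupancy does not imply equal loop size near tau_b ~ tau_E", {
  # the model's central claim: kinetics matter beyond occupancy
  slow <- expected_loop_size(ref(1320, 1320))         # o = 0.5, tau_b = tau_E
  fast <- expected_loop_size(ref(132, 132))           # o = 0.5, tau_b = tau_E/10
  expect_gt(abs(slow - fast) / slow, 0.10)
})

test_that("static limit is linear in occupancy", {
  # tau_u >> tau_E with tau_b set by occupancy: loop size ~ affine in o
  occ <- seq(0.1, 0.9, by = 0.1)
  tau_u <- 1e7
  loops <- vapply(occ, function(o)
    expected_loop_size(ref(tau_u * o / (1 - o), tau_u)), numeric(1))
  fit <- stats::lm(loops ~ occ)
  expect_lt(max(abs(stats::resid(fit))) / diff(range(loops)), 0.02)
})

test_that("loop_size_grid sweeps the phase diagram with oracle columns", {
  g <- loop_size_grid(c(132, 1320), c(150, 1500), oracle_n = 2000, seed = 5)
  expect_equal(nrow(g), 4)
  expect_true(all(c("occupancy", "loop_bp", "oracle_bp", "oracle_se") %in%
                    names(g)))
  expect_true(all(abs(g$loop_bp - g$oracle_bp) / g$loop_bp < 0.15))
})
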