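test_that("legs map to monomers by integer coarse-graining", {
  expect_equal(nrow(legs_to_bonds(data.frame(left = 0L, right = 9L))), 0)
  b <- legs_to_bonds(data.frame(left = 5L, right = 4005L))
  expect_equal(c(b$monomer_i, b$monomer_j), c(0L, 400L))
  # reference scaling: 2.5 Mb at 250 bp/site, 2.5 kb monomers -> 1000 monomers
  expect_equal((10000 * 250) %/% 2500, 1000)
  expect_error(legs_to_bonds(data.frame(left = 1, right = 2),
                             site_bp = 250, monomer_bp = 300), "multiple")
})

test_that("advance_polymer is deterministic and preserves connectivity", {
  pc <- polymer_config()
  co <- init_conformation(200, seed = 1)
  a <- advance_polymer(co, NULL, pc, 500, seed = 2)
  b <- advance_polymer(co, NULL, pc, 500, seed = 2)
  expect_identical(a, b)
  bl <- sqrt(rowSums((a[-1, ] - a[-200, ])^2))
  expect_lt(max(bl), 2 * pc$bond_length + 2)
  expect_equal(mean(bl), 1, tolerance = 0.1)
})

test_that("an extruder bond holds its monomers near the rest length", {
  pc <- polymer_config()
  co <- init_conformation(300, seed = 3)
  bonds <- tibble::tibble(monomer_i = 20L, monomer_j = 250L)
  co <- advance_polymer(co, bonds, pc, 8000, seed = 4)
  bonded <- sqrt(sum((co[21, ] - co[251, ])^2))
  free <- advance_polymer(init_conformation(300, seed = 3), NULL, pc, 8000,
                          seed = 4)
  unbonded <- sqrt(sum((free[21, ] - free[251, ])^2))
  expect_lt(bonded, 2)
  expect_gt(unbonded, 3 * bonded)
})

test_that("ideal chain internal distances scale linearly in separation", {
  pc <- polymer_config(excluded_volume_strength = 0)
  co <- advance_polymer(init_conformation(300, seed = 5), NULL, pc, 20000,
                        seed = 6)
  msd <- function(s) mean(rowSums((co[seq_len(300 - s), ] -
                                     co[s + seq_len(300 - s), ])^2))
  ratios <- vapply(c(5, 20, 60), function(s) msd(s) / s, numeric(1))
  expect_lt(max(ratios) / min(ratios), 1.45)
})

test_that("radius of gyration grows with a coil-like exponent", {
  pc <- polymer_config()
  rg <- function(n, seeds) mean(vapply(seeds, function(s) {
    co <- advance_polymer(init_conformation(n, seed = s), NULL, pc,
                          40000, seed = s + 100)
    sqrt(mean(rowSums(sweep(co, 2, colMeans(co))^2)))
  }, numeric(1)))
  r_small <- rg(64, 1:3)
  r_large <- rg(256, 1:3)
  nu <- log(r_large / r_small) / log(4)
  expect_gt(nu, 0.4)
  expect_lt(nu, 0.75)
})

test_that("capture_contacts finds exactly the close non-neighbour pairs", {
  rod <- cbind(3 * (0:49), 0, 0)                     # spacing > radius
  expect_equal(nrow(capture_contacts(rod, 2)), 0)
  point <- matrix(0, 10, 3)
  expect_equal(nrow(capture_contacts(point, 2)), choose(10, 2) - 9)
  ring <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6), 0)
  got <- capture_contacts(ring, 1.3)
  expect_true(all(got$monomer_j - got$monomer_i >= 2))
})

test_that("contact frequency decays with genomic distance", {
  pc <- polymer_config()
  co <- advance_polymer(init_conformation(400, seed = 7), NULL, pc, 15000,
                        seed = 8)
  contacts <- capture_contacts(co, 2)
  sep <- contacts$monomer_j - contacts$monomer_i
  counts <- vapply(list(2:5, 6:20, 21:80, 81:399),
                   function(rng) sum(sep %in% rng) / length(rng), numeric(1))
  expect_true(all(diff(counts) < 0))
})

test_that("aggregate_map bins symmetrically and linearly", {
  conf <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0), c(10.5, 0, 0))
  # monomers 1 and 3 (0-based) are 0.5 apart -> one contact, bins 1 and 2
  m1 <- aggregate_map(list(conf), resolution = 5000, monomer_bp = 2500,
                      capture_radius = 2)
  expect_equal(m1$matrix[1, 2], 1)
  expect_equal(m1$matrix[2, 1], 1)
  m2 <- aggregate_map(list(conf, conf), resolution = 5000,
                      monomer_bp = 2500, capture_radius = 2)
  expect_equal(m2$matrix, 2 * m1$matrix)
  expect_true(isSymmetric(m1$matrix))
  one <- matrix(0, 30, 30); one[11, 21] <- one[21, 11] <- 1
  cm <- new_contact_map(one, 10000)
  expect_equal(tidy(cm)$count[tidy(cm)$start_i == 1e5 &
                                tidy(cm)$start_j == 2e5], 1)
})

test_that("run_polymer couples bonds to lattice frames exactly", {
  lay <- convergent_pair(50000, 250000, tau_b = 1e9, tau_u = 0)
  cfg <- lattice_config(n_sites = 1000, n_replicas = 2,
                        extruder_separation = 500, tau_E = 500, seed = 41)
  tr <- run_lattice(cfg, lay, duration = 1800, sample_every = 60)
  ens <- run_polymer(tr, polymer_config(init_steps = 200,
                                        steps_per_frame = 50), replicas = 1)
  expect_equal(ens$n_monomers, 100)
  expect_equal(ens$n_frames, length(tr$times))
  # frame t bonds == coarse-grained legs of replica 1 at frame t
  per_rep <- tr$n_extruders / 2
  for (f in c(1, ens$n_frames)) {
    legs <- data.frame(left = tr$left[f, 1:per_rep],
                       right = tr$right[f, 1:per_rep])
    expect_equal(ens$bonds[[f]], legs_to_bonds(legs, 250, 2500))
  }
  # determinism of the full coupled pipeline
  ens2 <- run_polymer(tr, polymer_config(init_steps = 200,
                                         steps_per_frame = 50), replicas = 1)
  expect_identical(ens$contact_counts, ens2$contact_counts)
  expect_error(run_polymer(tr, polymer_config(), replicas = c(1, 3)),
               "contiguous")
})
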