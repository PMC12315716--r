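uniform_map <- function(n = 60, value = 3, resolution = 10000)
  new_contact_map(matrix(value, n, n), resolution)

test_that("insulation is 1 on uniform and distance-only maps", {
  expect_equal(insulation_score(uniform_map(), c(20L, 30L)), 1)
  # distance-only decay: congruent triangles cancel it exactly
  n <- 60
  decay <- outer(1:n, 1:n, function(i, j) 100 / (1 + abs(i - j))^1.5)
  expect_equal(insulation_score(new_contact_map(decay, 1e4), c(20L, 35L)), 1,
               tolerance = 1e-10)
})

test_that("insulation equals the within/between region mean ratio", {
  set.seed(8)
  n <- 50
  m <- matrix(runif(n * n, 1, 5), n, n); m <- (m + t(m)) / 2
  map <- new_contact_map(m, 1e4)
  b <- 25L; w <- 5L
  # independent re-derivation of the three congruent triangles
  tri_mean <- function(lo) {
    vals <- c()
    for (i in lo:(lo + w)) for (j in lo:(lo + w))
      if (j - i >= 2) vals <- c(vals, m[i, j])
    mean(vals)
  }
  manual <- mean(c(tri_mean(b - w), tri_mean(b))) / tri_mean(b - 3L)
  expect_equal(insulation_score(map, b), manual)
})

test_that("insulation responds to a block-TAD map and flags empty regions", {
  n <- 40; b <- 20L
  m <- matrix(1, n, n)
  m[1:b, 1:b] <- 4; m[(b + 1):n, (b + 1):n] <- 4   # two TADs, weak between
  map <- new_contact_map(m, 1e4)
  expect_gt(insulation_score(map, b), 1.5)
  zero <- new_contact_map(matrix(0, n, n), 1e4)
  expect_warning(res <- insulation_score(zero, c(b, 10L), per_barrier = TRUE),
                 "excluded")
  expect_true(all(is.na(res$insulation)))
  expect_error(insulation_score(map, c(2L)), "margins")
  expect_error(insulation_score(map, b, window = 33333), "multiple")
})

test_that("dot profile scores center over corner controls", {
  n <- 120
  m <- matrix(2, n, n)
  pair <- tibble::tibble(bin_i = 40L, bin_j = 70L)   # 300 kb apart
  m[40, 70] <- m[70, 40] <- 10                       # 5x the corners
  prof <- dot_profile(new_contact_map(m, 1e4), pair)
  expect_s3_class(prof, "dot_profile")
  expect_equal(sum(prof$n_snippets), 1)
  expect_equal(prof$score[prof$n_snippets > 0], 5)
  # uniform map scores 1 in every populated bin
  prs <- tibble::tibble(bin_i = c(30L, 20L, 50L), bin_j = c(60L, 80L, 95L))
  pu <- dot_profile(uniform_map(120), prs)
  expect_true(all(abs(pu$score[pu$n_snippets > 0] - 1) < 1e-12))
  expect_equal(sum(pu$n_snippets), 3)
})

test_that("a uniform stripe through the anchor does not inflate the score", {
  # broad enriched band through the anchor row: the corner controls lie on
  # the same band, so the local-background ratio stays at 1 (a global
  # background would report 6)
  n <- 120
  m <- matrix(1, n, n)
  m[36:44, ] <- 6
  m <- pmax(m, t(m))
  prof <- dot_profile(new_contact_map(m, 1e4),
                      tibble::tibble(bin_i = 40L, bin_j = 70L))
  expect_equal(prof$score[prof$n_snippets > 0], 1, tolerance = 1e-12)
})

test_that("dot scores are invariant under uniform map rescaling", {
  set.seed(9)
  n <- 150
  m <- matrix(rpois(n * n, 4) + 1, n, n); m <- m + t(m)
  prs <- tibble::tibble(bin_i = c(30L, 60L), bin_j = c(55L, 120L))
  p1 <- dot_profile(new_contact_map(m, 1e4), prs)
  p2 <- dot_profile(new_contact_map(7 * m, 1e4), prs)
  expect_equal(p1$score, p2$score)
  b <- c(40L, 100L)
  expect_equal(insulation_score(new_contact_map(m, 1e4), b),
               insulation_score(new_contact_map(7 * m, 1e4), b))
})

test_that("mean dot score is the snippet-count-weighted mean", {
  prof <- structure(tibble::tibble(
    bin = 1:3, d_lo = c(1, 2, 4) * 1e5, d_hi = c(2, 4, 8) * 1e5,
    d_mid = c(1.4, 2.8, 5.6) * 1e5,
    n_snippets = c(1L, 3L, 0L), score = c(1, 3, NA)),
    class = c("dot_profile", "tbl_df", "tbl", "data.frame"))
  expect_equal(mean_dot_score(prof), 2.5)
  single <- prof; single$n_snippets <- c(2L, 0L, 0L)
  expect_equal(mean_dot_score(single), 1)
  none <- prof; none$n_snippets <- 0L
  expect_error(mean_dot_score(none), "empty")
})

test_that("distance bins are geometric, right-open, and count snippets", {
  prof <- dot_profile(uniform_map(600), tibble::tibble(bin_i = 1L, bin_j = 2L))
  expect_equal(nrow(prof), 25)
  expect_true(all(diff(prof$d_lo) > 0))
  expect_equal(prof$d_lo[1], 1e5)
  expect_equal(prof$d_hi[25], 5e6)
  ratios <- prof$d_hi / prof$d_lo
  expect_lt(diff(range(ratios)), 1e-6)
  # a pair exactly at the lower edge lands in bin 1
  at_edge <- dot_profile(uniform_map(600),
                         tibble::tibble(bin_i = 100L, bin_j = 110L))
  expect_equal(at_edge$n_snippets[1], 1L)
})

test_that("vermicelli score separates identical, independent and axial fields", {
  coil <- morphology_fixture("coil", 400, seed = 5)
  # extruders = every monomer: the two fields coincide
  expect_equal(vermicelli_score(coil$coords, 0:399), 1)
  # extruder positions far outside the chromatin support: near zero
  far <- rbind(coil$coords, matrix(rnorm(60, mean = 300, sd = 2), 20, 3))
  expect_lt(abs(vermicelli_score(far, 400:419)), 0.2)
  expect_error(vermicelli_score(coil$coords, integer(0)), "extruder")
  expect_error(vermicelli_score(coil$coords[0, , drop = FALSE], 0L), "empty")
})

test_that("axial morphology outscores a random coil by a clear margin", {
  axial <- morphology_fixture("axial", 500, seed = 11)
  coil <- morphology_fixture("coil", 500, seed = 11)
  s_axial <- vermicelli_score(axial$coords, axial$extruder_monomers)
  s_coil <- vermicelli_score(coil$coords, coil$extruder_monomers)
  expect_gt(s_axial - s_coil, 0.3)
  # fixtures are pure functions of their seed
  again <- morphology_fixture("axial", 500, seed = 11)
  expect_identical(axial, again)
  expect_error(morphology_fixture("coil", 50), ">= 100")
})
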