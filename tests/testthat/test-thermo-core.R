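test_that("solution mole fraction follows the mole balance", {
  expect_equal(solution_mole_fraction(0, 136, 11974), 136 / 12110)
  expect_equal(solution_mole_fraction(75, 136, 11974), 61 / 12035)
  expect_equal(solution_mole_fraction(136, 136, 11974), 0)
  n <- seq(0, 136, by = 1)
  x <- solution_mole_fraction(n, 136, 11974)
  expect_true(all(diff(x) < 0))
  expect_error(solution_mole_fraction(-1, 136, 11974), "n_xtal")
  expect_error(solution_mole_fraction(137, 136, 11974), "n_xtal")
})

test_that("confined free energy is zero at n = 0 and rejects full depletion", {
  for (i in 1:5) {
    cs <- random_case()
    expect_identical(
      confined_free_energy(0, cs$n_tot, cs$n_tot_s, cs$x_star, cs$sigma_prime),
      0
    )
  }
  expect_error(
    confined_free_energy(136, 136, 11974, 2.7e-3, 4.8),
    "n_xtal"
  )
})

test_that("undersaturated compositions give a strictly increasing profile", {
  x_star <- 5e-3
  n_tot <- 100
  n_tot_s <- round(n_tot / (x_star / 2) - n_tot)  # x0 = x*/2
  prof <- free_energy_profile(n_tot, n_tot_s, x_star, 5)
  expect_true(all(diff(prof$beta_dF) > 0))
  st <- stationary_points(n_tot, n_tot_s, x_star, 5)
  expect_true(is.na(st$n_crit) && is.na(st$n_ss))
})

test_that("analytic gradient agrees with central finite differences", {
  set.seed(11)
  for (i in 1:100) {
    cs <- random_case()
    n <- exp(seq(log(0.5), log(cs$n_tot * 0.95), length.out = 7))
    g_an <- confined_free_energy_gradient(n, cs$n_tot, cs$n_tot_s,
                                          cs$x_star, cs$sigma_prime)
    g_fd <- fd_gradient(n, cs$n_tot, cs$n_tot_s, cs$x_star, cs$sigma_prime)
    expect_lt(max(abs(g_an - g_fd) / pmax(abs(g_an), 1e-3)), 1e-6)
  }
})

test_that("stationary points bracket a maximum before a minimum", {
  st <- stationary_points(316, 19348, 2.731e-3, 4.81)
  expect_false(is.na(st$n_ss))
  expect_false(is.na(st$n_crit))
  expect_lt(st$n_crit, st$n_ss)
  # Table 1 beta row 4 relaxed to 238 molecules; the minimum under the
  # printed parameters should sit within 15% of that
  expect_lt(abs(st$n_ss - 238) / 238, 0.15)
  # gradient vanishes at both roots
  g <- confined_free_energy_gradient(c(st$n_crit, st$n_ss),
                                     316, 19348, 2.731e-3, 4.81)
  expect_lt(max(abs(g)), 1e-6)
  # and the labels are right: curvature up at the minimum, down at the max
  h <- 1e-3
  curv <- function(n) {
    (confined_free_energy(n + h, 316, 19348, 2.731e-3, 4.81) -
       2 * confined_free_energy(n, 316, 19348, 2.731e-3, 4.81) +
       confined_free_energy(n - h, 316, 19348, 2.731e-3, 4.81)) / h^2
  }
  expect_lt(curv(st$n_crit), 0)
  expect_gt(curv(st$n_ss), 0)
})

test_that("gradient changes sign twice for a supersaturated confined box", {
  grid <- seq(1, 315, length.out = 2000)
  g <- confined_free_energy_gradient(grid, 316, 19348, 2.731e-3, 4.81)
  expect_gte(sum(diff(sign(g)) != 0), 2)
})

test_that("confined profile converges to the macroscopic profile in large boxes", {
  x_star <- 2.731e-3
  sigma <- 4.81
  x0 <- 2 * x_star
  n_tot <- 1e7
  n_tot_s <- n_tot * (1 - x0) / x0
  # depletion bias scales as n^2 / (2 n_tot), so agreement to 1e-3 kBT holds
  # for clusters up to ~100 molecules at this box size ...
  n <- seq(1, 100, length.out = 100)
  conf <- confined_free_energy(n, n_tot, n_tot_s, x_star, sigma)
  macro <- macroscopic_free_energy(n, S = 2, sigma_prime = sigma)
  expect_lt(max(abs(conf - macro)), 1e-3)
  # ... and shrinks ~10x for a 10x larger box
  conf10 <- confined_free_energy(n, 1e8, 1e8 * (1 - x0) / x0, x_star, sigma)
  expect_lt(max(abs(conf10 - macro)), 1.2e-4)
  # and the confined critical size approaches the closed form
  st <- stationary_points(n_tot, n_tot_s, x_star, sigma)
  expect_equal(st$n_crit, critical_size_macroscopic(2, sigma),
               tolerance = 1e-3)
})

test_that("macroscopic profile: reference state, zero driving force, barrier", {
  expect_identical(macroscopic_free_energy(0, 2, 5), 0)
  n <- seq(0, 1e4, length.out = 500)
  expect_true(all(diff(macroscopic_free_energy(n, 1, 5)) > 0))
  expect_error(macroscopic_free_energy(10, -1, 5), "S")
})

test_that("critical size follows the closed form and is decreasing in S", {
  expect_equal(critical_size_macroscopic(exp(1), 3), 8)
  # grid-search cross-check
  n <- seq(0.01, 100, by = 0.01)
  n_grid <- n[which.max(macroscopic_free_energy(n, exp(1), 3))]
  expect_equal(n_grid, 8, tolerance = 1e-2)
  S <- c(1.2, 1.5, 2, 3, 10)
  expect_true(all(diff(critical_size_macroscopic(S, 3)) < 0))
  expect_error(critical_size_macroscopic(1, 3), "exceed 1")
})

test_that("CNT barrier matches its profile maximum and scales as 1/ln^2 S", {
  curve <- solubility_curve_params(2.731e-3, 298, 33.9)
  sigma <- 4.81
  x <- 2 * solubility_at(298, curve)
  b <- cnt_barrier(x, 298, curve, sigma)
  # independent grid-search oracle on the macroscopic profile
  S <- x / solubility_at(298, curve)
  nstar <- critical_size_macroscopic(S, sigma)
  expect_equal(b, macroscopic_free_energy(nstar, S, sigma), tolerance = 1e-12)
  # doubling ln S quarters the barrier
  x2 <- solubility_at(298, curve) * S^2
  expect_equal(cnt_barrier(x2, 298, curve, sigma), b / 4)
  # divergence approaching saturation
  eps <- 10^seq(-2, -6, by = -1)
  bseq <- cnt_barrier(solubility_at(298, curve) * (1 + eps), 298, curve, sigma)
  expect_true(all(diff(bseq) > 0))
  expect_gt(max(bseq), 1e6)
  expect_error(cnt_barrier(solubility_at(298, curve), 298, curve, sigma),
               "saturation")
})
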