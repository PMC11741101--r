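#' Solute mole fraction coupled to the crystal size
#'
#' In a closed simulation box the solution composition is slaved to the size
#' of the crystalline nucleus: every molecule that joins the crystal leaves
#' the solution. With `n_tot` solute and `n_tot_s` solvent molecules in the
#' box and `n_xtal` molecules in the crystal, the mole fraction of solute
#' remaining in solution is
#' \deqn{x(n) = \frac{n_{tot} - n}{(n_{tot} - n) + n^s_{tot}}.}
#'
#' @param n_xtal Crystal size, in molecules. May be non-integer (the
#'   thermodynamic model treats the cluster size as continuous). Vectorised.
#' @param n_tot Total number of solute molecules in the box.
#' @param n_tot_s Total number of solvent molecules in the box.
#'
#' @return Numeric vector of mole fractions, strictly decreasing in `n_xtal`,
#'   equal to the nominal composition `x0` at `n_xtal = 0` and to 0 at full
#'   depletion `n_xtal = n_tot`.
#' @examples
#' solution_mole_fraction(0, n_tot = 136, n_tot_s = 11974)
#' solution_mole_fraction(75, n_tot = 136, n_tot_s = 11974)
#' @export
solution_mole_fraction <- function(n_xtal, n_tot, n_tot_s) {
  check_composition(n_tot, n_tot_s)
  if (any(n_xtal < 0 | n_xtal > n_tot)) {
    abort("`n_xtal` must lie in [0, n_tot].")
  }
  (n_tot - n_xtal) / ((n_tot - n_xtal) + n_tot_s)
}

# The thermodynamic layer treats both counts as continuous positive
# quantities (phase maps scan composition continuously); integer counts are
# enforced only at the observation-table boundary.
check_composition <- function(n_tot, n_tot_s) {
  if (any(!is.finite(n_tot)) || any(n_tot <= 0)) {
    abort("`n_tot` must be a positive, finite count.")
  }
  if (any(!is.finite(n_tot_s)) || any(n_tot_s <= 0)) {
    abort("`n_tot_s` must be a positive, finite count.")
  }
  invisible(TRUE)
}

check_params <- function(x_star, sigma_prime) {
  if (!is.finite(x_star) || x_star <= 0 || x_star >= 1) {
    abort("`x_star` must lie in (0, 1).")
  }
  if (!is.finite(sigma_prime) || sigma_prime <= 0) {
    abort("`sigma_prime` must be positive.")
  }
  invisible(TRUE)
}

#' Nucleation free energy of a crystal in a confined solution
#'
#' Free energy (in units of \eqn{k_B T}) of a crystalline nucleus of size
#' `n_xtal` in a closed, thermostated box, relative to the fully dissolved
#' state. The driving-force term accounts for the depletion of the solution
#' as the nucleus grows; with all activity-coefficient ratios taken as unity
#' (the dilute-solution simplification adopted throughout) it reads
#' \deqn{\beta\Delta F(n) = n \ln x^* + (n_{tot}-n)\ln x(n) - n_{tot}\ln x_0
#'   + n^s_{tot} \ln\frac{1 - x(n)}{1 - x_0} + \sigma' n^{2/3},}
#' where \eqn{x(n)} is [solution_mole_fraction()], \eqn{x_0 = x(0)}, and
#' \eqn{\sigma'} is the effective surface energy of a quasi-spherical
#' nucleus. Its derivative in `n` reduces to
#' \eqn{-\ln(x(n)/x^*) + (2/3)\sigma' n^{-1/3}}, so in the macroscopic limit
#' (`n_tot`, `n_tot_s` to infinity at fixed \eqn{x_0}) the profile tends to
#' the classical \eqn{-n \ln S + \sigma' n^{2/3}} form
#' ([macroscopic_free_energy()]).
#'
#' For supersaturated compositions that are not too strongly confined the
#' profile has two stationary points: a maximum (the critical nucleus) and,
#' unlike the macroscopic profile, a minimum where the nucleus coexists with
#' the depleted solution. That minimum is the steady-state cluster size that
#' seeded simulations relax to.
#'
#' @inheritParams solution_mole_fraction
#' @param x_star Equilibrium (saturation) solute mole fraction, in (0, 1).
#' @param sigma_prime Effective surface energy, in units of \eqn{k_B T}
#'   (multiplies \eqn{n^{2/3}}).
#'
#' @return Numeric vector, \eqn{\beta\Delta F(n_{xtal})} in \eqn{k_B T};
#'   exactly 0 at `n_xtal = 0`.
#' @seealso [confined_free_energy_gradient()], [stationary_points()],
#'   [free_energy_profile()]
#' @examples
#' confined_free_energy(75, n_tot = 136, n_tot_s = 11974,
#'                      x_star = 2.731e-3, sigma_prime = 4.81)
#' @export
confined_free_energy <- function(n_xtal, n_tot, n_tot_s, x_star, sigma_prime) {
  check_composition(n_tot, n_tot_s)
  check_params(x_star, sigma_prime)
  if (any(n_xtal < 0 | n_xtal >= n_tot)) {
    abort("`n_xtal` must lie in [0, n_tot).")
  }
  x <- solution_mole_fraction(n_xtal, n_tot, n_tot_s)
  if (any(x == 0)) {
    abort("x(n_xtal) = 0: the solution branch of the free energy involves ln x(n), which is undefined at full depletion.")
  }
  x0 <- n_tot / (n_tot + n_tot_s)
  n_xtal * log(x_star) + (n_tot - n_xtal) * log(x) - n_tot * log(x0) +
    n_tot_s * log((1 - x) / (1 - x0)) + sigma_prime * n_xtal^(2 / 3)
}

#' Derivative of the confined nucleation free energy
#'
#' Analytic derivative of [confined_free_energy()] with respect to the
#' crystal size. The ideal-mixing bookkeeping terms cancel exactly, leaving
#' \deqn{\frac{d\,\beta\Delta F}{dn} = -\ln\frac{x(n)}{x^*}
#'   + \frac{2}{3}\sigma' n^{-1/3},}
#' i.e. the macroscopic gradient evaluated at the instantaneous (depleted)
#' solution composition. Zeros of this function are the stationary points of
#' the profile, and its value at an observed steady-state size is the
#' residual entering the least-squares estimation of
#' \eqn{(x^*, \sigma')} in [fit_thermo_params()].
#'
#' @inheritParams confined_free_energy
#' @return Numeric vector, \eqn{k_B T} per molecule.
#' @export
confined_free_energy_gradient <- function(n_xtal, n_tot, n_tot_s, x_star,
                                          sigma_prime) {
  check_composition(n_tot, n_tot_s)
  check_params(x_star, sigma_prime)
  if (any(n_xtal <= 0 | n_xtal >= n_tot)) {
    abort("`n_xtal` must lie strictly inside (0, n_tot); the gradient is singular at the boundaries.")
  }
  x <- solution_mole_fraction(n_xtal, n_tot, n_tot_s)
  -log(x / x_star) + (2 / 3) * sigma_prime * n_xtal^(-1 / 3)
}

#' Tabulate a confined free-energy profile
#'
#' Convenience wrapper evaluating [confined_free_energy()] on a grid,
#' suitable for plotting or CSV export.
#'
#' @inheritParams confined_free_energy
#' @param n_grid Crystal sizes at which to evaluate the profile. Defaults to
#'   512 points spanning `[0, n_tot)`.
#' @return A tibble with columns `n_xtal` and `beta_dF`.
#' @export
free_energy_profile <- function(n_tot, n_tot_s, x_star, sigma_prime,
                                n_grid = NULL) {
  if (is.null(n_grid)) {
    n_grid <- seq(0, n_tot * (1 - 1e-9), length.out = 512)
  }
  if (is.unsorted(n_grid, strictly = TRUE)) {
    abort("`n_grid` must be strictly increasing.")
  }
  tibble(
    n_xtal = n_grid,
    beta_dF = confined_free_energy(n_grid, n_tot, n_tot_s, x_star, sigma_prime)
  )
}

# Bracketing grid for gradient sign changes: a dense linear grid plus a
# log-spaced refinement so stationary points at n << n_tot are not missed in
# very large boxes.
stationary_grid <- function(n_tot, n_points = 2048) {
  hi <- n_tot * (1 - 1e-9)
  lo <- min(1e-4, hi * 1e-9)
  sort(unique(c(
    seq(lo, hi, length.out = n_points),
    exp(seq(log(lo), log(hi), length.out = 512))
  )))
}

#' Stationary points of the confined free-energy profile
#'
#' Locates the zeros of [confined_free_energy_gradient()] by scanning a dense
#' bracketing grid on `(0, n_tot)` for sign changes and refining each bracket
#' by root bisection. A downward zero-crossing of the gradient (+ to -) is a
#' maximum of the profile (the critical nucleus in confinement); an upward
#' crossing (- to +) is the stable minimum (the steady-state cluster).
#' Undersaturated compositions, or supersaturated ones so small that
#' depletion erases the minimum, return `NA` for the missing points.
#'
#' @inheritParams confined_free_energy
#' @param n_points Number of points of the linear bracketing grid.
#' @param tol Absolute tolerance on the root location, in molecules.
#' @return A one-row tibble with columns `n_crit` (maximum) and `n_ss`
#'   (minimum), `NA_real_` where absent. When both exist, `n_crit < n_ss`.
#' @examples
#' stationary_points(n_tot = 316, n_tot_s = 19348,
#'                   x_star = 2.731e-3, sigma_prime = 4.81)
#' @export
stationary_points <- function(n_tot, n_tot_s, x_star, sigma_prime,
                              n_points = 2048, tol = 1e-8) {
  check_composition(n_tot, n_tot_s)
  check_params(x_star, sigma_prime)
  g <- function(n) {
    confined_free_energy_gradient(n, n_tot, n_tot_s, x_star, sigma_prime)
  }
  grid <- stationary_grid(n_tot, n_points)
  gv <- g(grid)
  cross <- which(gv[-length(gv)] * gv[-1] < 0)
  n_crit <- NA_real_
  n_ss <- NA_real_
  for (i in cross) {
    root <- uniroot(g, lower = grid[i], upper = grid[i + 1], tol = tol)$root
    if (gv[i] > 0 && is.na(n_crit)) n_crit <- root       # maximum
    if (gv[i] < 0 && is.na(n_ss)) n_ss <- root           # minimum
  }
  # exact zeros on grid points are vanishingly unlikely but would be skipped
  tibble(n_crit = n_crit, n_ss = n_ss)
}

#' Macroscopic (classical) nucleation free energy
#'
#' Free-energy profile of a nucleus in an infinite reservoir at fixed
#' supersaturation \eqn{S = x/x^*}:
#' \deqn{\beta\Delta F^\infty(n) = -n \ln S + \sigma' n^{2/3}.}
#' This is the large-system limit of [confined_free_energy()] at fixed
#' nominal composition.
#'
#' @param n Nucleus size, molecules (vectorised, `n >= 0`).
#' @param S Supersaturation ratio `x / x_star`, must be positive.
#' @inheritParams confined_free_energy
#' @return Numeric vector, \eqn{k_B T}.
#' @export
macroscopic_free_energy <- function(n, S, sigma_prime) {
  if (any(!is.finite(S)) || any(S <= 0)) abort("`S` must be positive.")
  if (any(n < 0)) abort("`n` must be non-negative.")
  -n * log(S) + sigma_prime * n^(2 / 3)
}

#' Critical nucleus size in macroscopic conditions
#'
#' Maximiser of [macroscopic_free_energy()]; for the \eqn{n^{2/3}} surface
#' law the closed form is \eqn{n^* = (2\sigma'/(3\ln S))^3}.
#'
#' @inheritParams macroscopic_free_energy
#' @return Critical size in molecules.
#' @export
critical_size_macroscopic <- function(S, sigma_prime) {
  if (any(!is.finite(S)) || any(S <= 1)) {
    abort("`S` must exceed 1: no critical nucleus exists at or below saturation.")
  }
  (2 * sigma_prime / (3 * log(S)))^3
}

#' Classical nucleation barrier at given composition and temperature
#'
#' Height of the macroscopic free-energy profile at its critical size, for a
#' solution of mole fraction `x` at temperature `T` whose saturation
#' composition follows the Van't Hoff curve `curve`:
#' \deqn{\beta\Delta F^*(x, T) = \frac{4}{27}\,
#'   \frac{\sigma'^3}{\ln^2\!\big(x / x^*(T)\big)}.}
#' The barrier diverges as the composition approaches the solubility line
#' and decreases monotonically with supersaturation. The solid-liquid
#' surface energy is assumed temperature-independent.
#'
#' @param x Solute mole fraction of the solution (vectorised).
#' @param T_K Temperature, Kelvin.
#' @param curve A [solubility_curve_params()] object giving \eqn{x^*(T)}.
#' @inheritParams confined_free_energy
#' @return Barrier height in \eqn{k_B T}.
#' @export
cnt_barrier <- function(x, T_K, curve, sigma_prime) {
  xs <- solubility_at(T_K, curve)
  if (any(x <= xs)) {
    abort("no barrier below saturation: `x` must exceed x*(T).")
  }
  (4 / 27) * sigma_prime^3 / log(x / xs)^2
}
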