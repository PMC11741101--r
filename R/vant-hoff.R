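#' Parameters of a Van't Hoff solubility curve
#'
#' Bundles the three quantities defining a solubility curve
#' \deqn{\ln x^*(T) = \ln x^*(T_{ref})
#'   - \frac{\Delta H_{diss}}{R}\Big(\frac{1}{T} - \frac{1}{T_{ref}}\Big):}
#' the solubility at a reference temperature, that temperature, and the
#' dissolution enthalpy. The form follows from the Gibbs-Konovalev treatment
#' of solid-liquid equilibrium and assumes only that the activity
#' coefficients and \eqn{\Delta H_{diss}} are constant over the temperature
#' range, not that the solution is ideal.
#'
#' @param x_ref Solubility (mole fraction) at `T_ref`, in (0, 1).
#' @param T_ref Reference temperature, Kelvin.
#' @param dH_diss Dissolution enthalpy, kJ/mol (enthalpy of transferring one
#'   mole of solute from the crystal to an infinitely dilute solution).
#' @return An object of class `solubility_curve`.
#' @examples
#' beta_md <- solubility_curve_params(2.731e-3, 298, 33.9)
#' solubility_at(290, beta_md)
#' @export
solubility_curve_params <- function(x_ref, T_ref, dH_diss) {
  if (!is.finite(x_ref) || x_ref <= 0 || x_ref >= 1) {
    abort("`x_ref` must lie in (0, 1).")
  }
  if (!is.finite(T_ref) || T_ref <= 0) abort("`T_ref` must be positive (Kelvin).")
  if (!is.finite(dH_diss)) abort("`dH_diss` must be a finite number (kJ/mol).")
  structure(
    list(x_ref = x_ref, T_ref = T_ref, dH_diss = dH_diss),
    class = "solubility_curve"
  )
}

#' @export
print.solubility_curve <- function(x, ...) {
  cat(sprintf(
    "<solubility_curve> x* = %.4g at T_ref = %g K, dH_diss = %.4g kJ/mol\n",
    x$x_ref, x$T_ref, x$dH_diss
  ))
  invisible(x)
}

#' Solubility at a temperature from a Van't Hoff curve
#'
#' Evaluates the curve defined by [solubility_curve_params()]. Returns
#' `x_ref` exactly at `T = T_ref` and is increasing in `T` whenever
#' `dH_diss > 0`.
#'
#' @param T_K Temperature(s), Kelvin.
#' @param curve A `solubility_curve` object.
#' @return Mole fraction(s).
#' @export
solubility_at <- function(T_K, curve) {
  stopifnot(inherits(curve, "solubility_curve"))
  if (any(!is.finite(T_K)) || any(T_K <= 0)) abort("`T_K` must be positive (Kelvin).")
  curve$x_ref * exp(-(curve$dH_diss / .R_KJ) * (1 / T_K - 1 / curve$T_ref))
}

#' Tabulate a solubility curve over a temperature grid
#'
#' @param curve A `solubility_curve` object.
#' @param T_grid Temperatures, Kelvin. Default 273-343 K in 1 K steps, the
#'   experimentally accessible aqueous range.
#' @return A tibble with columns `T_K` and `x_star`.
#' @export
solubility_curve <- function(curve, T_grid = seq(273, 343, by = 1)) {
  tibble(T_K = T_grid, x_star = solubility_at(T_grid, curve))
}

#' Dissolution enthalpy from bulk-phase potential energies
#'
#' Combines the total potential energies of three equilibrium simulations -
#' a bulk crystal, a pure-solvent box, and a single solute molecule in the
#' same solvent (approximating infinite dilution) - into the enthalpy of
#' transferring one mole of solute from the crystal to an infinitely dilute
#' solution:
#' \deqn{\Delta H_{diss} = \Big(U^\infty_{sol}
#'   - \frac{N^\infty_{solv}}{N_{solv}} U_{solv}\Big)
#'   - \frac{U_{xtal}}{N_{xtal}}.}
#' The bracket is the energy of the solvated solute after subtracting the
#' energy of the same amount of pure solvent; the last term is the
#' per-molecule energy of the crystal. The result is invariant to extensive
#' rescaling of either bulk box (crystal or solvent).
#'
#' @param U_xtal Total potential energy of the bulk-crystal box, kJ/mol.
#' @param N_xtal Number of solute molecules in that box.
#' @param U_solvent Total potential energy of the pure-solvent box, kJ/mol.
#' @param N_solvent Number of solvent molecules in it.
#' @param U_solution_inf Total potential energy of the infinite-dilution box
#'   (one solute molecule in solvent), kJ/mol.
#' @param N_solvent_inf Number of solvent molecules in the infinite-dilution
#'   box.
#' @return Dissolution enthalpy, kJ/mol.
#' @export
dissolution_enthalpy_from_energies <- function(U_xtal, N_xtal,
                                               U_solvent, N_solvent,
                                               U_solution_inf, N_solvent_inf) {
  counts <- c(N_xtal, N_solvent, N_solvent_inf)
  if (any(!is.finite(counts)) || any(counts < 1)) {
    abort("all molecule counts must be >= 1.")
  }
  (U_solution_inf - (N_solvent_inf / N_solvent) * U_solvent) - U_xtal / N_xtal
}

#' Dissolution enthalpy from two solubility measurements
#'
#' Inverts the Van't Hoff relation through two (x, T) points:
#' \deqn{\Delta H_{diss} = R\,\frac{\ln(x_1/x_2)}{1/T_2 - 1/T_1}.}
#' Antisymmetric under swapping the two points; exact inverse of
#' [solubility_at()].
#'
#' @param x1,x2 Solubilities (mole fraction) at `T1` and `T2`.
#' @param T1,T2 Temperatures, Kelvin; must differ.
#' @return Dissolution enthalpy, kJ/mol.
#' @export
enthalpy_from_two_solubilities <- function(x1, T1, x2, T2) {
  if (any(c(x1, x2) <= 0) || any(c(x1, x2) >= 1)) {
    abort("solubilities must lie in (0, 1).")
  }
  if (any(c(T1, T2) <= 0)) abort("temperatures must be positive (Kelvin).")
  if (T1 == T2) abort("`T1` and `T2` must differ.")
  .R_KJ * log(x1 / x2) / (1 / T2 - 1 / T1)
}

#' Chemical-potential difference between two polymorphs
#'
#' Relative thermodynamic stability of two polymorphs from their solubility
#' curves, with unit activity-coefficient ratios:
#' \deqn{\beta\Delta\mu_{b \to a}(T) = \ln\frac{x^*_a(T)}{x^*_b(T)}.}
#' Positive values mean polymorph `b` (the less soluble one) is the more
#' stable form at `T`.
#'
#' @param T_K Temperature(s), Kelvin.
#' @param curve_a Solubility curve of polymorph `a` (the numerator).
#' @param curve_b Solubility curve of polymorph `b` (the denominator).
#' @return \eqn{\beta\Delta\mu_{b\to a}} in \eqn{k_B T} (vectorised over
#'   `T_K`).
#' @examples
#' beta_md <- solubility_curve_params(2.731e-3, 298, 33.9)
#' alpha_md <- solubility_curve_params(6.460e-3, 298, 24.7)
#' chemical_potential_difference(298, alpha_md, beta_md)
#' @export
chemical_potential_difference <- function(T_K, curve_a, curve_b) {
  log(solubility_at(T_K, curve_a) / solubility_at(T_K, curve_b))
}
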