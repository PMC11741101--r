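#' Tidy a confined-seed thermodynamic fit
#'
#' @param x A `thermo_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`x_star`, `sigma_prime`),
#'   the point `estimate`, and bootstrap `conf.low`/`conf.high` when the fit
#'   carries a bootstrap.
#' @method tidy thermo_fit
#' @export
tidy.thermo_fit <- function(x, ...) {
  out <- tibble(
    term = c("x_star", "sigma_prime"),
    estimate = c(x$x_star, x$sigma_prime)
  )
  if (!is.null(x$boot)) {
    out <- dplyr::left_join(out, x$boot$ci, by = "term")
  }
  out
}

#' One-row summary of a confined-seed thermodynamic fit
#'
#' @inheritParams tidy.thermo_fit
#' @return A tibble with columns `nobs`, `objective` (sum of squared
#'   stationarity residuals, \eqn{(k_BT/\text{molecule})^2}), `rmsd` of the
#'   residuals, `T_ref`, `polymorph` and `converged`.
#' @method glance thermo_fit
#' @export
glance.thermo_fit <- function(x, ...) {
  tibble(
    nobs = nrow(x$observations),
    objective = x$objective,
    rmsd = sqrt(mean(x$residuals^2)),
    T_ref = x$T_ref,
    polymorph = x$polymorph,
    converged = x$convergence %in% 1:4
  )
}

#' Augment seed observations with fitted quantities
#'
#' @inheritParams tidy.thermo_fit
#' @return The fit's observation table with `.resid` (stationarity-gradient
#'   residual, \eqn{k_BT}/molecule), `.fitted` (predicted steady-state size
#'   from the fitted parameters) and `.x_at_ss` (solution mole fraction at
#'   the observed size).
#' @method augment thermo_fit
#' @export
augment.thermo_fit <- function(x, ...) {
  obs <- x$observations
  pred <- predict_equilibrium_sizes(x, obs[, c("n_tot", "n_tot_s")])
  dplyr::mutate(
    obs,
    .fitted = pred$n_ss_pred,
    .resid = x$residuals,
    .x_at_ss = solution_mole_fraction(obs$n_ss, obs$n_tot, obs$n_tot_s)
  )
}
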