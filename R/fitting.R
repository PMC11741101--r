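validate_observations <- function(observations) {
  obs <- as_tibble(observations)
  required <- c("n_tot", "n_tot_s", "n_ss")
  missing <- setdiff(required, names(obs))
  if (length(missing)) {
    abort(paste0(
      "observation table is missing column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  if (!"temperature" %in% names(obs)) obs$temperature <- NA_real_
  if (!"polymorph" %in% names(obs)) obs$polymorph <- NA_character_
  bad <- which(!(obs$n_ss > 0 & obs$n_ss < obs$n_tot))
  if (length(bad)) {
    abort(paste0(
      "`n_ss` must lie in (0, n_tot); violated in row(s) ",
      paste(bad, collapse = ", ")
    ))
  }
  check_composition(obs$n_tot, obs$n_tot_s)
  obs
}

# Residual vector of the stationarity conditions at the observed sizes, as a
# function of the transformed parameters (ln x*, ln sigma').
fit_residuals <- function(log_par, obs) {
  confined_free_energy_gradient(
    obs$n_ss, obs$n_tot, obs$n_tot_s,
    x_star = exp(log_par[1]), sigma_prime = exp(log_par[2])
  )
}

#' Fit solubility and surface energy to steady-state seed observations
#'
#' Estimates the simulation-independent thermodynamic parameters
#' \eqn{(x^*, \sigma')} from a set of confined seeded simulations, each
#' contributing one observation: its box composition `(n_tot, n_tot_s)` and
#' the steady-state crystal size `n_ss` it relaxed to. Each observed size is
#' a stable stationary point of the confined free-energy profile of its box,
#' so the gradient of [confined_free_energy()] must vanish there for the one
#' true parameter pair. The fit minimises the sum of squared gradients
#' \deqn{\sum_i \big[F'_i(n_{ss,i};\, x^*, \sigma')\big]^2}
#' over \eqn{(x^*, \sigma')} with a Levenberg-Marquardt solver in
#' \eqn{(\ln x^*, \ln \sigma')} coordinates (positivity enforced by the
#' transform). Because the observed sizes come from stable steady states,
#' the unstable (critical-nucleus) branch of the stationarity condition is
#' avoided automatically.
#'
#' The default initial guess takes \eqn{x^*} as the most depleted final
#' solution composition among the observations (which bounds the solubility
#' from above) and \eqn{\sigma' = 5\,k_BT}, and the solver settings are
#' fixed, so the fit is deterministic.
#'
#' @param observations Data frame with columns `n_tot`, `n_tot_s`, `n_ss`
#'   and optionally `temperature` (must be common to all rows) and
#'   `polymorph`. See [read_observation_table()] and [lga_table1()].
#' @param n_boot Number of bootstrap resamples used for confidence
#'   intervals; 0 (default) skips the bootstrap. See
#'   [bootstrap_uncertainty()].
#' @param seed RNG seed for the bootstrap.
#' @param sigma_prime_init Initial guess for the surface energy, \eqn{k_BT}.
#' @return An object of class `thermo_fit`: a list with elements `x_star`,
#'   `sigma_prime`, `T_ref`, `residuals` (per-observation gradient at the
#'   optimum, \eqn{k_BT}/molecule), `objective`, `observations`, and when
#'   `n_boot > 0` a `boot` element with resample draws and percentile
#'   intervals. Use [tidy()], [glance()], [augment()] and
#'   [predict_equilibrium_sizes()] on it.
#' @examples
#' fit <- fit_thermo_params(lga_table1("beta"))
#' tidy(fit)
#' @export
fit_thermo_params <- function(observations, n_boot = 0, seed = NULL,
                              sigma_prime_init = 5) {
  obs <- validate_observations(observations)
  if (nrow(obs) < 2) {
    abort("underdetermined fit: at least 2 observations are required to identify (x_star, sigma_prime).")
  }
  temps <- unique(obs$temperature[!is.na(obs$temperature)])
  if (length(temps) > 1) {
    abort("mixed temperatures: all observations in one fit must share `temperature`.")
  }
  x_at_ss <- solution_mole_fraction(obs$n_ss, obs$n_tot, obs$n_tot_s)
  start <- c(log(min(x_at_ss)), log(sigma_prime_init))
  sol <- minpack.lm::nls.lm(
    par = start, fn = fit_residuals, obs = obs,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  if (!sol$info %in% 1:4) {
    abort(paste0(
      "least-squares solver did not converge (info = ", sol$info, "); ",
      "final residual sum of squares = ", format(sol$deviance)
    ))
  }
  res <- fit_residuals(sol$par, obs)
  fit <- structure(
    list(
      x_star = exp(sol$par[1]),
      sigma_prime = exp(sol$par[2]),
      T_ref = if (length(temps)) temps else NA_real_,
      polymorph = if (length(unique(obs$polymorph)) == 1) obs$polymorph[1] else NA_character_,
      residuals = res,
      objective = sum(res^2),
      observations = obs,
      convergence = sol$info,
      n_boot = n_boot,
      seed = seed,
      boot = NULL
    ),
    class = "thermo_fit"
  )
  if (n_boot > 0) {
    fit$boot <- bootstrap_uncertainty(obs, n_boot = n_boot, seed = seed,
                                      sigma_prime_init = sigma_prime_init)
  }
  fit
}

#' @export
print.thermo_fit <- function(x, ...) {
  cat("<thermo_fit> confined-seed thermodynamic parameters\n")
  cat(sprintf("  x*          = %.6g\n", x$x_star))
  cat(sprintf("  sigma'      = %.6g kBT\n", x$sigma_prime))
  if (!is.na(x$T_ref)) cat(sprintf("  T_ref       = %g K\n", x$T_ref))
  cat(sprintf("  observations = %d, sum of squared residuals = %.3g\n",
              nrow(x$observations), x$objective))
  if (!is.null(x$boot)) {
    ci <- x$boot$ci
    cat(sprintf("  bootstrap (%d resamples): x* in [%.4g, %.4g], sigma' in [%.4g, %.4g]\n",
                x$boot$n_boot, ci$conf.low[1], ci$conf.high[1],
                ci$conf.low[2], ci$conf.high[2]))
  }
  invisible(x)
}

#' Bootstrap confidence intervals for the seed-observation fit
#'
#' Case-resamples whole observations with replacement, refits each resample
#' with [fit_thermo_params()] and summarises the resample distributions of
#' \eqn{x^*} and \eqn{\sigma'} by percentile intervals (default 16-84%,
#' i.e. a one-standard-deviation band). Resamples on which the refit fails
#' (degenerate compositions) are skipped and counted.
#'
#' @inheritParams fit_thermo_params
#' @param n_boot Number of resamples (>= 1).
#' @param probs Lower and upper percentile of the reported interval.
#' @return A list of class `thermo_boot` with elements `draws` (tibble of
#'   `replicate`, `x_star`, `sigma_prime`), `ci` (tibble of `term`,
#'   `conf.low`, `conf.high`), `n_boot`, `n_failed`, `probs`, `seed`.
#' @export
bootstrap_uncertainty <- function(observations, n_boot = 1000, seed = NULL,
                                  probs = c(0.16, 0.84),
                                  sigma_prime_init = 5) {
  obs <- validate_observations(observations)
  if (n_boot < 1) abort("`n_boot` must be >= 1.")
  refit_one <- function(rows) {
    tryCatch({
      f <- fit_thermo_params(obs[rows, ], sigma_prime_init = sigma_prime_init)
      c(f$x_star, f$sigma_prime)
    }, error = function(e) c(NA_real_, NA_real_))
  }
  run <- function() {
    purrr::map(seq_len(n_boot), function(b) {
      refit_one(sample.int(nrow(obs), nrow(obs), replace = TRUE))
    })
  }
  draws_raw <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  m <- do.call(rbind, draws_raw)
  draws <- tibble(
    replicate = seq_len(n_boot),
    x_star = m[, 1], sigma_prime = m[, 2]
  )
  n_failed <- sum(is.na(draws$x_star))
  if (n_failed > 0) {
    warn(paste0(n_failed, " bootstrap resample(s) gave a degenerate fit and were skipped."))
  }
  ok <- dplyr::filter(draws, !is.na(.data$x_star))
  ci <- tibble(
    term = c("x_star", "sigma_prime"),
    conf.low = c(quantile(ok$x_star, probs[1], names = FALSE),
                 quantile(ok$sigma_prime, probs[1], names = FALSE)),
    conf.high = c(quantile(ok$x_star, probs[2], names = FALSE),
                  quantile(ok$sigma_prime, probs[2], names = FALSE))
  )
  structure(
    list(draws = draws, ci = ci, n_boot = n_boot, n_failed = n_failed,
         probs = probs, seed = seed),
    class = "thermo_boot"
  )
}

#' Predict steady-state cluster sizes for new box compositions
#'
#' For each composition, returns the stable-minimum branch of
#' [stationary_points()] under the given thermodynamic parameters - the
#' cluster size a confined seeded simulation of that box is predicted to
#' relax to. Compositions whose profile has no interior minimum (the
#' solution is undersaturated, or confinement suppresses nucleation) are
#' flagged.
#'
#' @param params A `thermo_fit` object, or a list/tibble with elements
#'   `x_star` and `sigma_prime`.
#' @param compositions Data frame with columns `n_tot` and `n_tot_s`.
#' @return `compositions` as a tibble with added columns `n_ss_pred`
#'   (`NA` where absent) and `has_minimum`.
#' @examples
#' fit <- fit_thermo_params(lga_table1("beta"))
#' predict_equilibrium_sizes(fit, lga_table1("beta"))
#' @export
predict_equilibrium_sizes <- function(params, compositions) {
  p <- as.list(params)[c("x_star", "sigma_prime")]
  check_params(p$x_star, p$sigma_prime)
  comp <- as_tibble(compositions)
  pred <- purrr::map_dbl(seq_len(nrow(comp)), function(i) {
    stationary_points(comp$n_tot[i], comp$n_tot_s[i],
                      p$x_star, p$sigma_prime)$n_ss
  })
  dplyr::mutate(comp, n_ss_pred = pred, has_minimum = !is.na(pred))
}

#' @export
as.list.thermo_fit <- function(x, ...) {
  list(x_star = x$x_star, sigma_prime = x$sigma_prime, T_ref = x$T_ref)
}
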