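stability_labels <- c("undersaturated", "confined_stabilized",
                      "nucleation_permitted")

#' Classify the stability of a confined solution
#'
#' Places one (composition, box-size) condition into one of three regimes of
#' the confined free-energy landscape:
#' * `undersaturated` - the nominal composition is at or below the
#'   solubility (`x0 <= x_star`); the solution is stable in any system size.
#' * `confined_stabilized` - nominally supersaturated, but the box is so
#'   small that depletion erases the interior minimum: confinement
#'   stabilises a solution that would nucleate in macroscopic conditions.
#' * `nucleation_permitted` - the profile has an interior minimum; a
#'   crystal of that size can coexist in equilibrium with the confined
#'   solution.
#'
#' Provide either the nominal mole fraction `x0` (the solute count is then
#' implied by `n_tot_s`) or an explicit `n_tot`; if both are given they must
#' be consistent.
#'
#' @param n_tot_s Number of solvent molecules (the box-size coordinate).
#' @param x0 Nominal solute mole fraction `n_tot / (n_tot + n_tot_s)`.
#' @param n_tot Number of solute molecules; implied by `x0` when omitted.
#' @inheritParams confined_free_energy
#' @return A one-row tibble: `x0`, `n_tot`, `n_tot_s`, `label` (factor with
#'   levels undersaturated, confined_stabilized, nucleation_permitted),
#'   `n_crit`, `n_ss`.
#' @examples
#' classify_confined_state(n_tot_s = 11974, n_tot = 136,
#'                         x_star = 2.731e-3, sigma_prime = 4.81)
#' @export
classify_confined_state <- function(n_tot_s, x0 = NULL, n_tot = NULL,
                                    x_star, sigma_prime) {
  check_params(x_star, sigma_prime)
  if (is.null(x0) && is.null(n_tot)) {
    abort("provide `x0` or `n_tot`.")
  }
  if (is.null(n_tot)) {
    if (x0 <= 0 || x0 >= 1) abort("`x0` must lie in (0, 1).")
    n_tot <- x0 / (1 - x0) * n_tot_s
  } else if (!is.null(x0)) {
    implied <- n_tot / (n_tot + n_tot_s)
    if (abs(implied - x0) > 1e-6 * max(x0, implied)) {
      abort(sprintf(
        "inconsistent inputs: `x0` = %.6g but `n_tot`/`n_tot_s` imply %.6g.",
        x0, implied
      ))
    }
  }
  x0 <- n_tot / (n_tot + n_tot_s)
  if (x0 <= x_star) {
    st <- tibble(n_crit = NA_real_, n_ss = NA_real_)
    label <- "undersaturated"
  } else {
    st <- stationary_points(n_tot, n_tot_s, x_star, sigma_prime)
    label <- if (is.na(st$n_ss)) "confined_stabilized" else "nucleation_permitted"
  }
  tibble(
    x0 = x0, n_tot = n_tot, n_tot_s = n_tot_s,
    label = factor(label, levels = stability_labels),
    n_crit = st$n_crit, n_ss = st$n_ss
  )
}

#' Stability map of confined solutions in the composition/size plane
#'
#' Classifies every combination of nominal composition and box size with
#' [classify_confined_state()]. The box volume is parameterised by the
#' solvent count `n_tot_s` (at fixed pressure, total molecule count sets the
#' volume).
#'
#' @param x0_grid Nominal solute mole fractions.
#' @param size_grid Solvent counts `n_tot_s`.
#' @inheritParams confined_free_energy
#' @return Long-format tibble with one row per `(x0, n_tot_s)` pair and
#'   columns as in [classify_confined_state()]; row order follows
#'   `expand_grid(x0 = x0_grid, n_tot_s = size_grid)`.
#' @export
stability_map <- function(x0_grid, size_grid, x_star, sigma_prime) {
  if (!length(x0_grid) || !length(size_grid)) {
    abort("`x0_grid` and `size_grid` must be non-empty.")
  }
  grid <- tidyr::expand_grid(x0 = x0_grid, n_tot_s = size_grid)
  purrr::pmap_dfr(grid, function(x0, n_tot_s) {
    classify_confined_state(n_tot_s = n_tot_s, x0 = x0,
                            x_star = x_star, sigma_prime = sigma_prime)
  })
}

#' Metastable-zone limit: the locus of a fixed nucleation barrier
#'
#' The limit of solution stability \eqn{x'(T)} is the composition at which
#' the classical nucleation barrier [cnt_barrier()] drops to a threshold of
#' a few \eqn{k_B T}, so nucleation ceases to be a rare event and
#' precipitation becomes effectively instantaneous. For the \eqn{n^{2/3}}
#' surface law the locus has the closed form
#' \deqn{x'(T) = x^*(T)\, \exp\sqrt{\frac{4 \sigma'^3}{27\,\Delta F^*_{thr}}},}
#' i.e. a temperature-independent multiple of the solubility curve. A
#' bisection solver of \eqn{\beta\Delta F^*(x, T) = \Delta F^*_{thr}} is
#' available as a cross-check. The default threshold of 3 \eqn{k_B T} is a
#' conventional, admittedly arbitrary, marker of barrierless conditions and
#' is configurable.
#'
#' @param curve A `solubility_curve` object.
#' @inheritParams confined_free_energy
#' @param T_grid Temperatures, Kelvin.
#' @param threshold Barrier height defining the limit, \eqn{k_B T}.
#' @param method `"closed_form"` (default) or `"bisection"`.
#' @return A tibble of class `metastable_limit` with columns `T_K`,
#'   `x_star` (solubility) and `x_limit`; the band between the two columns
#'   is the computed metastable zone. The threshold is stored in the
#'   `"threshold"` attribute.
#' @export
metastable_limit <- function(curve, sigma_prime, T_grid = seq(273, 343, by = 1),
                             threshold = 3,
                             method = c("closed_form", "bisection")) {
  method <- match.arg(method)
  if (!is.finite(threshold) || threshold <= 0) {
    abort("`threshold` must be positive.")
  }
  if (!is.finite(sigma_prime) || sigma_prime <= 0) {
    abort("`sigma_prime` must be positive.")
  }
  xs <- solubility_at(T_grid, curve)
  lnS <- sqrt(4 * sigma_prime^3 / (27 * threshold))
  if (method == "closed_form") {
    xl <- xs * exp(lnS)
  } else {
    xl <- purrr::map_dbl(seq_along(T_grid), function(i) {
      f <- function(lx) {
        cnt_barrier(exp(lx), T_grid[i], curve, sigma_prime) - threshold
      }
      exp(uniroot(f, lower = log(xs[i]) + 1e-12, upper = log(xs[i]) + 10 * (lnS + 1),
                  tol = 1e-14)$root)
    })
  }
  out <- tibble(T_K = T_grid, x_star = xs, x_limit = xl)
  class(out) <- c("metastable_limit", class(out))
  attr(out, "threshold") <- threshold
  attr(out, "sigma_prime") <- sigma_prime
  out
}
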