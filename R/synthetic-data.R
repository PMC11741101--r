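#' Generate synthetic seed observations from known thermodynamic parameters
#'
#' Inverse of the fitting problem, used to exercise and benchmark the
#' estimation pipeline: for each box composition the steady-state size is
#' placed at the interior minimum of the confined free-energy profile under
#' the generating parameters, then optionally perturbed with Gaussian noise
#' and rounded to whole molecules (trajectory-derived steady-state sizes
#' fluctuate by a few molecules, so the default noise sd is 2).
#' Compositions whose profile has no interior minimum cannot host a stable
#' cluster; they are reported in the `"rejected"` attribute rather than
#' silently dropped.
#'
#' @inheritParams confined_free_energy
#' @param compositions Data frame with columns `n_tot` and `n_tot_s`.
#' @param temperature Temperature label attached to the observations, K.
#' @param polymorph Polymorph label attached to the observations.
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   steady-state sizes, molecules. 0 gives exact minima.
#' @param round_sizes Round sizes to whole molecules (after noise).
#' @param seed RNG seed; same seed, same output.
#' @return A tibble of observations (`n_tot`, `n_tot_s`, `n_ss`,
#'   `temperature`, `polymorph`) ready for [fit_thermo_params()], with a
#'   `"rejected"` attribute listing compositions without a minimum.
#' @examples
#' comps <- lga_table1("beta")[, c("n_tot", "n_tot_s")]
#' obs <- generate_observations(2.731e-3, 4.81, comps, noise_sd = 0)
#' fit_thermo_params(obs)
#' @export
generate_observations <- function(x_star, sigma_prime, compositions,
                                  temperature = 298, polymorph = "synthetic",
                                  noise_sd = 2, round_sizes = TRUE,
                                  seed = NULL) {
  check_params(x_star, sigma_prime)
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  comp <- as_tibble(compositions)
  pred <- predict_equilibrium_sizes(
    list(x_star = x_star, sigma_prime = sigma_prime), comp
  )
  rejected <- dplyr::filter(pred, !.data$has_minimum)
  if (nrow(rejected) > 0) {
    warn(paste0(
      nrow(rejected),
      " composition(s) admit no stable cluster under the generating parameters and were rejected."
    ))
  }
  kept <- dplyr::filter(pred, .data$has_minimum)
  n_ss <- kept$n_ss_pred
  if (noise_sd > 0) {
    draw <- function() rnorm(length(n_ss), 0, noise_sd)
    eps <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    n_ss <- n_ss + eps
  }
  if (round_sizes) n_ss <- round(n_ss)
  n_ss <- pmin(pmax(n_ss, 1), kept$n_tot - 1)
  out <- tibble(
    n_tot = kept$n_tot, n_tot_s = kept$n_tot_s, n_ss = n_ss,
    temperature = temperature, polymorph = polymorph
  )
  attr(out, "rejected") <- rejected[, c("n_tot", "n_tot_s")]
  out
}

# Cubic-lattice site coordinates for n molecules, centred at the origin.
lattice_sites <- function(n, spacing) {
  side <- ceiling(n^(1 / 3))
  ax <- (seq_len(side) - (side + 1) / 2) * spacing
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  g[seq_len(n), , drop = FALSE]
}

# Uniform random unit vectors.
random_unit_vectors <- function(n) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Generate a synthetic crystal-core-in-liquid configuration
#'
#' Builds a benchmark snapshot for the cluster classifier: a cubic-lattice
#' crystalline core of `n_core` molecules with perfectly aligned internal
#' vectors, immersed in `n_liquid` liquid-like molecules placed uniformly at
#' random with isotropic random orientations, subject to a hard
#' minimum-distance rejection rule against all previously placed molecules.
#' The ground-truth labels are returned alongside the snapshot. The box
#' defaults to a cube holding all molecules at a number density of
#' 0.8 molecules per `lattice_spacing` cubed.
#'
#' @param n_core Number of crystalline core molecules.
#' @param n_liquid Number of liquid molecules.
#' @param lattice_spacing Core lattice constant, Angstrom. The default 6 is
#'   of the order of a small-molecule first coordination shell.
#' @param box Cubic box edge length (Angstrom) or length-3 vector; computed
#'   from the density default when `NULL`.
#' @param min_dist Minimum allowed centre-centre distance when inserting
#'   liquid molecules, Angstrom.
#' @param seed RNG seed.
#' @param max_tries Insertion attempts per liquid molecule before giving up.
#' @return A list with elements `snapshot` (a [molecular_snapshot()]) and
#'   `labels` (logical ground truth, `TRUE` = crystalline core).
#' @export
generate_crystal_liquid_frame <- function(n_core, n_liquid,
                                          lattice_spacing = 6, box = NULL,
                                          min_dist = 0.6 * lattice_spacing,
                                          seed = NULL, max_tries = 200) {
  if (n_core < 0 || n_liquid < 0 || n_core + n_liquid < 1) {
    abort("need at least one molecule.")
  }
  if (is.null(box)) {
    edge <- ((n_core + n_liquid) * lattice_spacing^3 / 0.8)^(1 / 3)
    core_extent <- ceiling(n_core^(1 / 3)) * lattice_spacing
    box <- rep(max(edge, core_extent + lattice_spacing), 3)
  }
  if (length(box) == 1) box <- rep(box, 3)
  build <- function() {
    pos <- matrix(numeric(0), ncol = 3)
    if (n_core > 0) {
      pos <- sweep(lattice_sites(n_core, lattice_spacing), 2, box / 2, "+")
    }
    min_image_ok <- function(p) {
      if (nrow(pos) == 0) return(TRUE)
      dk <- sweep(pos, 2, p, "-")
      dk <- dk - sweep(round(sweep(dk, 2, box, "/")), 2, box, "*")
      all(rowSums(dk^2) >= min_dist^2)
    }
    for (i in seq_len(n_liquid)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- runif(3) * box
        if (min_image_ok(cand)) {
          pos <- rbind(pos, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort("could not place all liquid molecules: packing infeasible under `min_dist`.")
      }
    }
    vec <- rbind(
      matrix(rep(c(0, 0, 1), n_core), ncol = 3, byrow = TRUE),
      random_unit_vectors(n_liquid)
    )
    list(
      snapshot = molecular_snapshot(pos, vec, box = box),
      labels = rep(c(TRUE, FALSE), c(n_core, n_liquid))
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}
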