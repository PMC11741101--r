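#' Build a molecular snapshot
#'
#' A snapshot reduces each rigid molecule to a reference point and an
#' internal orientation vector (defined by a designated atom pair), which is
#' all the orientation-fingerprint classifier needs. Vectors are normalised
#' on construction; positions are wrapped into the primary periodic cell
#' when a box is given.
#'
#' @param positions N x 3 matrix of per-molecule reference coordinates
#'   (Angstrom).
#' @param internal_vectors N x 3 matrix of per-molecule internal vectors
#'   (any length; normalised internally).
#' @param box Periodic cell dimensions, length-3 numeric (orthorhombic,
#'   Angstrom), or `NULL` for a non-periodic snapshot.
#' @return An object of class `molecular_snapshot`.
#' @export
molecular_snapshot <- function(positions, internal_vectors, box = NULL) {
  positions <- as.matrix(positions)
  internal_vectors <- as.matrix(internal_vectors)
  if (ncol(positions) != 3 || ncol(internal_vectors) != 3) {
    abort("`positions` and `internal_vectors` must have 3 columns.")
  }
  if (nrow(positions) != nrow(internal_vectors)) {
    abort("`positions` and `internal_vectors` must have the same number of rows.")
  }
  norms <- sqrt(rowSums(internal_vectors^2))
  if (any(norms == 0)) abort("internal vectors must be non-zero.")
  internal_vectors <- internal_vectors / norms
  if (!is.null(box)) {
    if (length(box) != 3 || any(box <= 0)) {
      abort("`box` must be three positive cell lengths.")
    }
    positions <- sweep(positions, 2, box, function(p, b) p %% b)
  }
  structure(
    list(positions = positions, internal_vectors = internal_vectors, box = box),
    class = "molecular_snapshot"
  )
}

#' @export
print.molecular_snapshot <- function(x, ...) {
  cat(sprintf("<molecular_snapshot> %d molecules, %s\n",
              nrow(x$positions),
              if (is.null(x$box)) "non-periodic" else
                paste0("box ", paste(signif(x$box, 4), collapse = " x "), " A")))
  invisible(x)
}

# Full pairwise distance matrix under the minimum-image convention
# (orthorhombic cells). N is at most a few thousand in intended use.
pair_distance_matrix <- function(snapshot) {
  pos <- snapshot$positions
  box <- snapshot$box
  d2 <- matrix(0, nrow(pos), nrow(pos))
  for (k in 1:3) {
    dk <- outer(pos[, k], pos[, k], "-")
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

# Polar angle (degrees, in [0, 180]) between internal vectors of the given
# molecule pairs; optionally folded to [0, 90].
pair_angles <- function(snapshot, i, j, fold = FALSE) {
  v <- snapshot$internal_vectors
  dot <- rowSums(v[i, , drop = FALSE] * v[j, , drop = FALSE])
  dot <- pmin(1, pmax(-1, dot))
  theta <- acos(dot) * 180 / pi
  if (fold) theta <- pmin(theta, 180 - theta)
  theta
}

#' Reference orientation fingerprint of a bulk crystal
#'
#' Builds the relative-orientation probability density \eqn{p(\theta)} of a
#' crystal polymorph: the histogram of polar angles between the internal
#' vectors of all molecule pairs closer than `r_cut` (the first coordination
#' shell) in one or more bulk-crystal snapshots, under the minimum-image
#' convention. Bins whose density reaches at least `accept_frac` of the peak
#' density are marked as crystalline-compatible; that acceptance mask is
#' what [classify_molecules()] tests neighbour angles against. The 20%
#' default makes the otherwise qualitative "falls within the reference
#' fingerprint" rule explicit and tunable.
#'
#' @param frames A `molecular_snapshot` or list of them, sampled from the
#'   reference bulk crystal.
#' @param r_cut Radial cutoff (Angstrom) delimiting the first coordination
#'   shell (e.g. 6.25 for alpha-LGA, 7.0 for beta-LGA).
#' @param n_bins Number of angle bins over \[0, 180\] degrees.
#' @param accept_frac Fraction of the peak density above which a bin is
#'   accepted as crystalline.
#' @param fold Fold angles to \eqn{\min(\theta, 180 - \theta)} (treat the
#'   internal vector as headless). Default keeps the full polar angle so
#'   parallel and antiparallel packings are distinguished.
#' @return An object of class `orientation_fingerprint` with fields
#'   `theta_bins` (bin edges, degrees), `density` (normalised to unit
#'   integral over degrees), `acceptance_mask`, `r_cut`, `accept_frac`,
#'   `fold`, `n_pairs`.
#' @export
build_fingerprint <- function(frames, r_cut, n_bins = 36, accept_frac = 0.2,
                              fold = FALSE) {
  if (inherits(frames, "molecular_snapshot")) frames <- list(frames)
  if (!is.finite(r_cut) || r_cut <= 0) abort("`r_cut` must be positive.")
  edges <- seq(0, 180, length.out = n_bins + 1)
  counts <- numeric(n_bins)
  n_pairs <- 0L
  for (fr in frames) {
    d <- pair_distance_matrix(fr)
    idx <- which(upper.tri(d) & d <= r_cut, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    th <- pair_angles(fr, idx[, 1], idx[, 2], fold = fold)
    bin <- pmin(n_bins, findInterval(th, edges, rightmost.closed = TRUE))
    counts <- counts + tabulate(bin, nbins = n_bins)
    n_pairs <- n_pairs + nrow(idx)
  }
  if (n_pairs == 0) {
    abort("empty fingerprint: no molecule pairs within `r_cut` in the reference frames.")
  }
  width <- diff(edges)
  density <- counts / (sum(counts) * width)
  structure(
    list(
      theta_bins = edges,
      density = density,
      acceptance_mask = density >= accept_frac * max(density),
      r_cut = r_cut,
      accept_frac = accept_frac,
      fold = fold,
      n_pairs = n_pairs
    ),
    class = "orientation_fingerprint"
  )
}

#' @export
print.orientation_fingerprint <- function(x, ...) {
  cat(sprintf(
    "<orientation_fingerprint> %d bins over [0, 180] deg, r_cut = %g A, %d accepted bin(s), %d reference pairs\n",
    length(x$density), x$r_cut, sum(x$acceptance_mask), x$n_pairs
  ))
  invisible(x)
}

#' Label molecules as crystalline or liquid
#'
#' A molecule is labelled crystalline when at least `min_matches` of its
#' neighbours within the fingerprint's radial cutoff have a pairwise
#' internal-vector angle falling in an accepted fingerprint bin. The
#' criterion is binary and deterministic - it is an a-posteriori analysis
#' descriptor, not a differentiable order parameter.
#'
#' @param frame A `molecular_snapshot`.
#' @param fingerprint An [build_fingerprint()] result built with the same
#'   internal-vector convention.
#' @param min_matches Minimum number of orientation-conforming neighbours
#'   required (default 1: a single conforming neighbour suffices).
#' @return Logical vector, `TRUE` for crystalline molecules. Molecules with
#'   no neighbours within the cutoff are liquid.
#' @export
classify_molecules <- function(frame, fingerprint, min_matches = 1) {
  stopifnot(inherits(frame, "molecular_snapshot"),
            inherits(fingerprint, "orientation_fingerprint"))
  n <- nrow(frame$positions)
  d <- pair_distance_matrix(frame)
  idx <- which(upper.tri(d) & d <= fingerprint$r_cut, arr.ind = TRUE)
  matches <- integer(n)
  if (nrow(idx) > 0) {
    th <- pair_angles(frame, idx[, 1], idx[, 2], fold = fingerprint$fold)
    edges <- fingerprint$theta_bins
    bin <- pmin(length(fingerprint$density),
                findInterval(th, edges, rightmost.closed = TRUE))
    ok <- fingerprint$acceptance_mask[bin]
    matches <- tabulate(idx[, 1][ok], nbins = n) +
      tabulate(idx[, 2][ok], nbins = n)
  }
  matches >= min_matches
}

#' Size of the largest crystalline cluster
#'
#' Builds the contact graph on crystalline-labelled molecules (edges between
#' pairs at minimum-image distance at most `r_cut`, the same cutoff used for
#' classification) and returns the cardinality of its largest connected
#' component; 0 when no molecule is crystalline.
#'
#' @param labels Logical vector from [classify_molecules()].
#' @param frame The `molecular_snapshot` the labels refer to.
#' @param r_cut Clustering distance cutoff, Angstrom.
#' @return Integer cluster size.
#' @export
largest_cluster <- function(labels, frame, r_cut) {
  stopifnot(inherits(frame, "molecular_snapshot"),
            length(labels) == nrow(frame$positions))
  xt <- which(labels)
  if (length(xt) == 0) return(0L)
  if (length(xt) == 1) return(1L)
  sub <- molecular_snapshot(frame$positions[xt, , drop = FALSE],
                            frame$internal_vectors[xt, , drop = FALSE],
                            frame$box)
  d <- pair_distance_matrix(sub)
  adj <- (d <= r_cut)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  as.integer(max(igraph::components(g)$csize))
}

#' Largest-cluster time series over a trajectory
#'
#' Applies [classify_molecules()] and [largest_cluster()] to each frame.
#'
#' @param frames List of `molecular_snapshot` objects (trajectory frames).
#' @param fingerprint Reference `orientation_fingerprint`.
#' @param times Frame times (any unit); defaults to the frame index.
#' @inheritParams classify_molecules
#' @return A tibble with columns `time` and `largest_cluster`.
#' @export
largest_cluster_series <- function(frames, fingerprint, times = NULL,
                                   min_matches = 1) {
  if (inherits(frames, "molecular_snapshot")) frames <- list(frames)
  if (is.null(times)) times <- seq_along(frames)
  sizes <- purrr::map_int(frames, function(fr) {
    as.integer(largest_cluster(
      classify_molecules(fr, fingerprint, min_matches), fr, fingerprint$r_cut
    ))
  })
  tibble(time = times, largest_cluster = sizes)
}

#' Steady-state cluster size from a largest-cluster time series
#'
#' Averages the largest-cluster size over the final portion of the
#' trajectory and reports the mean, its standard error, and a drift flag: a
#' linear trend is fitted over the window and the series is flagged as
#' drifting (with a warning) when the slope differs from zero by more than
#' two standard errors, i.e. when the cluster has not yet reached its
#' steady state.
#'
#' @param series A tibble with columns `time` and `largest_cluster` (as
#'   returned by [largest_cluster_series()]), or a bare numeric vector of
#'   sizes.
#' @param window_fraction Fraction of the trajectory tail to average over.
#' @return A one-row tibble: `n_ss`, `se`, `drifting`, `n_frames` (window
#'   length).
#' @export
steady_state_size <- function(series, window_fraction = 0.5) {
  if (is.numeric(series)) {
    series <- tibble(time = seq_along(series), largest_cluster = series)
  }
  stopifnot(all(c("time", "largest_cluster") %in% names(series)))
  if (window_fraction <= 0 || window_fraction > 1) {
    abort("`window_fraction` must lie in (0, 1].")
  }
  n <- nrow(series)
  if (n < 10) abort("series too short: at least 10 frames are required.")
  win <- series[seq(n - ceiling(window_fraction * n) + 1, n), ]
  m <- mean(win$largest_cluster)
  se <- sd(win$largest_cluster) / sqrt(nrow(win))
  drifting <- FALSE
  if (nrow(win) >= 3 && sd(win$largest_cluster) > 0) {
    trend <- suppressWarnings(
      summary(lm(largest_cluster ~ time, data = win))$coefficients
    )
    if (nrow(trend) == 2) {
      drifting <- abs(trend[2, 1]) > 2 * trend[2, 2]
    }
  }
  if (drifting) {
    warn("largest-cluster series is still drifting over the averaging window; `n_ss` may not be a steady state.")
  }
  tibble(n_ss = m, se = se, drifting = drifting, n_frames = nrow(win))
}
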