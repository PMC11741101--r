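test_that("fingerprint of aligned and bipartite lattices lands in the right bins", {
  snap <- aligned_lattice_snapshot(27, spacing = 6)
  fp <- build_fingerprint(snap, r_cut = 7)
  width <- diff(fp$theta_bins)
  expect_equal(sum(fp$density * width), 1)
  expect_equal(which(fp$density > 0), 1L)            # all mass at theta = 0
  expect_true(fp$acceptance_mask[1])
  # antiparallel bipartite lattice: alternate vectors +z/-z in a chain;
  # the cutoff spans nearest (antiparallel) and next-nearest (parallel)
  # neighbours, so only the 0 and 180 degree bins fill
  n <- 20
  pos <- cbind(seq_len(n) * 6, 0, 0)
  vec <- matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE)
  vec[seq(2, n, 2), 3] <- -1
  fp2 <- build_fingerprint(molecular_snapshot(pos, vec), r_cut = 13)
  hot <- which(fp2$density > 0)
  expect_setequal(hot, c(1L, length(fp2$density)))   # theta = 0 and 180 only
  expect_equal(sum(fp2$density * diff(fp2$theta_bins)), 1)
  # no pairs within reach -> explicit error
  expect_error(build_fingerprint(snap, r_cut = 1), "empty fingerprint")
})

test_that("classification is exact on the reference crystal and specific on liquids", {
  ref <- aligned_lattice_snapshot(64, spacing = 6)
  fp <- build_fingerprint(ref, r_cut = 7)
  expect_true(all(classify_molecules(ref, fp)))
  # isolated molecule: no neighbours, liquid by definition
  lone <- molecular_snapshot(rbind(c(0, 0, 0), c(100, 100, 100)),
                             rbind(c(0, 0, 1), c(0, 0, 1)))
  expect_equal(classify_molecules(lone, fp), c(FALSE, FALSE))
  # random orientations at liquid density: < 5% false crystalline
  liq <- generate_crystal_liquid_frame(0, 500, seed = 91)
  expect_lt(mean(classify_molecules(liq$snapshot, fp)), 0.05)
})

test_that("classification is invariant to rotation, translation, relabeling", {
  gen <- generate_crystal_liquid_frame(27, 120, seed = 5)
  fp <- build_fingerprint(aligned_lattice_snapshot(27, spacing = 6), r_cut = 7)
  # drop periodicity so a rigid rotation is exact
  snap <- molecular_snapshot(gen$snapshot$positions,
                             gen$snapshot$internal_vectors)
  lab <- classify_molecules(snap, fp)
  th <- pi / 7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- molecular_snapshot(snap$positions %*% t(R) + 5,
                            snap$internal_vectors %*% t(R))
  expect_equal(classify_molecules(rot, fp), lab)
  perm <- sample(nrow(snap$positions))
  shuf <- molecular_snapshot(snap$positions[perm, ],
                             snap$internal_vectors[perm, ])
  expect_equal(classify_molecules(shuf, fp), lab[perm])
})

test_that("largest cluster matches a brute-force BFS oracle and simple geometries", {
  # two blobs far apart: sizes 30 and 50
  blob <- function(n, centre) {
    sweep(aligned_lattice_snapshot(n, spacing = 4)$positions, 2, centre, "+")
  }
  pos <- rbind(blob(30, c(0, 0, 0)), blob(50, c(200, 200, 200)))
  vec <- matrix(rep(c(0, 0, 1), 80), ncol = 3, byrow = TRUE)
  snap <- molecular_snapshot(pos, vec)
  expect_equal(largest_cluster(rep(TRUE, 80), snap, r_cut = 7), 50L)
  expect_equal(largest_cluster(rep(FALSE, 80), snap, r_cut = 7), 0L)
  # random geometric graphs against the oracle
  set.seed(41)
  for (i in 1:50) {
    n <- sample(20:80, 1)
    box <- runif(1, 15, 40)
    snap <- molecular_snapshot(matrix(runif(3 * n) * box, ncol = 3),
                               matrix(rnorm(3 * n), ncol = 3),
                               box = rep(box, 3))
    keep <- runif(n) < 0.8
    rc <- runif(1, 2, 8)
    got <- largest_cluster(keep, snap, rc)
    d <- seedtherm:::pair_distance_matrix(snap)
    want <- bfs_largest_component(d[keep, keep, drop = FALSE], rc)
    expect_equal(got, want)
  }
})

test_that("flipping molecules to crystalline never shrinks the largest cluster", {
  gen <- generate_crystal_liquid_frame(27, 100, seed = 13)
  snap <- gen$snapshot
  set.seed(14)
  labels <- runif(nrow(snap$positions)) < 0.3
  base <- largest_cluster(labels, snap, r_cut = 7)
  grown <- labels
  grown[sample(which(!grown), 20)] <- TRUE
  expect_gte(largest_cluster(grown, snap, r_cut = 7), base)
})

test_that("seed-in-liquid benchmark recovers the core within the stated band", {
  gen <- generate_crystal_liquid_frame(100, 900, seed = 42)
  fp <- build_fingerprint(aligned_lattice_snapshot(64, spacing = 6), r_cut = 7)
  lab <- classify_molecules(gen$snapshot, fp)
  expect_true(all(lab[gen$labels]))   # whole core found
  size <- largest_cluster(lab, gen$snapshot, fp$r_cut)
  expect_gte(size, 100)
  expect_lte(size, 100 + 0.05 * 900)
})

test_that("steady-state extraction averages the plateau and flags drift", {
  const <- steady_state_size(rep(75, 40))
  expect_equal(const$n_ss, 75)
  expect_equal(const$se, 0)
  expect_false(const$drifting)
  # ramp then noisy plateau at 238
  set.seed(3)
  ser <- c(seq(10, 238, length.out = 50),
           238 + round(rnorm(50, 0, 2)))
  ss <- steady_state_size(ser, window_fraction = 0.4)
  expect_lt(abs(ss$n_ss - 238), 1)
  expect_false(ss$drifting)
  expect_warning(drift <- steady_state_size(seq_len(60)), "drifting")
  expect_true(drift$drifting)
  expect_error(steady_state_size(rep(5, 9)), "too short")
})

test_that("largest-cluster time series runs over synthetic trajectories", {
  fp <- build_fingerprint(aligned_lattice_snapshot(27, spacing = 6), r_cut = 7)
  frames <- lapply(1:3, function(i) {
    generate_crystal_liquid_frame(27, 60, seed = i)$snapshot
  })
  ser <- largest_cluster_series(frames, fp, times = c(0, 10, 20))
  expect_equal(ser$time, c(0, 10, 20))
  expect_true(all(ser$largest_cluster >= 27))
})
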