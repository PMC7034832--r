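within_chain <- function(top, chain) {
  top$atoms$chain <- chain
  top
}

abind_frames <- function(static_xyz, trajectory) {
  nf <- n_frames(trajectory)
  na <- nrow(static_xyz) + dim(trajectory$coords)[1]
  out <- array(NA_real_, dim = c(na, 3, nf))
  for (f in seq_len(nf)) {
    out[, , f] <- rbind(static_xyz, frame_xyz(trajectory, f))
  }
  out
}

random_rotation <- function(seed = 1) {
  withr::with_seed(seed, {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, byrow = TRUE)
  })
}

test_that("superposing a structure on itself is the identity", {
  xyz <- matrix(stats::rnorm(30), ncol = 3)
  fit <- superpose(xyz, xyz, seq_len(10))
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
})

test_that("a rigidly transformed copy superposes back to zero RMSD", {
  withr::with_seed(5, {
    for (k in 1:5) {
      xyz <- matrix(stats::rnorm(30), ncol = 3)
      R <- random_rotation(seed = k)
      moved <- xyz %*% t(R) + matrix(rep(stats::rnorm(3, sd = 10),
                                         each = 10), ncol = 3)
      fit <- superpose(moved, xyz, seq_len(10))
      expect_lt(fit$rmsd, 1e-6)
      expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    }
  })
})

test_that("the fitted RMSD matches an exhaustive-orientation oracle", {
  withr::with_seed(17, {
    for (k in 1:3) {
      a <- matrix(stats::rnorm(30), ncol = 3)
      b <- matrix(stats::rnorm(30), ncol = 3)
      fit <- superpose(a, b, seq_len(10))
      expect_equal(fit$rmsd, oracle_superpose_rmsd(a, b), tolerance = 1e-4)
    }
  })
})

test_that("the fitted RMSD agrees with an independent implementation", {
  withr::with_seed(23, {
    a <- matrix(stats::rnorm(45), ncol = 3)
    b <- matrix(stats::rnorm(45), ncol = 3)
    ours <- superpose(a, b, seq_len(15))$rmsd
    theirs <- bio3d::rmsd(as.vector(t(b)), as.vector(t(a)), fit = TRUE)
    expect_equal(ours, theirs, tolerance = 1e-3)   # bio3d reports 3 decimals
  })
})

test_that("degenerate fit geometry is rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line, 1:5), "degenerate|collinear")
  expect_error(superpose(line[1:2, ], line[1:2, ], 1:2), "at least 3")
})

test_that("rmsd series separates fit and calc conventions", {
  cx <- make_test_complex()
  top <- cx$topology
  ref <- top$xyz
  nf <- 8
  coords <- array(rep(ref, nf), dim = c(nrow(ref), 3, nf))
  dna_idx <- resolve_selection(top, "dna")$indices
  # plant a rigid 5 A DNA shift (protein untouched) in every frame
  coords[dna_idx, 1, ] <- coords[dna_idx, 1, ] + 5
  tr <- new_trajectory(top, coords)
  rs <- rmsd_series(tr, "protein and name CA", "dna", reference = ref)
  expect_equal(rs$rmsd, rep(5, nf), tolerance = 1e-9)
  # identical frames -> zeros; calc = fit reproduces the superpose rmsd
  tr0 <- new_trajectory(top, array(rep(ref, 3), dim = c(nrow(ref), 3, 3)))
  expect_equal(rmsd_series(tr0, "protein and name CA", "dna",
                           reference = ref)$rmsd, rep(0, 3))
})

test_that("RMSF is zero for a static trajectory and scales linearly", {
  top <- generate_ca_protein(20)
  ref <- top$xyz
  static <- new_trajectory(top, array(rep(ref, 4), dim = c(20, 3, 4)))
  expect_equal(rmsf_profile(static, "all")$rmsf, rep(0, 20), tolerance = 1e-12)

  # doubling all displacements doubles the RMSF
  withr::with_seed(31, {
    disp <- array(stats::rnorm(20 * 3 * 10, sd = 0.3), dim = c(20, 3, 10))
  })
  base <- array(rep(ref, 10), dim = c(20, 3, 10))
  t1 <- new_trajectory(top, base + disp)
  t2 <- new_trajectory(top, base + 2 * disp)
  # fit on a distant static anchor so the comparison is exact
  anchor <- generate_ca_protein(10, start_resid = 900, radius = 60)
  ctop <- combine_topologies(anchor,
                             within_chain(top, "Q"))
  c1 <- new_trajectory(ctop, abind_frames(anchor$xyz, t1))
  c2 <- new_trajectory(ctop, abind_frames(anchor$xyz, t2))
  r1 <- rmsf_profile(c1, "resid 900-909", calc_set = "chain Q")
  r2 <- rmsf_profile(c2, "resid 900-909", calc_set = "chain Q")
  expect_equal(r2$rmsf, 2 * r1$rmsf, tolerance = 1e-9)
})

test_that("harmonic ensembles calibrate RMSF to sqrt(3) sigma", {
  # static fit anchor + noisy atoms far from the fit region
  anchor <- generate_ca_protein(10, start_resid = 1, radius = 10)
  noisy <- generate_ca_protein(40, start_resid = 101, radius = 25)
  top <- combine_topologies(anchor, within_chain(noisy, "Q"))
  sig <- c(rep(0, 10), rep(0.5, 40))
  tr <- harmonic_ensemble(top, sigmas = sig, n_frames = 600, seed = 7)
  prof <- rmsf_profile(tr, "resid 1-10", calc_set = "chain Q")
  expect_equal(mean(prof$rmsf), sqrt(3) * 0.5, tolerance = 0.05)
})

test_that("RMSD and RMSF are invariant under a global rigid transform", {
  top <- generate_ca_protein(15)
  tr <- harmonic_ensemble(top, sigmas = 0.2, n_frames = 30, seed = 9)
  R <- random_rotation(2)
  shifted <- tr
  for (f in seq_len(n_frames(tr)))
    shifted$coords[, , f] <- tr$coords[, , f] %*% t(R) +
      matrix(rep(c(3, -7, 2), each = 15), ncol = 3)
  r0 <- rmsd_series(tr, "all", "all", reference = top$xyz)
  r1 <- rmsd_series(shifted, "all", "all", reference = top$xyz)
  expect_equal(r0$rmsd, r1$rmsd, tolerance = 1e-9)
  expect_equal(rmsf_profile(tr, "all")$rmsf,
               rmsf_profile(shifted, "all")$rmsf, tolerance = 1e-9)
})

test_that("tail slicing keeps the trailing window and clips politely", {
  top <- generate_ca_protein(5)
  coords <- array(0, dim = c(5, 3, 20))
  coords[1, 1, ] <- 1:20          # encode the frame index
  tr <- new_trajectory(top, coords, dt = 100)  # 100 ps spacing -> 2 ns total
  expect_equal(slice_tail(tr, last_n_frames = 10)$coords[1, 1, ], 11:20)
  expect_equal(slice_tail(tr, last_t_ns = 1)$coords[1, 1, ], 11:20)
  expect_warning(full <- slice_tail(tr, last_n_frames = 50), "clip|keeping")
  expect_equal(n_frames(full), 20)
})

test_that("replica QC excludes exactly the divergent member, in any order", {
  cx <- make_test_complex()
  reps <- make_replica_set(cx$topology, n = 5, n_frames = 30, sigma = 0.1,
                           divergent = 2, displacement = 6, seed = 4)
  qc <- suppressMessages(
    qc_replicas(reps, "protein and name CA", "dna",
                reference = cx$topology$xyz, threshold = 4,
                tail_frames = 15))
  expect_equal(qc$status, c("pass", "excluded", "pass", "pass", "pass"))
  expect_gt(qc$mean_rmsd[2], 4)
  qc_rev <- suppressMessages(
    qc_replicas(rev(reps), "protein and name CA", "dna",
                reference = cx$topology$xyz, threshold = 4,
                tail_frames = 15))
  expect_equal(qc_rev$status, rev(qc$status))
  # threshold 0 excludes everything that moves
  qc0 <- suppressMessages(
    qc_replicas(reps, "protein and name CA", "dna",
                reference = cx$topology$xyz, threshold = 0))
  expect_true(all(qc0$status == "excluded"))
})

test_that("ring centroid distances and their KDE behave", {
  cx <- make_test_complex()
  tr <- new_trajectory(cx$topology,
                       array(rep(cx$topology$xyz, 5),
                             dim = c(nrow(cx$topology$xyz), 3, 5)))
  ring1 <- "chain A and resid 2 and name N1 C2 N3 C4 C5 C6"
  ring2 <- "chain B and resid 2 and name N1 C2 N3 C4 C5 C6"
  dd <- ring_distance_series(tr, ring1, ring2)
  expect_length(dd$samples, 5)
  expect_true(all(dd$samples == dd$samples[1]))  # static -> constant
  expect_null(dd$kde)                            # no variance, no KDE
  expect_error(ring_distance_series(tr, "none", ring2), "3 atoms")
})

test_that("KDE integrates to one, matches the normal closed form, shifts", {
  withr::with_seed(12, x <- stats::rnorm(10000))
  k <- gaussian_kde(x)
  expect_equal(predict(k, 0), 1 / sqrt(2 * pi), tolerance = 0.05)
  lo <- min(x) - 6 * k$bandwidth; hi <- max(x) + 6 * k$bandwidth
  integral <- stats::integrate(function(t) predict(k, t), lo, hi,
                               subdivisions = 1000)$value
  expect_equal(integral, 1, tolerance = 1e-3)
  k2 <- gaussian_kde(x + 3)
  grid <- seq(-2, 2, by = 0.5)
  expect_equal(predict(k2, grid + 3), predict(k, grid), tolerance = 1e-12)
  expect_error(gaussian_kde(rep(1, 10)), "zero variance")
})

test_that("a KDE mode recovers a planted distance distribution", {
  withr::with_seed(3, d <- stats::rnorm(4000, mean = 6, sd = 0.3))
  k <- gaussian_kde(d)
  grid <- seq(4, 8, by = 0.005)
  expect_equal(grid[which.max(predict(k, grid))], 6, tolerance = 0.1)
})
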