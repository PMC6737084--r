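test_that("RMS fit removes rigid rotations and leaves identity alone", {
  traj <- random_trajectory(n_atoms = 8, n_frames = 1, seed = 5)
  base <- frame_coords(traj, 1)
  coords <- array(0, dim = c(4, 8, 3))
  coords[1, , ] <- base
  for (k in 2:4) {
    coords[k, , ] <- sweep(base %*% t(random_rotation(k)), 2,
                           c(k, -k, 2 * k), "+")
  }
  rot_traj <- new_trajectory(traj$topology, coords)
  fitted <- rms_fit_trajectory(rot_traj, traj$topology$atom_id)
  for (k in 2:4) {
    expect_lt(rmsd(frame_coords(fitted, k), base), 1e-8)
  }
  # an already-aligned trajectory is unchanged
  same <- new_trajectory(traj$topology,
                         array(rep(base, each = 3), dim = c(3, 8, 3)))
  refit <- rms_fit_trajectory(same, traj$topology$atom_id)
  expect_lt(max(abs(refit$coords - same$coords)), 1e-10)
})

test_that("fitted per-frame RMSD matches the quaternion oracle", {
  traj <- random_trajectory(n_atoms = 10, n_frames = 5, seed = 11)
  fitted <- rms_fit_trajectory(traj, traj$topology$atom_id)
  ref <- frame_coords(traj, 1)
  for (k in 2:5) {
    got <- rmsd(ref, frame_coords(fitted, k))
    want <- oracle_rmsd(ref, frame_coords(traj, k), fit = TRUE)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("collinear fit references are rejected", {
  top <- make_topology("CA", 1:4, element = "C")
  coords <- array(0, dim = c(2, 4, 3))
  coords[, , 1] <- matrix(rep(1:4, each = 2), 2, 4, byrow = FALSE)
  traj <- new_trajectory(top, coords)
  expect_error(rms_fit_trajectory(traj, 1:4), "collinear")
})

test_that("covariance follows the dot-product definition", {
  # a fixed atom contributes a zero row/column
  top <- make_topology("CA", 1:2, element = "C")
  coords <- array(0, dim = c(4, 2, 3))
  coords[, 2, 1] <- c(-1, 1, -1, 1)      # atom 2 oscillates on x
  traj <- new_trajectory(top, coords)
  cov <- covariance_matrix(traj)
  expect_equal(cov$values[1, ], c(0, 0))
  expect_equal(cov$values[2, 2], 1)       # variance of +/-1 is 1 A^2
  expect_error(covariance_matrix(traj, window = c(1, 1)), "insufficient")
})

test_that("covariance and cross-correlation equal the double-loop oracle", {
  traj <- random_trajectory(n_atoms = 6, n_frames = 50, seed = 21)
  cov <- covariance_matrix(traj)
  cc <- cross_correlation_matrix(cov)
  want <- oracle_cov_cc(traj$coords)
  expect_lt(max(abs(cov$values - want$cov)), 1e-12)
  expect_lt(max(abs(cc$values - want$cc)), 1e-12)
})

test_that("lockstep and mirrored motion hit the +/-1 correlation limits", {
  top <- make_topology("CA", 1:3, element = "C")
  coords <- array(0, dim = c(20, 3, 3))
  set.seed(4)
  disp <- rnorm(20)
  coords[, 1, 1] <- disp
  coords[, 2, 1] <- disp + 5          # mirrors atom 1 exactly
  coords[, 3, 1] <- -disp             # negated displacement
  cc <- cross_correlation_matrix(covariance_matrix(new_trajectory(top, coords)))
  expect_equal(cc$values[1, 2], 1)
  expect_equal(cc$values[1, 3], -1)
})

test_that("zero-variance atoms are flagged, not NaN-propagated", {
  top <- make_topology("CA", 1:2, element = "C")
  coords <- array(0, dim = c(5, 2, 3))
  coords[, 2, 2] <- rnorm(5)
  expect_warning(
    cc <- cross_correlation_matrix(covariance_matrix(new_trajectory(top, coords))),
    "zero-variance")
  expect_equal(cc$zero_variance_atoms, 1L)
  expect_false(anyNA(cc$values))
  expect_equal(cc$values[1, 2], 0)
})

make_cc_fixture <- function(values, nres) {
  # wrap a residue-level CC matrix in the package types
  top <- make_topology("CA", seq_len(nres), element = "C")
  structure(list(values = values, atom_ids = seq_len(nres),
                 zero_variance_atoms = integer(0)),
            class = "cross_correlation")
}

test_that("segment scores discard the sub-threshold band and normalize by density", {
  segs <- make_segment_map(c("A", "B"), c(1, 4), c(3, 5))
  cc <- diag(5)
  cc[1:3, 4:5] <- 0.5; cc[4:5, 1:3] <- 0.5
  tab <- segment_correlation_score(make_cc_fixture(cc, 5),
                                   make_topology("CA", 1:5, element = "C"),
                                   segs)
  expect_equal(tab$score, 0)              # all pairs inside the noise band
  expect_equal(tab$n_contributing_pairs, 0L)

  # single-residue segments: normalizer is 1 x 1
  segs1 <- make_segment_map(c("A", "B"), c(1, 2), c(1, 2))
  cc1 <- matrix(c(1, 0.8, 0.8, 1), 2)
  tab1 <- segment_correlation_score(make_cc_fixture(cc1, 2),
                                    make_topology("CA", 1:2, element = "C"),
                                    segs1)
  expect_equal(tab1$score, 0.8)
})

test_that("segment scores equal a brute-force filter-sum-normalize oracle", {
  set.seed(8)
  segs <- make_segment_map(c("A", "B"), c(1, 4), c(3, 5))
  cc <- matrix(runif(25, -1, 1), 5); cc <- (cc + t(cc)) / 2; diag(cc) <- 1
  thr <- 0.6
  tab <- segment_correlation_score(make_cc_fixture(cc, 5),
                                   make_topology("CA", 1:5, element = "C"),
                                   segs, threshold = thr)
  # oracle: loop over all residue pairs of the 3 x 2 block
  s <- 0; contrib_i <- c(); contrib_j <- c(); npairs <- 0
  for (i in 1:3) for (j in 4:5) {
    if (abs(cc[i, j]) >= thr) {
      s <- s + cc[i, j]; npairs <- npairs + 1
      contrib_i <- union(contrib_i, i); contrib_j <- union(contrib_j, j)
    }
  }
  want <- if (npairs == 0) 0 else
    s / (length(contrib_i) * length(contrib_j))
  expect_equal(tab$score, want)
  expect_equal(tab$n_contributing_pairs, npairs)
})

test_that("raising the threshold never adds contributing pairs", {
  set.seed(9)
  segs <- make_segment_map(c("A", "B"), c(1, 5), c(4, 8))
  cc <- matrix(runif(64, -1, 1), 8); cc <- (cc + t(cc)) / 2; diag(cc) <- 1
  fix <- make_cc_fixture(cc, 8)
  top <- make_topology("CA", 1:8, element = "C")
  prev <- Inf
  for (thr in c(0.2, 0.4, 0.6, 0.8)) {
    n <- segment_correlation_score(fix, top, segs,
                                   threshold = thr)$n_contributing_pairs
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("per-residue profiles sum thresholded couplings to the focus segment", {
  segs <- make_segment_map(c("H12", "rest"), c(1, 3), c(2, 6))
  top <- make_topology("CA", 1:6, element = "C")
  # identically-zero CC: all-zero profile
  cc0 <- diag(6) * 0
  prof0 <- per_residue_profile(make_cc_fixture(cc0, 6), top, "H12", segs)
  expect_equal(prof0$score, rep(0, 4))
  # a single supra-threshold coupling shows up alone
  cc1 <- diag(6)
  cc1[4, 1] <- cc1[1, 4] <- 0.9
  cc1[5, 2] <- cc1[2, 5] <- 0.4
  prof1 <- per_residue_profile(make_cc_fixture(cc1, 6), top, "H12", segs)
  expect_equal(prof1$score[prof1$residue_index == 4], 0.9)
  expect_equal(sum(prof1$score != 0), 1)
  # random matrix: brute-force oracle
  set.seed(10)
  ccr <- matrix(runif(36, -1, 1), 6); ccr <- (ccr + t(ccr)) / 2; diag(ccr) <- 1
  prof <- per_residue_profile(make_cc_fixture(ccr, 6), top, "H12", segs)
  for (r in 3:6) {
    want <- sum(ccr[r, 1:2][abs(ccr[r, 1:2]) >= 0.6])
    expect_equal(prof$score[prof$residue_index == r], want)
  }
})

test_that("cross-correlation invariants hold on generated trajectories", {
  for (seed in 1:3) {
    traj <- random_trajectory(n_atoms = 7, n_frames = 40, seed = seed)
    cc <- cross_correlation_matrix(covariance_matrix(traj))
    expect_lt(max(abs(cc$values - t(cc$values))), 1e-12)
    expect_true(all(cc$values >= -1 & cc$values <= 1))
    expect_equal(diag(cc$values), rep(1, 7), tolerance = 1e-12)
  }
})

test_that("a global rigid transform leaves the post-fit correlation unchanged", {
  traj <- random_trajectory(n_atoms = 9, n_frames = 60, seed = 14)
  sel <- traj$topology$atom_id
  cc_ref <- cross_correlation_matrix(
    covariance_matrix(rms_fit_trajectory(traj, sel)))
  # one arbitrary rotation+translation applied to every frame
  moved <- transform_trajectory(traj, random_rotation(77), c(12, -3, 8))
  cc_moved <- cross_correlation_matrix(
    covariance_matrix(rms_fit_trajectory(moved, sel)))
  expect_lt(max(abs(cc_ref$values - cc_moved$values)), 1e-8)
})

test_that("block correlations are recovered from synthetic trajectories", {
  segs <- make_segment_map(c("S1", "S2"), c(1, 6), c(5, 10))
  for (rho in c(-0.8, 0, 0.8)) {
    gen <- generate_correlated_trajectory(
      segs, within_block_rho = 0.9,
      cross_block_rho = list("S1:S2" = rho), n_frames = 4000, seed = 30)
    cc <- cross_correlation_matrix(covariance_matrix(gen$trajectory))
    est <- mean(cc$values[1:5, 6:10])
    expect_lt(abs(est - rho), 0.05)
    score <- segment_correlation_score(cc, gen$topology, segs)$score
    if (abs(rho) >= 0.6) expect_true(score != 0) else expect_equal(score, 0)
  }
})

test_that("eigen summary accounts for all positional variance", {
  traj <- random_trajectory(n_atoms = 6, n_frames = 30, seed = 2)
  cov <- covariance_matrix(traj)
  es <- covariance_eigen(cov)
  expect_equal(sum(es$eigenvalue), sum(diag(cov$values)))
  expect_equal(es$cumulative_fraction[nrow(es)], 1)
  expect_true(all(diff(es$eigenvalue) <= 1e-12))
})
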