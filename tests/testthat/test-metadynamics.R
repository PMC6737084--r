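test_that("the rational switch gives the coordination-number limits", {
  frame <- rbind(c(0, 0, 0), c(0.01, 0, 0))
  spec <- cv_spec("coordination_number", 1L, 2L, r0 = 3)
  expect_equal(coordination_number(frame, spec), 1, tolerance = 1e-6)
  far <- rbind(c(0, 0, 0), c(500, 0, 0))
  expect_lt(coordination_number(far, spec), 1e-10)
  # removable singularity at r = r0: s = n/m = 0.5 for n = 6, m = 12
  at_r0 <- rbind(c(0, 0, 0), c(3, 0, 0))
  expect_equal(coordination_number(at_r0, spec), 0.5)
})

test_that("centre-of-mass distance is mass-weighted and reported in nm", {
  spec <- cv_spec("com_distance", 1:2, 3:4)
  frame <- rbind(c(0, 0, 0), c(0, 0, 0), c(30, 0, 0), c(30, 0, 0))
  expect_equal(com_distance(frame, rep(1, 4), spec), 3)   # 30 A = 3 nm
  expect_equal(com_distance(frame[c(1, 2, 1, 2), ], rep(1, 4), spec), 0)
  # random two-group system vs a hand-rolled centroid oracle
  set.seed(61)
  fr <- matrix(rnorm(18, sd = 5), 6, 3)
  masses <- runif(6, 1, 16)
  sp <- cv_spec("com_distance", 1:3, 4:6)
  ca <- colSums(fr[1:3, ] * masses[1:3]) / sum(masses[1:3])
  cb <- colSums(fr[4:6, ] * masses[4:6]) / sum(masses[4:6])
  expect_equal(com_distance(fr, masses, sp),
               sqrt(sum((ca - cb)^2)) / 10, tolerance = 1e-12)
  expect_error(com_distance(frame, rep(0, 4), spec), "positive")
})

test_that("cv specs validate their invariants", {
  expect_error(cv_spec("coordination_number", 1L, 1L), "disjoint")
  expect_error(cv_spec("coordination_number", 1L, 2L, r0 = 0), "r0")
  expect_error(cv_spec("coordination_number", 1L, 2L, n = 12, m = 6),
               "m > n")
  expect_error(cv_spec("coordination_number", integer(0), 2L), "non-empty")
})

test_that("hill deposition produces the Gaussian bias it claims", {
  hills <- NULL
  hills <- deposit_hill(hills, c(0.5, 1.2), widths = c(0.06, 0.015),
                        height = 0.6, step = 800)
  # bias at the centre of a single hill equals the configured height
  expect_equal(bias_potential(hills, c(0.5, 1.2)), 0.6)
  # >= 8 sigma away the Gaussian has decayed below 1e-10
  expect_lt(bias_potential(hills, c(0.5 + 8 * 0.06, 1.2)), 1e-10 * 0.6)

  # bias on a grid after 50 hills equals a per-hill summation oracle
  set.seed(62)
  centers <- cbind(runif(50, -1, 1), runif(50, 0, 2))
  h50 <- hill_set(centers, widths = c(0.1, 0.2), height = 0.6)
  pts <- as.matrix(expand.grid(seq(-1, 1, length.out = 11),
                               seq(0, 2, length.out = 11)))
  got <- bias_potential(h50, pts)
  want <- numeric(nrow(pts))
  for (k in 1:50) {
    want <- want + 0.6 * exp(-((pts[, 1] - centers[k, 1])^2 / (2 * 0.1^2) +
                                 (pts[, 2] - centers[k, 2])^2 / (2 * 0.2^2)))
  }
  expect_lt(max(abs(got - want)), 1e-12)
})

test_that("the one-sided harmonic wall is zero below and quadratic above", {
  expect_equal(harmonic_wall_force(3.0, 3.5, 1000)$energy, 0)
  expect_equal(harmonic_wall_force(3.5, 3.5, 1000)$gradient, 0)
  w <- harmonic_wall_force(3.5 + 0.02, 3.5, 1000)
  expect_equal(w$energy, 1000 * 0.02^2)
  expect_equal(w$gradient, 2 * 1000 * 0.02)
})

dw_grid <- list(list(min = -2.2, max = 2.2, n = 881))

test_that("zero-temperature, zero-bias dynamics stays at a minimum", {
  pot <- make_toy_potential("double_well_1d", h = 10)
  cfg <- mtd_config(hill_height = 0.6, hill_widths = 0.1, pace = 1e9,
                    temperature = 1e-12, total_steps = 2000, grid = dw_grid,
                    x0 = 1, seed = 3)
  run <- run_langevin_mtd(pot, cfg)
  expect_lt(max(abs(run$cv_traj$cv1 - 1)), 1e-6)
  expect_equal(nrow(run$hills), 0)
})

test_that("unbiased sampling of a harmonic well satisfies equipartition", {
  k <- 10
  pot <- make_toy_potential("harmonic", k = k)
  cfg <- mtd_config(hill_height = 0.6, hill_widths = 0.1, pace = 1e9,
                    temperature = 310, total_steps = 1e6, dt = 0.005,
                    friction = 2, grid = list(list(min = -5, max = 5, n = 501)),
                    x0 = 0, seed = 4)
  run <- run_langevin_mtd(pot, cfg, cv_stride = 5L)
  kT <- KB_KJ_MOL_K * 310
  v <- stats::var(run$cv_traj$cv1[run$cv_traj$step > 1e4])
  expect_lt(abs(v - kT / k) / (kT / k), 0.05)
})

test_that("metadynamics runs are bit-identical under a fixed seed", {
  pot <- make_toy_potential("double_well_1d", h = 8)
  cfg <- mtd_config(hill_height = 0.6, hill_widths = 0.1, pace = 200,
                    temperature = 310, total_steps = 20000, grid = dw_grid,
                    x0 = -1, seed = 11)
  r1 <- run_langevin_mtd(pot, cfg)
  r2 <- run_langevin_mtd(pot, cfg)
  expect_identical(r1$hills, r2$hills)
  expect_identical(r1$cv_traj, r2$cv_traj)
  f1 <- reconstruct_fes(r1$hills, dw_grid)
  f2 <- reconstruct_fes(r2$hills, dw_grid)
  expect_identical(f1$values, f2$values)
})

test_that("bias only grows as hills accumulate", {
  pot <- make_toy_potential("double_well_1d", h = 8)
  cfg <- mtd_config(hill_height = 0.6, hill_widths = 0.1, pace = 200,
                    temperature = 310, total_steps = 20000, grid = dw_grid,
                    x0 = -1, seed = 12)
  run <- run_langevin_mtd(pot, cfg)
  pts <- matrix(seq(-2, 2, length.out = 41), ncol = 1)
  prev <- numeric(41)
  for (n in c(10, 40, 70, nrow(run$hills))) {
    cur <- bias_potential(run$hills[seq_len(n), ], pts)
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})

test_that("FES reconstruction inverts the bias with min shifted to zero", {
  hills <- deposit_hill(NULL, 0.3, widths = 0.1, height = 0.6)
  grid <- list(list(min = -1, max = 1.5, n = 251))
  fes <- reconstruct_fes(hills, grid)
  # single hill: F(s) = h (1 - exp(-(s-c)^2 / 2 sigma^2)), depth = height
  x <- fes$axes[[1]]
  want <- 0.6 * (1 - exp(-(x - 0.3)^2 / (2 * 0.1^2)))
  expect_lt(max(abs(fes$values - want)), 1e-10)
  expect_equal(min(fes$values), 0)
  expect_equal(max(fes$values), 0.6, tolerance = 1e-6)
  expect_error(reconstruct_fes(NULL, grid), "empty")
})

test_that("a uniform hill carpet reconstructs to a flat surface", {
  centers <- matrix(seq(-2, 2, by = 0.05), ncol = 1)
  hills <- hill_set(centers, widths = 0.1, height = 0.6)
  fes <- reconstruct_fes(hills, list(list(min = -1, max = 1, n = 201)))
  expect_lt(max(fes$values) - min(fes$values), 0.05 * 0.6)
})

test_that("barrier extraction picks the unique path maximum in 1-D", {
  x <- seq(-2, 2, length.out = 401)
  vals <- 10 * exp(-(x)^2 / 0.02) + ifelse(x > 0, -3, 0) # basins 0 and -3, peak 10
  vals <- vals - min(vals)
  fes <- structure(list(values = vals, axes = list(x),
                        grid = list(list(min = -2, max = 2, n = 401))),
                   class = "free_energy_surface")
  b <- estimate_barrier(fes, list(c(-2, -1)), list(c(1, 2)))
  expect_equal(attr(b, "kJ_mol"), max(vals) - min(vals[x >= -2 & x <= -1]))
  # flat FES: zero barrier
  flat <- structure(list(values = rep(0, 401), axes = list(x),
                         grid = fes$grid), class = "free_energy_surface")
  expect_equal(as.numeric(estimate_barrier(flat, list(c(-2, -1)),
                                           list(c(1, 2)))), 0)
  expect_error(estimate_barrier(fes, list(c(-2, 0)), list(c(-0.5, 2))),
               "overlap")
})

test_that("the lower of two channel saddles is selected on a 2-D surface", {
  pot <- make_toy_potential("two_channel_2d", h1 = 10, h2 = 20)
  ax <- seq(-1.5, 1.5, by = 0.05)
  vals <- outer(ax, ax, Vectorize(function(x, y) pot$energy(c(x, y))))
  fes <- structure(list(values = vals, axes = list(ax, ax),
                        grid = list(list(min = -1.5, max = 1.5, n = length(ax)),
                                    list(min = -1.5, max = 1.5, n = length(ax)))),
                   class = "free_energy_surface")
  b <- estimate_barrier(fes, list(c(-1.1, -0.9), c(0.9, 1.1)),
                        list(c(0.9, 1.1), c(0.9, 1.1)))
  expect_equal(attr(b, "kJ_mol"), 10, tolerance = 1e-6)
  expect_equal(as.numeric(b), 10 / 4.184, tolerance = 1e-6)
  # exhaustive minimax-path oracle on a coarse version of the same surface
  axc <- seq(-1.5, 1.5, by = 0.25)
  vc <- outer(axc, axc, Vectorize(function(x, y) pot$energy(c(x, y))))
  fesc <- structure(list(values = vc, axes = list(axc, axc),
                         grid = list(list(min = -1.5, max = 1.5, n = length(axc)),
                                     list(min = -1.5, max = 1.5, n = length(axc)))),
                    class = "free_energy_surface")
  bc <- estimate_barrier(fesc, list(c(-1.1, -0.9), c(0.9, 1.1)),
                         list(c(0.9, 1.1), c(0.9, 1.1)))
  start <- c(which.min(abs(axc + 1)), which.min(abs(axc - 1)))
  goal <- c(which.min(abs(axc - 1)), which.min(abs(axc - 1)))
  want <- oracle_minimax(vc, start, goal) - vc[start[1], start[2]]
  expect_equal(attr(bc, "kJ_mol"), want, tolerance = 1e-10)
})

test_that("standard metadynamics recovers the analytic double-well barrier", {
  kT <- KB_KJ_MOL_K * 310
  h <- 5 * kT
  pot <- make_toy_potential("double_well_1d", h = h)
  rel_err <- vapply(1:3, function(seed) {
    cfg <- mtd_config(hill_height = 0.6, hill_widths = 0.1, pace = 500,
                      temperature = 310, total_steps = 6e5, grid = dw_grid,
                      x0 = -1, seed = seed)
    run <- run_langevin_mtd(pot, cfg)
    fes <- reconstruct_fes(run$hills, dw_grid)
    b <- estimate_barrier(fes, list(c(-1.4, -0.6)), list(c(0.6, 1.4)))
    attr(b, "kJ_mol")
  }, numeric(1))
  expect_lt(abs(mean(rel_err) - h) / h, 0.15)
})

test_that("replica aggregation reports mean and sample sd", {
  est <- aggregate_replicas(c(12, 14, 16))
  expect_equal(est$mean, 14)
  expect_equal(est$sd, 2)
  single <- aggregate_replicas(14.1)
  expect_true(is.na(single$sd))
  expect_equal(single$mean, 14.1)
  set.seed(71)
  x <- rnorm(5, 10, 3)
  est5 <- aggregate_replicas(x)
  expect_equal(est5$mean, sum(x) / 5)
  expect_equal(est5$sd, sqrt(sum((x - mean(x))^2) / 4))
  expect_error(aggregate_replicas(numeric(0)), "no replica")
  expect_equal(glance(est)$sd, 2)
  expect_equal(nrow(tidy(est5)), 5)
})

test_that("reference settings round-trip exactly through config serialization", {
  grid2 <- list(list(min = 0, max = 12, n = 100),
                list(min = 0.5, max = 4, n = 100))
  cfg <- mtd_config(hill_height = 0.6, hill_widths = c(0.06, 0.015),
                    pace = 800, temperature = 310, total_steps = 1e5,
                    wall = list(cv_index = 2, position = 3.5, kappa = 1000),
                    grid = grid2, x0 = c(5, 1.2), seed = 7)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_mtd_config(cfg, path)
  back <- read_mtd_config(path)
  expect_identical(back$hill_height, 0.6)
  expect_identical(back$hill_widths, c(0.06, 0.015))
  expect_identical(back$pace, 800L)
  expect_identical(back$wall$position, 3.5)
  expect_equal(back$temperature, 310)
  expect_equal(unclass(back), unclass(cfg), ignore_attr = TRUE)
})

test_that("hill lists round-trip through the HILLS text dialect", {
  set.seed(72)
  hills <- hill_set(cbind(runif(20), runif(20)), widths = c(0.4, 0.025),
                    height = 0.6, deposit_step = seq(800, by = 800,
                                                     length.out = 20))
  path <- withr::local_tempfile()
  write_hills(hills, path)
  expect_match(readLines(path, n = 1), "^#! FIELDS time cv1 cv2")
  back <- read_hills(path)
  expect_equal(back$center_1, hills$center_1, tolerance = 1e-14)
  expect_equal(back$height, hills$height)
  expect_equal(back$step, hills$step)
})

test_that("the wall confines the dissociation coordinate", {
  pot <- make_toy_potential("harmonic", k = 0.5)
  cfg <- mtd_config(hill_height = 0.6, hill_widths = 0.2, pace = 100,
                    temperature = 310, total_steps = 5e4,
                    wall = list(cv_index = 1, position = 3, kappa = 1000),
                    grid = list(list(min = -6, max = 6, n = 601)),
                    x0 = 0, seed = 13)
  run <- run_langevin_mtd(pot, cfg)
  expect_lt(max(run$cv_traj$cv1), 3.3)
})

test_that("chain-rule bias forces match a finite-difference oracle", {
  pot <- make_toy_potential("host_guest")
  run <- run_hostguest_mtd(pot, total_steps = 300, pace = 25, seed = 21)
  expect_gt(nrow(run$hills), 0)
  frame <- rbind(c(0.4, -0.2, 0.3), pot$host_coords)
  masses <- run$masses
  force <- hostguest_bias_force(run$hills, frame, run$cv1, run$cv2, masses)
  eps <- 1e-6
  num <- vapply(1:3, function(d) {
    fp <- frame; fp[1, d] <- fp[1, d] + eps
    fm <- frame; fm[1, d] <- fm[1, d] - eps
    cvp <- c(coordination_number(fp, run$cv1),
             com_distance(fp, masses, run$cv2))
    cvm <- c(coordination_number(fm, run$cv1),
             com_distance(fm, masses, run$cv2))
    -(bias_potential(run$hills, cvp) - bias_potential(run$hills, cvm)) /
      (2 * eps)
  }, numeric(1))
  expect_equal(force, num, tolerance = 1e-6)
})

test_that("host-guest runs are reproducible under a fixed seed", {
  pot <- make_toy_potential("host_guest")
  r1 <- run_hostguest_mtd(pot, total_steps = 200, seed = 5)
  r2 <- run_hostguest_mtd(pot, total_steps = 200, seed = 5)
  expect_identical(r1$hills, r2$hills)
  expect_identical(r1$guest_traj, r2$guest_traj)
})
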