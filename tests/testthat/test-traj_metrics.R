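test_that("Kabsch superposition recovers identity and known rotations", {
  set.seed(12)
  X <- matrix(stats::rnorm(30), 10, 3)
  fit <- kabsch_superpose(X, X)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)

  th <- 30 * pi / 180
  R30 <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  Y <- rigid_transform_points(X, R30, c(1, -2, 3))
  fit2 <- kabsch_superpose(X, Y)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit2$rotation, t(R30), tolerance = 1e-6)

  expect_error(kabsch_superpose(X, X[1:5, ]), "mismatch")
  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("mirror images are not superposed by reflection", {
  set.seed(13)
  for (i in 1:5) {
    X <- matrix(stats::rnorm(12), 4, 3)
    Y <- X %*% diag(c(-1, 1, 1))  # reflected copy
    fit <- kabsch_superpose(X, Y)
    expect_gt(fit$rmsd, 1e-6)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

    # dense rotation-grid oracle over proper rotations only: the Kabsch
    # result must beat or match every grid rotation, and come within the
    # grid resolution of the best one. rmsd^2 is linear in R so the grid
    # evaluates as inner products.
    Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
    S <- t(Xc) %*% Yc
    c0 <- mean(rowSums(Xc^2)) + mean(rowSums(Yc^2))
    step <- pi / 36  # 5 degrees
    best_grid <- Inf
    for (a in seq(0, 2 * pi - step, step))
      for (b in seq(0, pi, step))
        for (g in seq(0, 2 * pi - step, step)) {
          Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                        3, 3, byrow = TRUE)
          Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)),
                       3, 3, byrow = TRUE)
          Rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1),
                        3, 3, byrow = TRUE)
          R <- Rz1 %*% Ry %*% Rz2
          r2 <- c0 - 2 * sum(S * R) / nrow(X)
          if (r2 < best_grid) best_grid <- r2
        }
    best_grid <- sqrt(max(best_grid, 0))
    expect_lte(fit$rmsd, best_grid + 1e-9)
    # grid can only overshoot by its angular resolution: compare squared
    # RMSDs, which differ by at most O(step^2) times the point scale
    expect_lt(best_grid^2 - fit$rmsd^2, 0.01)
  }
})

test_that("RMSD series is zero for static or rigidly rotated trajectories", {
  spec <- generator_spec(seed = 6, traj = list(n_residues = 40,
                                               n_frames = 10,
                                               core_sigma = 0))
  traj <- gen_trajectory(spec)
  rs <- rmsd_series(traj)
  expect_equal(rs$rmsd_A, rep(0, 10), tolerance = 1e-12)
  expect_equal(rs$time_ps, seq(0, 90, 10))

  # rigid rotations of the reference frame vanish under superposition
  set.seed(61)
  rot_frames <- lapply(1:8, function(i)
    rigid_transform_points(traj$frames[[1]], random_rotation(),
                           stats::rnorm(3, sd = 5)))
  rtraj <- trajectory(traj$atom_meta, rot_frames, 10)
  expect_lt(max(rmsd_series(rtraj)$rmsd_A), 1e-6)

  # and the whole series is invariant to a global rigid transform
  spec2 <- generator_spec(seed = 6, traj = list(n_residues = 40,
                                                n_frames = 10))
  jtraj <- gen_trajectory(spec2)
  R <- random_rotation(); tv <- c(4, -2, 9)
  moved <- trajectory(jtraj$atom_meta,
                      lapply(jtraj$frames, rigid_transform_points, R, tv),
                      10)
  expect_equal(rmsd_series(moved)$rmsd_A, rmsd_series(jtraj)$rmsd_A,
               tolerance = 1e-8)
})

test_that("isotropic jitter gives mean RMSD of sigma*sqrt(3) without fitting", {
  sigma <- 0.25
  spec <- generator_spec(seed = 8, traj = list(
    n_residues = 200, n_frames = 100, core_sigma = sigma,
    terminal_multiplier = 1))
  traj <- gen_trajectory(spec)
  # reference = the noise-free structure: regenerate with zero jitter
  ref <- gen_trajectory(generator_spec(seed = 8, traj = list(
    n_residues = 200, n_frames = 1, core_sigma = 0)))$frames[[1]]
  traj0 <- trajectory(traj$atom_meta, c(list(ref), traj$frames), 10)
  rs <- rmsd_series(traj0, ref = 1, superpose = FALSE)
  expect_equal(mean(rs$rmsd_A[-1]), sigma * sqrt(3),
               tolerance = 0.05)
  # nm reporting is Angstrom / 10
  expect_equal(rs$rmsd_nm, rs$rmsd_A / 10)
})

test_that("superposed RMSD never exceeds in-place RMSD", {
  traj <- gen_trajectory(generator_spec(seed = 14, traj = list(
    n_residues = 50, n_frames = 20)))
  on <- rmsd_series(traj, superpose = TRUE)$rmsd_A
  off <- rmsd_series(traj, superpose = FALSE)$rmsd_A
  expect_true(all(on <= off + 1e-10))
})

test_that("RMSF matches the closed form and flags floppy termini", {
  traj <- gen_trajectory(generator_spec(seed = 15))
  rf <- rmsf_per_residue(traj)
  p <- generator_spec()$traj
  core <- rf$res_index > p$n_terminal &
    rf$res_index <= p$n_residues - p$n_terminal
  # uniform-core closed form: sigma * sqrt(3)
  expect_equal(mean(rf$rmsf_A[core]), p$core_sigma * sqrt(3),
               tolerance = 0.10)
  # every terminal residue fluctuates more than every core residue
  expect_gt(min(rf$rmsf_A[!core]), max(rf$rmsf_A[core]))

  # static trajectory has zero RMSF; single frame is rejected
  st <- gen_trajectory(generator_spec(seed = 1, traj = list(
    n_residues = 20, n_frames = 5, core_sigma = 0)))
  expect_equal(max(rmsf_per_residue(st)$rmsf_A), 0, tolerance = 1e-12)
  one <- trajectory(st$atom_meta, st$frames[1], 10)
  expect_error(rmsf_per_residue(one), "2 frames")
})

test_that("RMSF is invariant to frame-order permutation", {
  traj <- gen_trajectory(generator_spec(seed = 16, traj = list(
    n_residues = 30, n_frames = 15)))
  set.seed(16)
  perm <- sample(length(traj$frames))
  shuffled <- trajectory(traj$atom_meta, traj$frames[perm], 10)
  expect_equal(rmsf_per_residue(shuffled)$rmsf_A,
               rmsf_per_residue(traj)$rmsf_A, tolerance = 1e-9)
})

test_that("multi-model PDB round trip and independent RMSD cross-check", {
  traj <- gen_trajectory(generator_spec(seed = 17, traj = list(
    n_residues = 25, n_frames = 6)))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_trajectory(traj, path)
  back <- read_pdb_trajectory(path)
  expect_length(back$frames, 6L)
  expect_equal(back$frames[[3]], traj$frames[[3]], tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_true(all(back$atom_meta$is_ca))

  # bio3d computes the same fitted RMSD between two frames
  A <- traj$frames[[1]]; B <- traj$frames[[2]]
  ref_rmsd <- bio3d::rmsd(as.numeric(t(A)), as.numeric(t(B)),
                          fit = TRUE)
  expect_equal(kabsch_superpose(B, A)$rmsd, ref_rmsd, tolerance = 1e-3)
})

test_that("XYZ trajectories read back what was written", {
  traj <- gen_trajectory(generator_spec(seed = 18, traj = list(
    n_residues = 10, n_frames = 3)))
  path <- withr::local_tempfile(fileext = ".xyz")
  lines <- character()
  for (fr in traj$frames) {
    lines <- c(lines, "10", "frame",
               sprintf("C %.6f %.6f %.6f", fr[, 1], fr[, 2], fr[, 3]))
  }
  writeLines(lines, path)
  back <- read_xyz_trajectory(path)
  expect_length(back$frames, 3L)
  expect_equal(back$frames[[2]], traj$frames[[2]], tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_error(rmsd_series(back, selection = rep(FALSE, 10)),
               "empty")
})
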