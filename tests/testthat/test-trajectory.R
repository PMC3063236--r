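test_that("multi-model PDB files round-trip through read_trajectory", {
  f <- withr::local_tempfile(fileext = ".pdb")
  g <- make_gaussian_trajectory(gaussian_traj_spec(6, 25, 0.04),
                                seed = 2, path = f)
  tr <- read_trajectory(f, atom_names = "CA")
  expect_equal(tr$n_frames, 25)
  expect_equal(tr$n_atoms, 6)
  expect_equal(tr$frames, g$traj$frames, tolerance = 1e-3)
  expect_error(read_trajectory(f, atom_names = "XX"), "no atoms")
})

test_that("backbone selection resolves 3 atoms per loop residue", {
  hp <- hairpin_g()
  s <- hp$struct
  s$xyz <- rbind(s$xyz, s$xyz + 0.1)  # fabricate a 2nd frame
  s$nmodels <- 2L
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  tr <- read_trajectory(f, chain = "A", resno = 104:119,
                        atom_names = c("N", "CA", "C"))
  expect_equal(tr$n_atoms, 3 * 14)  # 14-residue loop
  expect_equal(tr$n_frames, 2)
})

test_that("rmsd series is zero for self and rigidly rotated frames", {
  set.seed(21)
  ref <- matrix(rnorm(36), ncol = 3)
  frames <- rbind(as.vector(t(ref)), as.vector(t(ref)))
  tr <- trajectory_ensemble(frames, rep(12.011, 12))
  expect_equal(rmsd_series(tr, reference = ref)$rmsd, c(0, 0),
               tolerance = 1e-9)

  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
              3, byrow = TRUE)
  rot <- sweep(ref %*% R, 2, c(3, 3, 3), `+`)
  tr2 <- trajectory_ensemble(rbind(as.vector(t(ref)), as.vector(t(rot))),
                             rep(12.011, 12))
  expect_equal(rmsd_series(tr2, reference = ref)$rmsd, c(0, 0),
               tolerance = 1e-9)
})

test_that("a single displaced atom gives rmsd d/sqrt(n)", {
  set.seed(22)
  ref <- matrix(rnorm(30) * 3, ncol = 3)
  d <- 0.9
  fr <- ref; fr[1, ] <- fr[1, ] + c(d, 0, 0)
  tr <- trajectory_ensemble(matrix(as.vector(t(fr)), nrow = 3,
                                   ncol = 30, byrow = TRUE),
                            rep(12.011, 10))
  r <- rmsd_series(tr, reference = ref, fit_idx = 2:10)
  expect_equal(r$rmsd, rep(d / sqrt(10), 3), tolerance = 1e-9)
})

test_that("a frozen ensemble has zero entropy", {
  base <- as.vector(t(cbind(cos(1:6), sin(1:6), 1.5 * (1:6))))
  tr <- trajectory_ensemble(matrix(base, nrow = 10, ncol = 18,
                                   byrow = TRUE), rep(12.011, 6))
  e <- suppressWarnings(quasiharmonic_entropy(tr))
  expect_equal(e$entropy, 0)
  expect_equal(e$n_modes_used, 0)
  expect_error(quasiharmonic_entropy(
    trajectory_ensemble(matrix(base, nrow = 1), rep(12.011, 6))),
    "at least 2 frames")
})

test_that("entropy recovers the analytic closed form on Gaussian data", {
  va <- 0.02 * 1.35^(0:14)  # distinct spectrum: sorted sample
                            # eigenvalues track population modes
  for (seed in c(3, 8, 15)) {
    g <- make_gaussian_trajectory(gaussian_traj_spec(5, 2000, va),
                                  seed = seed)
    e <- quasiharmonic_entropy(g$traj, fit = "none")
    expect_lt(abs(e$entropy - (g$analytic_entropy + g$analytic_bias)),
              3 * g$analytic_se)
  }
})

test_that("entropy is invariant to per-frame rigid motion", {
  va <- 0.02 * 1.35^(0:14)
  g0 <- make_gaussian_trajectory(gaussian_traj_spec(5, 400, va,
                                                    rigid_motion = FALSE),
                                 seed = 6)
  g1 <- make_gaussian_trajectory(gaussian_traj_spec(5, 400, va,
                                                    rigid_motion = TRUE),
                                 seed = 6)
  e0 <- quasiharmonic_entropy(g0$traj, fit = "mean")$entropy
  e1 <- quasiharmonic_entropy(g1$traj, fit = "mean")$entropy
  expect_lt(abs(e0 - e1), 1e-3)
})

test_that("entropy is invariant to atom permutation", {
  va <- 0.02 * 1.35^(0:14)
  g <- make_gaussian_trajectory(gaussian_traj_spec(5, 300, va), seed = 4)
  perm <- c(3, 5, 1, 2, 4)
  cols <- as.vector(rbind(3 * perm - 2, 3 * perm - 1, 3 * perm))
  tp <- trajectory_ensemble(g$traj$frames[, cols],
                            g$traj$masses[perm])
  expect_equal(quasiharmonic_entropy(tp, fit = "mean")$entropy,
               quasiharmonic_entropy(g$traj, fit = "mean")$entropy,
               tolerance = 1e-9)
})

test_that("entropy grows monotonically with fluctuation scale", {
  for (seed in c(1, 9)) {
    g1 <- make_gaussian_trajectory(gaussian_traj_spec(6, 600, 0.05),
                                   seed = seed)
    g4 <- make_gaussian_trajectory(gaussian_traj_spec(6, 600, 0.20),
                                   seed = seed)
    expect_gt(quasiharmonic_entropy(g4$traj, fit = "none")$entropy,
              quasiharmonic_entropy(g1$traj, fit = "none")$entropy)
  }
  # closed form itself is monotone under uniform scaling
  lam <- 0.02 * 1.35^(0:5)
  expect_gt(entropy_closed_form(4 * lam), entropy_closed_form(lam))
})

test_that("entropy estimates converge toward the analytic value", {
  va <- 0.02 * 1.35^(0:14)
  errs <- vapply(c(100, 400, 1600), function(n) {
    dev <- vapply(1:4, function(seed) {
      g <- make_gaussian_trajectory(gaussian_traj_spec(5, n, va),
                                    seed = seed)
      abs(quasiharmonic_entropy(g$traj, fit = "none")$entropy -
            g$analytic_entropy)
    }, numeric(1))
    mean(dev)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("entropy difference is antisymmetric and signs floppy vs stiff", {
  floppy <- make_gaussian_trajectory(gaussian_traj_spec(6, 500, 0.20),
                                     seed = 11)
  stiff <- make_gaussian_trajectory(gaussian_traj_spec(6, 500, 0.05),
                                    seed = 12)
  d <- entropy_difference(floppy$traj, stiff$traj)
  expect_gt(d, 0)
  expect_equal(entropy_difference(stiff$traj, floppy$traj), -d,
               tolerance = 1e-12)
  expect_equal(entropy_difference(floppy$traj, floppy$traj), 0)
})
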