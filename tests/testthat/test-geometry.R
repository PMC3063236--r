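test_that("vec_distance is the Euclidean norm", {
  expect_equal(vec_distance(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(vec_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(vec_distance(c(1, 2, 3), c(4, 5, 6)),
               vec_distance(c(4, 5, 6), c(1, 2, 3)))
  expect_error(vec_distance(c(0, 0, NA), c(1, 1, 1)))
})

test_that("superposition recovers exact rigid transforms", {
  set.seed(11)
  ref <- matrix(rnorm(24), ncol = 3)
  fit0 <- superpose(ref, ref)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-8)

  fit1 <- superpose(sweep(ref, 2, c(1, 2, 3), `+`), ref)
  expect_equal(fit1$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit1$translation, c(-1, -2, -3), tolerance = 1e-8)
})

test_that("superposition matches the brute-force rotation oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    mob <- matrix(rnorm(18), ncol = 3)
    ref <- matrix(rnorm(18), ncol = 3)
    k <- superpose(mob, ref)
    expect_equal(det(k$rotation), 1, tolerance = 1e-9)
    expect_equal(k$rmsd, brute_force_superpose_rmsd(mob, ref),
                 tolerance = 1e-6)
  }
})

test_that("superposition rmsd is invariant to pre-transforming mobile", {
  set.seed(5)
  mob <- matrix(rnorm(30), ncol = 3)
  ref <- matrix(rnorm(30), ncol = 3)
  base <- superpose(mob, ref)$rmsd
  th <- 0.77
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, byrow = TRUE)
  pre <- sweep(mob %*% R, 2, c(4, -2, 9), `+`)
  expect_equal(superpose(pre, ref)$rmsd, base, tolerance = 1e-9)
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), "degenerate")
  expect_error(superpose(matrix(rnorm(6), ncol = 3),
                         matrix(rnorm(6), ncol = 3)), "at least 3")
})

test_that("hydrogen bonds obey distance window and angle criterion", {
  mk <- function(d, ang_deg) {
    # donor O at the origin with antecedent C on -x; acceptor O at
    # distance d such that the C-donor-acceptor angle is ang_deg
    th <- ang_deg * pi / 180
    data.frame(
      name = c("C", "OG", "O"),
      resid = c("SER", "SER", "ASP"), chain = "A",
      resno = c(1L, 1L, 2L), insert = "",
      element = c("C", "O", "O"),
      x = c(-1.43, 0, -d * cos(th)), y = c(0, 0, d * sin(th)), z = 0,
      stringsAsFactors = FALSE)
  }
  expect_equal(nrow(detect_hbonds(mk(5.0, 150))), 0)   # beyond cutoff
  expect_equal(nrow(detect_hbonds(mk(2.0, 150))), 0)   # closer than floor
  hb <- detect_hbonds(mk(2.8, 150))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$da_distance, 2.8, tolerance = 1e-9)
  expect_equal(nrow(detect_hbonds(mk(2.8, 60))), 0)    # angle fails
})

test_that("hydrogen-bond count is monotone in the distance cutoff", {
  hp <- hairpin_s()
  at <- structure_atoms(hp$struct)
  counts <- vapply(c(3.5, 3.2, 2.9, 2.6), function(mx)
    nrow(detect_hbonds(at, geometry_config(hb_max = mx))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("hydrogen-bond detection ignores atom-table order", {
  hp <- hairpin_s()
  at <- structure_atoms(hp$struct)
  hb1 <- detect_hbonds(at)
  set.seed(3)
  hb2 <- detect_hbonds(at[sample(nrow(at)), ])
  key <- function(h) sort(paste(pmin(h$atom_i, h$atom_j),
                                pmax(h$atom_i, h$atom_j)))
  expect_equal(key(hb1), key(hb2))
})

test_that("clash detection matches hand-computed overlaps", {
  carbon <- function(x, resno) data.frame(
    name = "CA", resid = "GLY", chain = "A", resno = resno, insert = "",
    element = "C", x = x, y = 0, z = 0, stringsAsFactors = FALSE)
  cfg <- geometry_config()
  ok <- detect_clashes(carbon(0, 1), carbon(4, 2), cfg)
  expect_equal(ok$count, 0)
  # 2 * 1.70 - 2.0 - 0.4 = 1.0 A overlap
  hit <- detect_clashes(carbon(0, 1), carbon(2, 2), cfg)
  expect_equal(hit$count, 1)
  expect_equal(hit$pairs$overlap, 1.0, tolerance = 1e-9)
})

test_that("clash count is monotone as tolerance decreases", {
  hp <- hairpin_g()
  at <- structure_atoms(hp$struct)
  placed <- at[at$resno == 107, ]
  env <- at[at$resno != 107 & !(at$resno %in% c(106, 108)), ]
  counts <- vapply(c(0.8, 0.4, 0.2, 0.0, -0.4), function(tol)
    detect_clashes(placed, env, tolerance = tol)$count, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("the cavity probe reports free radius against vdW envelopes", {
  hp <- hairpin_g()
  env <- structure_atoms(hp$struct)
  far <- colMeans(env[, c("x", "y", "z")]) + c(0, 0, 50)
  g <- probe_gap(far, env)
  expect_true(g$gap_present)
  expect_gt(g$max_free_radius, 8)

  on_carbon <- as.numeric(env[env$name == "CA", c("x", "y", "z")][1, ])
  g2 <- probe_gap(on_carbon, env)
  expect_equal(g2$max_free_radius, -1.70, tolerance = 1e-9)
  expect_false(g2$gap_present)
  expect_error(probe_gap(c(0, 0, 0), env[0, ]), "empty environment")
})

test_that("probe free radius is 1-Lipschitz in the centre", {
  hp <- hairpin_g()
  env <- structure_atoms(hp$struct)
  set.seed(9)
  for (i in 1:20) {
    c1 <- runif(3, -5, 15)
    delta <- rnorm(3); delta <- delta / sqrt(sum(delta^2)) * runif(1, 0, 2)
    r1 <- probe_gap(c1, env)$max_free_radius
    r2 <- probe_gap(c1 + delta, env)$max_free_radius
    expect_lte(abs(r1 - r2), sqrt(sum(delta^2)) + 1e-9)
  }
})
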