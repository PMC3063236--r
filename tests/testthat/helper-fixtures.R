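# Shared fixtures and independent oracles.  Hairpin generation runs a
# small deterministic optimisation, so fixtures are built once per test
# run and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

hairpin_g <- function() fixture("hp_g", function()
  make_hairpin(hairpin_spec(), name = "hp_g"))

hairpin_s <- function() fixture("hp_s", function()
  make_hairpin(hairpin_spec(loop_sequence = "CASSDAGGGYEQYF"),
               name = "hp_s"))

hairpin_ala40 <- function() fixture("hp_a40", function()
  make_hairpin(hairpin_spec(y40_aa = "A"), name = "hp_a40"))

anchor_of <- function(hp) {
  anchor_imgt(hp$struct, hp$manifest$beta_chain, hp$manifest$cdr3_seq,
              y40_author_number =
                if (is.na(hp$manifest$y40_author_number)) NULL
                else hp$manifest$y40_author_number)
}

# Independent superposition oracle: coarse search over ZYZ Euler angles
# followed by a generic local polish, minimising RMSD about centroids.
brute_force_superpose_rmsd <- function(mobile, reference) {
  euler_R <- function(a, b, c) {
    Rz <- function(t) matrix(c(cos(t), -sin(t), 0,
                               sin(t), cos(t), 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                               -sin(t), 0, cos(t)), 3, byrow = TRUE)
    Rz(a) %*% Ry(b) %*% Rz(c)
  }
  m0 <- sweep(mobile, 2, colMeans(mobile))
  r0 <- sweep(reference, 2, colMeans(reference))
  rms_at <- function(p) {
    m <- m0 %*% t(euler_R(p[1], p[2], p[3]))
    sqrt(mean(rowSums((m - r0)^2)))
  }
  grid <- as.matrix(expand.grid(a = seq(0, 2 * pi, length.out = 25),
                                b = seq(0, pi, length.out = 13),
                                c = seq(0, 2 * pi, length.out = 25)))
  vals <- apply(grid, 1, rms_at)
  o <- stats::optim(grid[which.min(vals), ], rms_at,
                    control = list(reltol = 1e-15, maxit = 10000))
  o$value
}

# Naive two-pass mean/SD oracle for the group summaries.
naive_mean_sd <- function(v) {
  v <- v[!is.na(v)]
  m <- sum(v) / length(v)
  s <- if (length(v) >= 2) sqrt(sum((v - m)^2) / (length(v) - 1)) else NA
  c(mean = m, sd = s)
}

# Random rigid transform applied to every atom of a structure model.
rigid_transform_structure <- function(struct, seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  tr <- runif(3, -20, 20)
  out <- struct
  for (m in seq_len(struct$nmodels)) {
    xyz <- matrix(struct$xyz[m, ], ncol = 3, byrow = TRUE)
    xyz <- sweep(xyz %*% R, 2, tr, `+`)
    out$xyz[m, ] <- as.vector(t(xyz))
  }
  out$atom$x <- out$xyz[1, seq(1, ncol(out$xyz), 3)]
  out$atom$y <- out$xyz[1, seq(2, ncol(out$xyz), 3)]
  out$atom$z <- out$xyz[1, seq(3, ncol(out$xyz), 3)]
  out
}
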