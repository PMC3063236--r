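# Deterministic fixture generators: idealized beta-hairpin loops with a
# G or S stalk residue, Gaussian-fluctuation trajectories with known
# covariance (hence closed-form entropy), and toy TRBV FASTA sets.
# These are geometric/statistical stand-ins built for testability, not
# physical models.

# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# Ideal backbone geometry used by the NeRF chain builder.
.bb <- list(b_NCa = 1.458, b_CaC = 1.525, b_CN = 1.329, b_CO = 1.231,
            a_NCaC = 111.2, a_CaCN = 116.2, a_CNCa = 121.7, a_CaCO = 120.5)

# Build backbone N/CA/C/O positions for given phi/psi (degrees).
build_backbone <- function(phi, psi, omega = rep(180, length(phi))) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2)
  res <- vector("list", n)
  N1 <- c(0, 0, 0); CA1 <- c(.bb$b_NCa, 0, 0)
  C1 <- place_atom(c(0, -1, 0), N1, CA1, .bb$b_CaC, .bb$a_NCaC, 123)
  res[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in 2:n) {
    p <- res[[i - 1]]
    Ni  <- place_atom(p$N, p$CA, p$C, .bb$b_CN, .bb$a_CaCN, psi[i - 1])
    CAi <- place_atom(p$CA, p$C, Ni, .bb$b_NCa, .bb$a_CNCa, omega[i - 1])
    Ci  <- place_atom(p$C, Ni, CAi, .bb$b_CaC, .bb$a_NCaC, phi[i])
    res[[i]] <- list(N = Ni, CA = CAi, C = Ci)
  }
  for (i in seq_len(n)) {
    if (i < n) {
      res[[i]]$O <- place_atom(res[[i + 1]]$N, res[[i]]$CA, res[[i]]$C,
                               .bb$b_CO, .bb$a_CaCO, 180)
    } else {
      res[[i]]$O <- place_atom(res[[i]]$N, res[[i]]$CA, res[[i]]$C,
                               .bb$b_CO, .bb$a_CaCO, psi[i] + 180)
    }
  }
  res
}

#' Specification of an idealized beta-hairpin fixture
#'
#' @param loop_sequence one-letter loop sequence (>= 8 residues,
#'   standard amino acids), e.g. a CDR3beta such as `"CASGDAGGGYEQYF"`.
#' @param stalk_index position of the G/S stalk residue (IMGT 107 sits
#'   at index 4 of a CDR3 starting at the conserved C).
#' @param include_y40 add a short V-region-like segment (author numbers
#'   38-42) carrying the Y40 analogue.
#' @param y40_aa residue placed at author number 40; anything but
#'   `"Y"` makes distance b unmeasurable downstream (by design).
#' @param strand_separation target mean facing-residue CA-CA distance
#'   across the hairpin, Angstrom.
#' @return A list of class `"hairpin_spec"`.
#' @export
hairpin_spec <- function(loop_sequence = "CASGDAGGGYEQYF",
                         stalk_index = 4, include_y40 = TRUE,
                         y40_aa = "Y", strand_separation = 4.8) {
  loop_sequence <- toupper(loop_sequence)
  if (nchar(loop_sequence) < 8)
    stop("loop_sequence must have at least 8 residues")
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", loop_sequence))
    stop("loop_sequence must use the standard 20 amino acids")
  stopifnot(stalk_index >= 2, stalk_index <= nchar(loop_sequence) - 1,
            strand_separation > 3, strand_separation < 8)
  structure(list(loop_sequence = loop_sequence, stalk_index = stalk_index,
                 include_y40 = include_y40, y40_aa = toupper(y40_aa),
                 strand_separation = strand_separation),
            class = "hairpin_spec")
}

# Idealized OG site for a serine at the given backbone, chi1 in degrees.
.ideal_og <- function(n, ca, c, chi1 = -60) {
  cb <- build_cb(n, ca, c)
  place_atom(n, ca, cb, .ideal_ser$b_cb_og, .ideal_ser$ang, chi1)
}

#' Generate an idealized beta-hairpin structure with a G or S stalk
#'
#' Two antiparallel extended strands (phi/psi -139/+135) joined by a
#' two-residue turn whose dihedrals are optimised deterministically so
#' the facing CA-CA separation matches the spec.  The stalk residue
#' carries an ideal Cbeta/Ogamma side chain when it is serine (chi1
#' -60); a glycine stalk leaves the inter-strand pocket empty by
#' construction.  With `include_y40`, a short segment numbered 38-42 is
#' placed so that residue 40's hydroxyl sits 3.05 Angstrom from the
#' idealized Ogamma site, out of the loop plane -- close enough to
#' hydrogen-bond a placed serine hydroxyl, far enough to leave the
#' cavity open to a water-sized probe.
#'
#' Generation is a pure function of the spec (the seed only shields the
#' caller's RNG stream); identical inputs give identical structures.
#'
#' @param spec a [hairpin_spec()].
#' @param seed integer; reserved for API symmetry with the stochastic
#'   generators.
#' @param name fixture name stored as `pdb_id`.
#' @return List with `struct` (a `"structure_model"`) and `manifest`
#'   (one-row data frame: `pdb_id`, `tcr_name`, `beta_chain`,
#'   `cdr3_seq`, `y40_author_number`).
#' @export
make_hairpin <- function(spec, seed = 1, name = "hairpin") {
  stopifnot(inherits(spec, "hairpin_spec"))
  L <- nchar(spec$loop_sequence)
  aa <- strsplit(spec$loop_sequence, "")[[1]]
  ns <- (L - 2L) %/% 2L

  mk_ca <- function(turn) {
    phi <- c(rep(-139, ns), turn[1:2], rep(-139, L - ns - 2))
    psi <- c(rep(135, ns), turn[3:4], rep(135, L - ns - 2))
    build_backbone(phi, psi)
  }
  objective <- function(turn) {
    bb <- mk_ca(turn)
    ca <- t(vapply(bb, function(r) r$CA, numeric(3)))
    d <- vapply(seq_len(ns), function(i)
      vec_distance(ca[i, ], ca[L + 1 - i, ]), numeric(1))
    sum((d - spec$strand_separation)^2)
  }
  opt <- stats::optim(c(17, 145, 13, 49), objective,
                      control = list(maxit = 2000))
  bb <- mk_ca(opt$par)

  rows <- list()
  add_atom <- function(name, resid, resno, element, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, resid = resid, chain = "A", resno = resno,
      insert = "", element = element,
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
  }

  stalk <- spec$stalk_index
  sb <- bb[[stalk]]
  og_site <- .ideal_og(sb$N, sb$CA, sb$C, chi1 = -60)

  # optional V-region-like segment with the Y40 analogue, placed along
  # the outward normal through the idealized OG site
  if (spec$include_y40) {
    all_ca <- t(vapply(bb, function(r) r$CA, numeric(3)))
    u <- unit(og_site - colMeans(all_ca))
    strand_axis <- unit(all_ca[ns, ] - all_ca[1, ])
    v <- unit(strand_axis - sum(strand_axis * u) * u)
    w <- cross3(u, v)
    oh <- og_site + 3.05 * u
    cz <- oh + 1.375 * u
    cb40 <- cz + 1.50 * u
    ca40 <- cb40 + 1.53 * u
    seg_aa <- c("G", "A", spec$y40_aa, "A", "G")
    for (k in seq_along(seg_aa)) {
      resno <- 37L + k
      ca_k <- ca40 + (k - 3) * 3.5 * v
      n_k <- ca_k + 1.46 * unit(-v + 0.35 * w)
      c_k <- ca_k + 1.52 * unit(v + 0.35 * w)
      o_k <- c_k + 1.23 * w
      resid <- aa_one_to_three(seg_aa[k])
      add_atom("N", resid, resno, "N", n_k)
      add_atom("CA", resid, resno, "C", ca_k)
      add_atom("C", resid, resno, "C", c_k)
      add_atom("O", resid, resno, "O", o_k)
      if (k == 3 && seg_aa[k] == "Y") {
        add_atom("CB", resid, resno, "C", cb40)
        add_atom("CZ", resid, resno, "C", cz)
        add_atom("OH", resid, resno, "O", oh)
      }
    }
  }

  for (i in seq_len(L)) {
    resid <- aa_one_to_three(aa[i])
    resno <- 103L + i
    add_atom("N", resid, resno, "N", bb[[i]]$N)
    add_atom("CA", resid, resno, "C", bb[[i]]$CA)
    add_atom("C", resid, resno, "C", bb[[i]]$C)
    add_atom("O", resid, resno, "O", bb[[i]]$O)
    if (i == stalk && aa[i] == "S") {
      cb <- build_cb(bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C)
      add_atom("CB", resid, resno, "C", cb)
      add_atom("OG", resid, resno, "O", og_site)
    }
  }

  atom <- do.call(rbind, rows)
  struct <- structure_from_atoms(atom, pdb_id = name)
  manifest <- data.frame(
    pdb_id = name, tcr_name = name, beta_chain = "A",
    cdr3_seq = spec$loop_sequence,
    y40_author_number = if (spec$include_y40 && spec$y40_aa == "Y")
      40L else NA_integer_,
    stringsAsFactors = FALSE)
  list(struct = struct, manifest = manifest)
}

#' Specification of a Gaussian-fluctuation trajectory
#'
#' @param n_atoms number of atoms.
#' @param n_frames number of frames (>= 2 for downstream entropy).
#' @param variances per-mode variances of the mass-weighted fluctuation
#'   coordinates, amu Angstrom^2; scalar recycled to 3 * n_atoms.
#' @param masses per-atom masses in amu; scalar recycled.
#' @param rigid_motion add a random rigid rotation/translation to each
#'   frame (removed again by the entropy estimator's superposition).
#' @param timestep ps per frame, metadata only.
#' @return A list of class `"gaussian_traj_spec"`.
#' @export
gaussian_traj_spec <- function(n_atoms, n_frames, variances = 0.05,
                               masses = 12.011, rigid_motion = FALSE,
                               timestep = 1) {
  stopifnot(n_atoms >= 2, n_frames >= 1)
  variances <- rep_len(variances, 3 * n_atoms)
  masses <- rep_len(masses, n_atoms)
  stopifnot(all(variances > 0), all(masses > 0))
  structure(list(n_atoms = as.integer(n_atoms),
                 n_frames = as.integer(n_frames),
                 variances = variances, masses = masses,
                 rigid_motion = rigid_motion, timestep = timestep),
            class = "gaussian_traj_spec")
}

# random proper rotation matrix from the current RNG stream
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Generate a seeded Gaussian-fluctuation trajectory with known entropy
#'
#' Frames are a fixed mean structure plus independent Gaussian
#' fluctuations drawn in mass-weighted coordinate space with the
#' specified per-mode variances, so the true covariance spectrum is
#' known by construction and the quasi-harmonic entropy has a closed
#' form.  With `rigid_motion`, each frame is additionally rotated and
#' translated at random, which a correct estimator must undo.
#'
#' @param spec a [gaussian_traj_spec()].
#' @param seed integer seed; identical (spec, seed) pairs give
#'   identical ensembles.
#' @param temperature Kelvin, used for the analytic entropy.
#' @param path optional file; when given, the ensemble is also written
#'   as a multi-model PDB of pseudo-atoms.
#' @return List with `traj` (a `"trajectory_ensemble"`),
#'   `analytic_entropy` (cal mol^-1 K^-1 at the true covariance),
#'   `analytic_se` (approximate sampling standard error of the
#'   estimator at this frame count), `analytic_bias` (second-order
#'   delta-method expectation shift of the estimator; add it to
#'   `analytic_entropy` to get the estimator's finite-sample
#'   expectation) and `lambda` (true mode variances, decreasing).
#' @export
make_gaussian_trajectory <- function(spec, seed = 1, temperature = 300,
                                     path = NULL) {
  stopifnot(inherits(spec, "gaussian_traj_spec"))
  N <- spec$n_atoms
  t_idx <- seq_len(N)
  mean_struct <- cbind(2.3 * cos(t_idx * 1.7), 2.3 * sin(t_idx * 1.7),
                       1.6 * t_idx)
  w <- sqrt(rep(spec$masses, each = 3))
  sdev <- sqrt(spec$variances)
  frames <- with_seed(seed, {
    z <- matrix(stats::rnorm(spec$n_frames * 3 * N), nrow = spec$n_frames)
    fl <- sweep(z, 2, sdev, `*`)          # mass-weighted fluctuations
    fl <- sweep(fl, 2, w, `/`)            # back to Cartesian Angstrom
    fr <- sweep(fl, 2, as.vector(t(mean_struct)), `+`)
    if (spec$rigid_motion) {
      for (i in seq_len(nrow(fr))) {
        R <- .random_rotation()
        tr <- stats::runif(3, -5, 5)
        m <- matrix(fr[i, ], ncol = 3, byrow = TRUE) %*% R
        fr[i, ] <- as.vector(t(sweep(m, 2, tr, `+`)))
      }
    }
    fr
  })
  traj <- trajectory_ensemble(frames, spec$masses,
                              selection_label = "gaussian pseudo-atoms",
                              timestep = spec$timestep)
  lambda <- sort(spec$variances, decreasing = TRUE)
  S <- entropy_closed_form(lambda, temperature)
  # delta method on the eigenvalue estimates, var(lambda_hat) ~
  # 2 lambda^2 / (n - 1): first order gives the sampling SE, second
  # order the finite-sample expectation shift (the mode entropy is
  # concave in lambda, so the estimator is biased slightly low)
  eps <- 1e-4
  dS <- vapply(lambda, function(l) {
    (entropy_closed_form(l * (1 + eps), temperature) -
       entropy_closed_form(l * (1 - eps), temperature)) / (2 * eps * l)
  }, numeric(1))
  d2S <- vapply(lambda, function(l) {
    (entropy_closed_form(l * (1 + eps), temperature) -
       2 * entropy_closed_form(l, temperature) +
       entropy_closed_form(l * (1 - eps), temperature)) / (eps * l)^2
  }, numeric(1))
  var_lam <- 2 * lambda^2 / max(1, spec$n_frames - 1)
  se <- sqrt(sum((dS * lambda)^2 * 2 / max(1, spec$n_frames - 1)))
  bias <- 0.5 * sum(d2S * var_lam)
  if (!is.null(path)) {
    atom <- data.frame(
      name = "CA", resid = "GLY", chain = "A", resno = t_idx,
      insert = "", element = "C",
      x = mean_struct[, 1], y = mean_struct[, 2], z = mean_struct[, 3],
      stringsAsFactors = FALSE)
    struct <- structure_from_atoms(atom, pdb_id = "gaussian_traj")
    struct$xyz <- frames
    struct$nmodels <- nrow(frames)
    write_structure(struct, path)
  }
  list(traj = traj, analytic_entropy = S, analytic_se = se,
       analytic_bias = bias, lambda = lambda)
}

#' Generate a toy TRBV FASTA set with known motif composition
#'
#' Writes `n_cass + n_casg + n_other` records for one species, with
#' random non-cysteine prefixes so the C104 anchor is unambiguous; a
#' census of the output returns exactly the requested counts.
#'
#' @param n_cass,n_casg,n_other non-negative counts (sum >= 1).
#' @param species species token written into headers.
#' @param seed integer seed.
#' @param path output FASTA file.
#' @return `path`, invisibly; the file has headers `TRBVk|species`.
#' @export
make_trbv_fasta <- function(n_cass, n_casg, n_other, species, seed, path) {
  stopifnot(n_cass >= 0, n_casg >= 0, n_other >= 0)
  total <- n_cass + n_casg + n_other
  if (total < 1) stop("at least one sequence must be requested")
  alphabet <- strsplit("ADEFGHIKLMNPQRSTVWY", "")[[1]]  # no cysteine
  motifs <- c(rep("CASS", n_cass), rep("CASG", n_casg),
              rep("CAWS", n_other))
  lines <- with_seed(seed, {
    out <- character(0)
    for (i in seq_len(total)) {
      prefix <- paste(sample(alphabet, 8, replace = TRUE), collapse = "")
      suffix <- paste(sample(alphabet, 2, replace = TRUE), collapse = "")
      out <- c(out, sprintf(">TRBV%d|%s", i, species),
               paste0(prefix, motifs[i], suffix))
    }
    out
  })
  writeLines(lines, path)
  invisible(path)
}
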