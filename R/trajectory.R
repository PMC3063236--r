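# Trajectory ensembles: per-frame superposition, RMSD time series, and
# quasi-harmonic (covariance-matrix) configurational entropy.
#
# The entropy estimator follows the standard quasi-harmonic scheme:
# after removing rigid-body motion, the mass-weighted covariance of the
# atomic fluctuations is diagonalised; each eigenvalue lambda_k (amu
# Angstrom^2) defines an effective oscillator frequency
# omega_k = sqrt(kB T / lambda_k), and the entropy is the sum of
# quantum harmonic-oscillator mode entropies
#   S = R * sum_k [ a_k/(exp(a_k)-1) - log(1-exp(-a_k)) ],
# with a_k = hbar omega_k / (kB T), reported in cal mol^-1 K^-1.

#' Build a trajectory ensemble from frame coordinates
#'
#' @param frames n_frames x 3N coordinate matrix (Angstrom), one row
#'   per frame, columns x1,y1,z1,x2,...
#' @param masses per-atom masses in amu (length N).
#' @param selection_label free-text description of the atom selection.
#' @param timestep metadata: time per frame in ps.
#' @return An object of class `"trajectory_ensemble"`.
#' @export
trajectory_ensemble <- function(frames, masses,
                                selection_label = "selection",
                                timestep = NA_real_) {
  frames <- as.matrix(frames)
  if (ncol(frames) %% 3 != 0)
    stop("frame width must be a multiple of 3")
  n_atoms <- ncol(frames) / 3
  stopifnot(length(masses) == n_atoms, all(masses > 0),
            all(is.finite(frames)))
  structure(list(frames = frames, masses = as.numeric(masses),
                 n_atoms = as.integer(n_atoms),
                 n_frames = nrow(frames),
                 selection_label = selection_label,
                 timestep = timestep),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("trajectory_ensemble: %d frames x %d atoms (%s)\n",
              x$n_frames, x$n_atoms, x$selection_label))
  invisible(x)
}

frame_coords <- function(traj, i) {
  matrix(traj$frames[i, ], ncol = 3, byrow = TRUE)
}

#' Read a multi-model PDB file as a trajectory ensemble
#'
#' Frames are the MODEL blocks in file order; the atom selection must
#' resolve to the same atoms in every model (enforced at parse time).
#' Masses are assigned from the element.
#'
#' @param path multi-model PDB file.
#' @param chain optional chain filter.
#' @param resno optional residue-number filter (e.g. the CDR3 loop).
#' @param atom_names atom-name filter; default is the backbone N, CA, C
#'   selection used for loop entropies.
#' @param timestep ps per frame, metadata only.
#' @return A `"trajectory_ensemble"`.
#' @export
read_trajectory <- function(path, chain = NULL, resno = NULL,
                            atom_names = c("N", "CA", "C"),
                            timestep = NA_real_) {
  struct <- parse_structure(path)
  if (struct$nmodels < 2)
    stop("trajectory file must contain at least 2 MODEL blocks")
  sel <- rep(TRUE, nrow(struct$atom))
  if (!is.null(chain)) sel <- sel & struct$atom$chain %in% chain
  if (!is.null(resno)) sel <- sel & struct$atom$resno %in% resno
  if (!is.null(atom_names)) sel <- sel & struct$atom$name %in% atom_names
  if (!any(sel)) stop("selection matches no atoms")
  cols <- as.vector(rbind(3 * which(sel) - 2, 3 * which(sel) - 1,
                          3 * which(sel)))
  label <- sprintf("%s%s%s",
                   if (is.null(chain)) "all chains" else
                     paste0("chain ", paste(chain, collapse = "")),
                   if (is.null(resno)) "" else
                     sprintf(", residues %d-%d", min(resno), max(resno)),
                   if (is.null(atom_names)) "" else
                     paste0(", atoms ", paste(atom_names, collapse = ",")))
  trajectory_ensemble(struct$xyz[, cols, drop = FALSE],
                      element_mass(struct$atom$element[sel]),
                      selection_label = label, timestep = timestep)
}

#' RMSD of each frame from a reference after superposition
#'
#' Each frame is rigid-body fitted to the reference over `fit_idx`
#' (Kabsch) and the RMSD is then computed over `report_idx`.
#'
#' @param traj a `"trajectory_ensemble"`.
#' @param reference reference coordinates: N x 3 matrix, a frame index,
#'   or NULL for frame 1 (the "initial structure").
#' @param fit_idx atom indices used for the fit; NULL fits on all atoms;
#'   NA skips fitting entirely.
#' @param report_idx atom indices entering the RMSD; NULL for all.
#' @return An object of class `"rmsd_series"`: data frame with `frame`
#'   and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, reference = NULL, fit_idx = NULL,
                        report_idx = NULL) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  ref <- if (is.null(reference)) frame_coords(traj, 1)
  else if (length(reference) == 1 && is.numeric(reference))
    frame_coords(traj, reference)
  else as.matrix(reference)
  stopifnot(nrow(ref) == traj$n_atoms)
  if (is.null(report_idx)) report_idx <- seq_len(traj$n_atoms)
  no_fit <- length(fit_idx) == 1 && all(is.na(fit_idx))
  if (is.null(fit_idx)) fit_idx <- seq_len(traj$n_atoms)

  vals <- vapply(seq_len(traj$n_frames), function(i) {
    fr <- frame_coords(traj, i)
    if (!no_fit) {
      fit <- superpose(fr[fit_idx, , drop = FALSE],
                       ref[fit_idx, , drop = FALSE])
      fr <- apply_transform(fr, fit)
    }
    coord_rmsd(fr[report_idx, , drop = FALSE],
               ref[report_idx, , drop = FALSE])
  }, numeric(1))
  out <- data.frame(frame = seq_len(traj$n_frames), rmsd = vals)
  class(out) <- c("rmsd_series", "data.frame")
  out
}

# Superpose all frames onto a reference (mass-weighted fit), returning
# the fitted frame matrix.
.fit_frames <- function(traj, ref) {
  out <- traj$frames
  for (i in seq_len(traj$n_frames)) {
    fr <- frame_coords(traj, i)
    fit <- superpose(fr, ref, weights = traj$masses)
    out[i, ] <- as.vector(t(apply_transform(fr, fit)))
  }
  out
}

#' Quasi-harmonic entropy of a trajectory ensemble
#'
#' Rigid-body motion is removed by mass-weighted superposition onto the
#' ensemble mean (iterated twice: fit, recompute mean, refit);
#' alternatively onto the first frame, or not at all for pre-aligned
#' input.  The mass-weighted covariance of the remaining fluctuations
#' is diagonalised and each eigenmode contributes a quantum
#' harmonic-oscillator entropy at the given temperature.  Eigenvalues
#' below `lambda_floor` are treated as numerically zero rigid/constraint
#' modes and excluded.
#'
#' @param traj a `"trajectory_ensemble"` with at least 2 frames.
#' @param temperature in Kelvin.
#' @param fit `"mean"` (default), `"first"`, or `"none"`.
#' @param lambda_floor smallest eigenvalue (amu Angstrom^2) kept.
#' @return An object of class `"entropy_result"`: `eigenvalues`
#'   (decreasing, amu Angstrom^2), `frequencies` (s^-1), `entropy`
#'   (cal mol^-1 K^-1), `temperature`, `n_modes_used`.
#' @export
quasiharmonic_entropy <- function(traj, temperature = 300,
                                  fit = c("mean", "first", "none"),
                                  lambda_floor = 1e-8) {
  stopifnot(inherits(traj, "trajectory_ensemble"), temperature > 0)
  fit <- match.arg(fit)
  if (traj$n_frames < 2)
    stop("entropy requires at least 2 frames")
  if (traj$n_frames < 3 * traj$n_atoms)
    warning("fewer frames (", traj$n_frames, ") than degrees of freedom (",
            3 * traj$n_atoms, "); covariance will be rank-deficient")

  frames <- traj$frames
  if (fit == "first") {
    frames <- .fit_frames(traj, frame_coords(traj, 1))
  } else if (fit == "mean") {
    ref <- matrix(colMeans(frames), ncol = 3, byrow = TRUE)
    for (it in 1:2) {
      tmp <- trajectory_ensemble(frames, traj$masses)
      frames <- .fit_frames(tmp, ref)
      ref <- matrix(colMeans(frames), ncol = 3, byrow = TRUE)
    }
  }

  w <- sqrt(rep(traj$masses, each = 3))
  q <- sweep(frames, 2, colMeans(frames))      # fluctuations
  q <- sweep(q, 2, w, `*`)                     # mass-weighted, amu^1/2 A
  covm <- crossprod(q) / (nrow(q) - 1)
  lambda <- sort(eigen(covm, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
  lambda[lambda < 0] <- 0
  used <- lambda[lambda >= lambda_floor]
  S <- entropy_closed_form(used, temperature)
  omega <- sqrt(.phys$kB * temperature /
                  (used * .phys$amu * 1e-20))
  structure(list(eigenvalues = lambda, frequencies = omega,
                 entropy = S, temperature = temperature,
                 n_modes_used = length(used)),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf(
    "entropy_result: S = %.4f cal/mol/K at %g K (%d modes)\n",
    x$entropy, x$temperature, x$n_modes_used))
  invisible(x)
}

#' Closed-form quasi-harmonic entropy at known mode variances
#'
#' Evaluates the quantum harmonic-oscillator mode sum directly at the
#' supplied eigenvalues of the mass-weighted covariance.  Serves as the
#' analytic oracle for ensembles whose true covariance is known by
#' construction.
#'
#' @param lambda eigenvalues in amu Angstrom^2.
#' @param temperature Kelvin.
#' @return Entropy in cal mol^-1 K^-1.
#' @export
entropy_closed_form <- function(lambda, temperature = 300) {
  lambda <- lambda[lambda > 0]
  if (!length(lambda)) return(0)
  lam_si <- lambda * .phys$amu * 1e-20            # kg m^2
  alpha <- .phys$hbar / sqrt(.phys$kB * temperature * lam_si)
  .phys$R_cal * sum(alpha / (exp(alpha) - 1) - log1p(-exp(-alpha)))
}

#' Entropy difference between two ensembles, S(a) - S(b)
#'
#' The sign convention matches a wild-type-minus-mutant comparison: a
#' positive value means the first (e.g. wild-type) ensemble is the more
#' disordered one.
#'
#' @param traj_a,traj_b `"trajectory_ensemble"` objects.
#' @param temperature Kelvin.
#' @param ... passed to [quasiharmonic_entropy()].
#' @return Signed entropy difference in cal mol^-1 K^-1.
#' @export
entropy_difference <- function(traj_a, traj_b, temperature = 300, ...) {
  quasiharmonic_entropy(traj_a, temperature, ...)$entropy -
    quasiharmonic_entropy(traj_b, temperature, ...)$entropy
}
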