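# Elementary structural geometry: distances, internal-coordinate atom
# placement (NeRF), Kabsch superposition, hydrogen-bond and steric-clash
# detection, and the cavity probe.

#' Euclidean distance between two points
#'
#' @param p,q numeric 3-vectors (Angstrom).
#' @return Distance in Angstrom.
#' @examples
#' vec_distance(c(0, 0, 0), c(3, 4, 0))  # 5
#' @export
vec_distance <- function(p, q) {
  stopifnot(length(p) == 3, length(q) == 3,
            all(is.finite(p)), all(is.finite(q)))
  sqrt(sum((p - q)^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

# Angle a-b-c in degrees.
vec_angle <- function(a, b, c) {
  u <- unit(a - b); v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given three reference atoms `a`, `b`, `c`, returns the position `d`
#' such that |c-d| = `bond`, angle(b,c,d) = `angle`, and the dihedral
#' a-b-c-d equals `dihedral`.
#'
#' @param a,b,c reference positions (3-vectors).
#' @param bond bond length c--d in Angstrom.
#' @param angle bond angle b-c-d in degrees.
#' @param dihedral dihedral a-b-c-d in degrees.
#' @return 3-vector position of the new atom.
#' @export
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unit(c - b)
  n <- cross3(b - a, bc)
  if (sqrt(sum(n^2)) < 1e-10) stop("collinear reference atoms")
  n <- unit(n)
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD
#' between `mobile %*% R + t` and `reference` over paired points,
#' optionally weighted.
#'
#' @param mobile,reference n x 3 coordinate matrices with paired rows,
#'   n >= 3.
#' @param weights optional non-negative per-point weights (e.g. masses).
#' @return A list with elements `rotation` (3 x 3, det +1), `translation`
#'   (length 3) and `rmsd` (Angstrom, weighted RMSD if weights given).
#' @examples
#' ref <- matrix(rnorm(18), ncol = 3)
#' fit <- superpose(ref + 5, ref)
#' fit$rmsd  # ~0
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 paired points")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)

  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  X <- sweep(mobile, 2, cm)
  Y <- sweep(reference, 2, cr)
  H <- t(X * w) %*% Y
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (abs(det(H)) < 1e-14 && qr(X)$rank < 2)
    stop("degenerate (collinear) point set; superposition undefined")
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  t_vec <- cr - as.numeric(cm %*% R)
  moved <- mobile %*% R
  moved <- sweep(moved, 2, t_vec, `+`)
  rmsd <- sqrt(sum(w * rowSums((moved - reference)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

#' Apply a rigid-body transform to coordinates
#'
#' @param coords n x 3 matrix.
#' @param fit result of [superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, fit) {
  coords <- as.matrix(coords)
  sweep(coords %*% fit$rotation, 2, fit$translation, `+`)
}

#' Root-mean-square deviation of paired coordinates
#'
#' No fitting is performed; superpose first if needed.
#'
#' @param a,b n x 3 matrices.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(dim(a) == dim(b))
  sqrt(mean(rowSums((a - b)^2)))
}

# Resolve the covalent antecedent of each N/O atom in an atom table: the
# nearest atom within 1.8 A (2.0 A for S) among the other atoms.  Used
# for the hydrogen-bond angle criterion; returns NA when nothing
# qualifies (the angle check is then waived for that atom).
.antecedent_index <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(atoms)
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    d <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    d[i] <- Inf
    j <- which.min(d)
    if (d[j] <= 1.9) out[i] <- j
  }
  out
}

.is_backbone <- function(name) toupper(name) %in% c("N", "CA", "C", "O", "OXT")

atom_label <- function(atoms, i) {
  sprintf("%s:%s%s/%s", atoms$chain[i], atoms$resno[i],
          ifelse(is.na(atoms$insert[i]) | atoms$insert[i] == "",
                 "", atoms$insert[i]),
          atoms$name[i])
}

#' Detect hydrogen bonds among N/O atoms by heavy-atom criteria
#'
#' Crystal structures lack hydrogens, so bonds are judged on heavy atoms
#' only: every nitrogen/oxygen pair from different residues whose
#' distance falls in `[hb_min, hb_max]` and whose
#' antecedent--atom--partner angle is at least `hb_angle_min` degrees at
#' both ends (waived for an atom whose covalent antecedent cannot be
#' found in the supplied set) is reported once.
#'
#' @param atoms atom table (as returned by [structure_atoms()]) covering
#'   the region of interest; must carry `element` assignments.
#' @param config a [geometry_config()].
#' @return A data frame of class `"hbond_set"`, sorted by distance, with
#'   one row per bond: partner labels, residue identifiers, the
#'   donor--acceptor distance `da_distance` and a backbone/side-chain
#'   classification per partner.
#' @export
detect_hbonds <- function(atoms, config = geometry_config()) {
  stopifnot(is.data.frame(atoms))
  empty <- data.frame(atom_i = character(), atom_j = character(),
                      res_i = character(), res_j = character(),
                      da_distance = numeric(),
                      class_i = character(), class_j = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("hbond_set", "data.frame")
  cand <- which(toupper(atoms$element) %in% c("N", "O"))
  if (length(cand) < 2) return(empty)

  ante <- .antecedent_index(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  res_key <- paste(atoms$chain, atoms$resno, atoms$insert)

  rows <- list()
  for (ii in seq_along(cand)) {
    for (jj in seq_len(ii - 1L)) {
      i <- cand[ii]; j <- cand[jj]
      if (res_key[i] == res_key[j]) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d < config$hb_min || d > config$hb_max) next
      ok <- TRUE
      for (pair in list(c(i, j), c(j, i))) {
        a <- ante[pair[1]]
        if (!is.na(a)) {
          ang <- vec_angle(xyz[a, ], xyz[pair[1], ], xyz[pair[2], ])
          if (ang < config$hb_angle_min) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      rows[[length(rows) + 1L]] <- data.frame(
        atom_i = atom_label(atoms, i), atom_j = atom_label(atoms, j),
        res_i = res_key[i], res_j = res_key[j],
        da_distance = d,
        class_i = if (.is_backbone(atoms$name[i])) "backbone" else "side-chain",
        class_j = if (.is_backbone(atoms$name[j])) "backbone" else "side-chain",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$da_distance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hbond_set", "data.frame")
  out
}

#' Detect steric clashes between a placed atom set and its environment
#'
#' A pair clashes when its interatomic distance is smaller than the sum
#' of the two van der Waals radii minus `tolerance`.  The caller is
#' responsible for removing bonded (1-2) and geminal (1-3) neighbours
#' from `environment` (see [place_serine()] for the exclusion rule used
#' by the mutator).
#'
#' @param placed,environment atom tables with `element`, `x`, `y`, `z`.
#' @param config a [geometry_config()]; supplies radii.
#' @param tolerance overlap forgiven before a contact counts, Angstrom;
#'   defaults to the config value.
#' @return A list of class `"clash_report"`: `pairs` (data frame with
#'   labels, distance and positive `overlap`) and `count`.
#' @export
detect_clashes <- function(placed, environment, config = geometry_config(),
                           tolerance = config$clash_tolerance) {
  stopifnot(is.data.frame(placed), is.data.frame(environment))
  pairs <- data.frame(placed = character(), environment = character(),
                      distance = numeric(), overlap = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(placed) && nrow(environment)) {
    rp <- vdw_radius(placed$element, config)
    re <- vdw_radius(environment$element, config)
    px <- as.matrix(placed[, c("x", "y", "z")])
    ex <- as.matrix(environment[, c("x", "y", "z")])
    for (i in seq_len(nrow(placed))) {
      d <- sqrt(rowSums(sweep(ex, 2, px[i, ])^2))
      ov <- rp[i] + re - d - tolerance
      hit <- which(ov > 0)
      for (j in hit) {
        pairs[nrow(pairs) + 1L, ] <- list(atom_label(placed, i),
                                          atom_label(environment, j),
                                          d[j], ov[j])
      }
    }
  }
  structure(list(pairs = pairs, count = nrow(pairs)),
            class = "clash_report")
}

#' Probe a putative cavity with a sphere
#'
#' The free radius at `center` is the largest sphere that fits without
#' entering any environment atom's van der Waals envelope:
#' `min(d(center, atom) - r_vdw(atom))`.  A gap is present when the free
#' radius admits the configured probe.
#'
#' @param center 3-vector, e.g. an idealized side-chain oxygen position.
#' @param environment atom table of non-adjacent heavy atoms.
#' @param config a [geometry_config()]; supplies radii and
#'   `probe_radius`.
#' @return A list of class `"gap_probe"` with `probe_center`,
#'   `max_free_radius` (Angstrom, may be negative), `gap_present` and
#'   `nearest_atom`.
#' @export
probe_gap <- function(center, environment, config = geometry_config()) {
  stopifnot(length(center) == 3, all(is.finite(center)))
  if (!is.data.frame(environment) || nrow(environment) == 0)
    stop("probe_gap: empty environment")
  ex <- as.matrix(environment[, c("x", "y", "z")])
  d <- sqrt(rowSums(sweep(ex, 2, center)^2))
  free <- d - vdw_radius(environment$element, config)
  k <- which.min(free)
  structure(list(probe_center = center,
                 max_free_radius = free[k],
                 gap_present = free[k] >= config$probe_radius,
                 nearest_atom = atom_label(environment, k)),
            class = "gap_probe")
}
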