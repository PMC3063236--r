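# In-silico G107S substitution on a rigid backbone.
#
# The claim being operationalised is existential: the serine
# hydroxymethyl fits in the stalk cavity of a CASG receptor at some
# canonical chi1 rotamer without moving any existing atom.  So the
# backbone is kept fixed, Cbeta and Ogamma are built from ideal internal
# coordinates, three staggered chi1 values are scanned, and each
# placement is scored by steric clashes, cavity filling and
# hydrogen-bond partners of the new hydroxyl.

#' Construct an ideal Cbeta from backbone N, CA, C
#'
#' The Cbeta is placed 1.53 Angstrom from CA with ideal tetrahedral
#' geometry (N-CA-CB and C-CA-CB about 110.5 deg) on the side consistent
#' with L-amino-acid chirality.
#'
#' @param n,ca,c backbone atom positions (3-vectors).
#' @return 3-vector Cbeta position.
#' @export
build_cb <- function(n, ca, c) {
  u_n <- unit(n - ca)
  u_c <- unit(c - ca)
  if (sqrt(sum(cross3(u_n, u_c)^2)) < 1e-6)
    stop("collinear backbone atoms; cannot construct Cbeta")
  # bisector construction: CB lies opposite the N/C bisector, tilted out
  # of the N-CA-C plane on the L-chirality side
  bis <- unit(u_n + u_c)
  perp <- unit(cross3(u_n, u_c))  # sign gives det[N-CA, C-CA, CB-CA] > 0
  b <- .ideal_ser$b_ca_cb
  # tilt of the CB direction away from the anti-bisector, fixed so that
  # both N-CA-CB and C-CA-CB come out near 110.5 deg
  half <- vec_angle(n, ca, c) / 2 * pi / 180
  target <- .ideal_ser$ang * pi / 180
  cos_tilt <- -cos(target) / cos(half)
  cos_tilt <- max(-1, min(1, cos_tilt))
  tilt <- acos(cos_tilt)
  dir <- -cos(tilt) * bis + sin(tilt) * perp
  ca + b * unit(dir)
}

#' Scan serine chi1 rotamers at the anchored position 107
#'
#' For each chi1 in `chi1_set`, Ogamma is built at 1.42 Angstrom from
#' the (ideal) Cbeta with a 110.5 deg CA-CB-OG angle and dihedral
#' N-CA-CB-OG = chi1.  Each placement is scored against all heavy atoms
#' of the structure, excluding the atoms of residue 107 itself and the
#' backbone atoms of its sequence neighbours (the 1-2/1-3 bonded
#' exemption); clash-free placements are feasible.  Hydrogen bonds of
#' the new Ogamma are evaluated with Cbeta as its antecedent.
#'
#' No input atom is moved: the result only describes candidate added
#' atoms.
#'
#' @param struct a `"structure_model"`.
#' @param anchor an `"imgt_anchor"`; the residue at 107 must be G or S.
#' @param chi1_set chi1 dihedrals (degrees) to scan.
#' @param config a [geometry_config()].
#' @param model model number used for coordinates.
#' @return An object of class `"mutation_result"`: `placements` (data
#'   frame: `chi1`, `cb_*`, `og_*`, `clash_count`, `max_overlap`,
#'   `n_hbonds`, `feasible`), `hbonds` (list of hbond tables per
#'   rotamer), `clashes` (list of clash reports), `best` (index or NA)
#'   and `verdict` (`"fits"` or `"clashes"`).  Ties for best are broken
#'   by more hydrogen bonds, then lower maximum overlap, then chi1
#'   closest to the common gauche- rotamer (-60 deg).
#' @export
place_serine <- function(struct, anchor, chi1_set = c(-60, 60, 180),
                         config = geometry_config(), model = 1) {
  stopifnot(inherits(struct, "structure_model"),
            inherits(anchor, "imgt_anchor"), length(chi1_set) >= 1)
  aa107 <- anchor$residues$aa[anchor$pos107]
  if (!aa107 %in% c("G", "S"))
    stop("position 107 is ", aa107,
         "; only G or S residues are supported")
  ch <- anchor$beta_chain_id
  n  <- .residue_atom_coord(struct, ch, anchor$pos107, "N",  model)
  ca <- .residue_atom_coord(struct, ch, anchor$pos107, "CA", model)
  c_ <- .residue_atom_coord(struct, ch, anchor$pos107, "C",  model)
  if (is.null(n) || is.null(ca) || is.null(c_))
    stop("residue 107 lacks a complete N/CA/C backbone")
  cb <- build_cb(n, ca, c_)

  env <- .mutation_environment(struct, anchor, model)

  placements <- NULL
  hb_list <- list()
  clash_list <- list()
  for (k in seq_along(chi1_set)) {
    chi1 <- chi1_set[k]
    og <- place_atom(n, ca, cb, .ideal_ser$b_cb_og, .ideal_ser$ang, chi1)
    placed <- data.frame(
      name = c("CB", "OG"), resid = "SER", chain = ch,
      resno = anchor$residues$resno[anchor$pos107],
      insert = anchor$residues$insert[anchor$pos107],
      element = c("C", "O"),
      x = c(cb[1], og[1]), y = c(cb[2], og[2]), z = c(cb[3], og[3]),
      stringsAsFactors = FALSE)
    cl <- detect_clashes(placed, env, config)
    raw_overlap <- if (nrow(env)) {
      max(vapply(seq_len(nrow(placed)), function(i) {
        d <- sqrt(rowSums(sweep(as.matrix(env[, c("x", "y", "z")]), 2,
                                as.numeric(placed[i, c("x", "y", "z")]))^2))
        max(vdw_radius(placed$element[i], config) +
              vdw_radius(env$element, config) - d)
      }, numeric(1)))
    } else -Inf
    hb <- .og_hbonds(og, cb, env, config)
    hb_list[[k]] <- hb
    clash_list[[k]] <- cl
    placements <- rbind(placements, data.frame(
      chi1 = chi1,
      cb_x = cb[1], cb_y = cb[2], cb_z = cb[3],
      og_x = og[1], og_y = og[2], og_z = og[3],
      clash_count = cl$count,
      max_overlap = raw_overlap,
      n_hbonds = nrow(hb),
      feasible = cl$count == 0,
      stringsAsFactors = FALSE))
  }

  best <- NA_integer_
  feas <- which(placements$feasible)
  if (length(feas)) {
    ord <- feas[order(-placements$n_hbonds[feas],
                      placements$max_overlap[feas],
                      abs(placements$chi1[feas] + 60))]
    best <- ord[1]
  }
  structure(list(placements = placements, hbonds = hb_list,
                 clashes = clash_list, best = best,
                 verdict = if (is.na(best)) "clashes" else "fits"),
            class = "mutation_result")
}

#' @export
print.mutation_result <- function(x, ...) {
  cat("mutation_result:", x$verdict, "\n")
  print(x$placements[, c("chi1", "clash_count", "max_overlap",
                         "n_hbonds", "feasible")])
  invisible(x)
}

# Environment for clash scoring: all heavy atoms except residue 107
# itself and the backbone atoms of its i+/-1 neighbours (1-2/1-3
# exemption across the peptide bond).
.mutation_environment <- function(struct, anchor, model = 1) {
  at <- structure_atoms(struct, model = model)
  ch <- anchor$beta_chain_id
  res <- anchor$residues
  key <- paste(at$chain, at$resno, at$insert)
  k107 <- paste(ch, res$resno[anchor$pos107], res$insert[anchor$pos107])
  drop <- key == k107
  for (nb in c(anchor$pos107 - 1L, anchor$pos107 + 1L)) {
    if (nb >= 1 && nb <= nrow(res)) {
      knb <- paste(ch, res$resno[nb], res$insert[nb])
      drop <- drop | (key == knb & .is_backbone(at$name))
    }
  }
  at[!drop & at$element != "H", , drop = FALSE]
}

# Hydrogen bonds of a candidate Ogamma: partner N/O atoms within the
# distance window, angle criterion applied at the partner (via its
# antecedent) and at OG (antecedent = CB).
.og_hbonds <- function(og, cb, env, config) {
  cand <- env[toupper(env$element) %in% c("N", "O"), , drop = FALSE]
  out <- data.frame(partner = character(), res = character(),
                    name = character(), da_distance = numeric(),
                    class = character(), stringsAsFactors = FALSE)
  if (!nrow(cand)) return(out)
  ex <- as.matrix(cand[, c("x", "y", "z")])
  d <- sqrt(rowSums(sweep(ex, 2, og)^2))
  keep <- d >= config$hb_min & d <= config$hb_max
  if (!any(keep)) return(out)
  cand <- cand[keep, , drop = FALSE]
  d <- d[keep]
  ante <- .antecedent_index(env)
  env_xyz <- as.matrix(env[, c("x", "y", "z")])
  keep_rows <- logical(nrow(cand))
  idx_in_env <- match(interaction(cand$chain, cand$resno, cand$insert,
                                  cand$name, drop = TRUE),
                      interaction(env$chain, env$resno, env$insert,
                                  env$name, drop = TRUE))
  for (i in seq_len(nrow(cand))) {
    p <- as.numeric(cand[i, c("x", "y", "z")])
    ok <- vec_angle(cb, og, p) >= config$hb_angle_min
    a <- ante[idx_in_env[i]]
    if (ok && !is.na(a))
      ok <- vec_angle(env_xyz[a, ], p, og) >= config$hb_angle_min
    keep_rows[i] <- ok
  }
  cand <- cand[keep_rows, , drop = FALSE]
  d <- d[keep_rows]
  if (!nrow(cand)) return(out)
  out <- data.frame(
    partner = vapply(seq_len(nrow(cand)), function(i)
      atom_label(cand, i), character(1)),
    res = paste(cand$chain, cand$resno, cand$insert),
    name = cand$name,
    da_distance = d,
    class = ifelse(.is_backbone(cand$name), "backbone", "side-chain"),
    stringsAsFactors = FALSE)
  out[order(out$da_distance), , drop = FALSE]
}

#' Materialise one rotamer placement as a mutated structure
#'
#' Returns a copy of the input with the residue at 107 renamed to SER
#' and the placement's Cbeta/Ogamma appended; every pre-existing atom
#' keeps its exact coordinates.  Only single-model structures are
#' supported.
#'
#' @param struct a `"structure_model"` (one model).
#' @param anchor the `"imgt_anchor"` used for placement.
#' @param result a `"mutation_result"`.
#' @param which placement index; defaults to the best one.
#' @return A new `"structure_model"`.
#' @export
apply_placement <- function(struct, anchor, result, which = result$best) {
  stopifnot(inherits(result, "mutation_result"), struct$nmodels == 1)
  if (is.na(which)) stop("no feasible placement to apply")
  p <- result$placements[which, ]
  at <- structure_atoms(struct, model = 1)
  ch <- anchor$beta_chain_id
  resno107 <- anchor$residues$resno[anchor$pos107]
  sel107 <- at$chain == ch & at$resno == resno107 &
    at$insert == anchor$residues$insert[anchor$pos107]
  at$resid[sel107] <- "SER"
  # drop any pre-existing side chain of residue 107, then append CB/OG
  at <- at[!(sel107 & !.is_backbone(at$name)), , drop = FALSE]
  add <- data.frame(
    serial = max(at$serial) + 1:2,
    name = c("CB", "OG"), resid = "SER",
    aa = "S", chain = ch, resno = resno107,
    insert = anchor$residues$insert[anchor$pos107],
    element = c("C", "O"),
    x = c(p$cb_x, p$og_x), y = c(p$cb_y, p$og_y), z = c(p$cb_z, p$og_z),
    stringsAsFactors = FALSE)
  # keep residue atoms contiguous: insert after the last atom of 107
  pos <- max(which(at$chain == ch & at$resno == resno107))
  at <- rbind(at[seq_len(pos), ], add,
              if (pos < nrow(at)) at[(pos + 1):nrow(at), ])
  at$aa <- aa_three_to_one(at$resid)
  structure_from_atoms(at, pdb_id = paste0(struct$pdb_id, "_G107S"))
}
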