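# Structure representation: a thin, validated layer over bio3d's PDB
# reader.  A structure_model holds one atom table (protein ATOM records
# only, one altloc per atom) plus an nmodels x 3N coordinate matrix, so
# multi-MODEL files double as trajectory carriers.

#' Parse a PDB-format file into a structure model
#'
#' Reads ATOM records (HETATM and waters are excluded), keeps a single
#' alternate location per atom (altloc "A"/blank, i.e. the first), and
#' stacks MODEL blocks as rows of a coordinate matrix.  All models must
#' contain the same atoms in the same order; a mismatch is reported with
#' the offending model number.
#'
#' @param path PDB-format text file.
#' @param pdb_id identifier stored on the model; defaults to the file
#'   base name.
#' @return An object of class `"structure_model"`: list with `pdb_id`,
#'   `atom` (data frame: `serial`, `name`, `resid`, `aa`, `chain`,
#'   `resno`, `insert`, `element`, `x`, `y`, `z` for model 1), `xyz`
#'   (nmodels x 3N matrix) and `nmodels`.
#' @examples
#' \dontrun{s <- parse_structure("1u3h.pdb")}
#' @export
parse_structure <- function(path, pdb_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  atom_mask <- startsWith(lines, "ATOM  ")
  het_mask <- startsWith(lines, "HETATM")
  if (!any(atom_mask)) stop("no protein ATOM records in ", path)

  # validate MODEL block sizes before handing off to bio3d
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 1) {
    block <- findInterval(which(atom_mask), model_starts)
    counts <- tabulate(block, nbins = length(model_starts))
    if (length(unique(counts)) != 1) {
      bad <- which(counts != counts[1])[1]
      stop(sprintf(
        "model %d has %d ATOM records where model 1 has %d; %s",
        bad, counts[bad], counts[1],
        "all models must share the same atoms"))
    }
  }

  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  keep <- at$type == "ATOM" &
    (is.na(at$alt) | at$alt %in% c("", "A")) &
    !(at$resid %in% c("HOH", "WAT", "DOD"))
  if (!any(keep)) stop("no protein ATOM records in ", path)
  xyz_cols <- as.vector(rbind(3 * which(keep) - 2,
                              3 * which(keep) - 1,
                              3 * which(keep)))
  xyz <- pdb$xyz[, xyz_cols, drop = FALSE]
  at <- at[keep, , drop = FALSE]

  element <- at$elesy
  miss <- is.na(element) | element == ""
  if (any(miss)) element[miss] <- .element_from_name(at$elety[miss])

  atom <- data.frame(
    serial = at$eleno,
    name = at$elety,
    resid = at$resid,
    aa = aa_three_to_one(at$resid),
    chain = at$chain,
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    element = toupper(element),
    x = xyz[1, seq(1, ncol(xyz), 3)],
    y = xyz[1, seq(2, ncol(xyz), 3)],
    z = xyz[1, seq(3, ncol(xyz), 3)],
    stringsAsFactors = FALSE)
  rownames(atom) <- NULL
  if (!all(is.finite(as.matrix(atom[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)

  structure(list(pdb_id = if (is.null(pdb_id))
                   sub("\\.(pdb|ent)$", "", basename(path)) else pdb_id,
                 atom = atom, xyz = xyz, nmodels = nrow(xyz)),
            class = "structure_model")
}

.element_from_name <- function(name) {
  stripped <- sub("^[0-9]*", "", toupper(name))
  two <- substr(stripped, 1, 2)
  one <- substr(stripped, 1, 1)
  ifelse(two %in% c("FE", "ZN", "MG", "SE"), two, one)
}

#' Build a structure model directly from an atom table
#'
#' Used by the synthetic generators; the single model's coordinates are
#' taken from the `x`, `y`, `z` columns.
#'
#' @param atom atom data frame in [parse_structure()] layout.
#' @param pdb_id identifier.
#' @return A `"structure_model"`.
#' @export
structure_from_atoms <- function(atom, pdb_id = "synthetic") {
  need <- c("name", "resid", "chain", "resno", "element", "x", "y", "z")
  stopifnot(all(need %in% names(atom)))
  atom$serial <- seq_len(nrow(atom))
  if (is.null(atom$insert)) atom$insert <- ""
  atom$aa <- aa_three_to_one(atom$resid)
  atom <- atom[, c("serial", "name", "resid", "aa", "chain", "resno",
                   "insert", "element", "x", "y", "z")]
  xyz <- matrix(t(as.matrix(atom[, c("x", "y", "z")])), nrow = 1)
  structure(list(pdb_id = pdb_id, atom = atom, xyz = xyz, nmodels = 1L),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model %s: %d atoms, %d chain(s), %d model(s)\n",
              x$pdb_id, nrow(x$atom),
              length(unique(x$atom$chain)), x$nmodels))
  invisible(x)
}

#' Extract an atom table, optionally filtered and for a given model
#'
#' @param struct a `"structure_model"`.
#' @param model model (frame) number, 1-based.
#' @param chain optional chain id filter.
#' @param resno optional author residue-number filter.
#' @param name optional atom-name filter (e.g. `c("N","CA","C")`).
#' @return Atom data frame with coordinates of the requested model.
#' @export
structure_atoms <- function(struct, model = 1, chain = NULL, resno = NULL,
                            name = NULL) {
  stopifnot(inherits(struct, "structure_model"),
            model >= 1, model <= struct$nmodels)
  atom <- struct$atom
  atom$x <- struct$xyz[model, seq(1, ncol(struct$xyz), 3)]
  atom$y <- struct$xyz[model, seq(2, ncol(struct$xyz), 3)]
  atom$z <- struct$xyz[model, seq(3, ncol(struct$xyz), 3)]
  if (!is.null(chain)) atom <- atom[atom$chain %in% chain, , drop = FALSE]
  if (!is.null(resno)) atom <- atom[atom$resno %in% resno, , drop = FALSE]
  if (!is.null(name)) atom <- atom[atom$name %in% name, , drop = FALSE]
  rownames(atom) <- NULL
  atom
}

#' Residue table of one chain, in file order
#'
#' @param struct a `"structure_model"`.
#' @param chain chain id.
#' @return Data frame with one row per residue: `resno`, `insert`,
#'   `resid`, `aa`.
#' @export
chain_residues <- function(struct, chain) {
  at <- struct$atom[struct$atom$chain == chain, , drop = FALSE]
  if (!nrow(at)) stop("no chain '", chain, "' in ", struct$pdb_id)
  key <- paste(at$resno, at$insert)
  first <- !duplicated(key)
  data.frame(resno = at$resno[first], insert = at$insert[first],
             resid = at$resid[first], aa = at$aa[first],
             stringsAsFactors = FALSE)
}

#' One-letter sequence of a chain
#'
#' @inheritParams chain_residues
#' @return Character scalar; nonstandard residues appear as `"X"`.
#' @export
chain_sequence <- function(struct, chain) {
  paste(chain_residues(struct, chain)$aa, collapse = "")
}

# Atoms of one residue (by chain + position in chain_residues order).
.residue_atoms <- function(struct, chain, res_index, model = 1) {
  res <- chain_residues(struct, chain)
  stopifnot(res_index >= 1, res_index <= nrow(res))
  structure_atoms(struct, model = model, chain = chain,
                  resno = res$resno[res_index])
}

# Coordinates of one named atom in a residue, or NULL if absent.
.residue_atom_coord <- function(struct, chain, res_index, atom_name,
                                model = 1) {
  at <- .residue_atoms(struct, chain, res_index, model)
  at <- at[at$name == atom_name, , drop = FALSE]
  if (!nrow(at)) return(NULL)
  as.numeric(at[1, c("x", "y", "z")])
}

#' Write a structure model to a PDB-format file
#'
#' Coordinates are written at the standard fixed 8.3 width; multi-model
#' structures produce MODEL/ENDMDL blocks, so a written file re-parses
#' to the same atoms, numbering and coordinates (to 3 decimals).
#'
#' @param struct a `"structure_model"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(struct, path) {
  stopifnot(inherits(struct, "structure_model"))
  con <- file(path, "w")
  on.exit(close(con))
  multi <- struct$nmodels > 1
  for (m in seq_len(struct$nmodels)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    at <- structure_atoms(struct, model = m)
    nm <- ifelse(nchar(at$name) < 4, paste0(" ", at$name), at$name)
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$serial %% 100000, nm, at$resid, at$chain, at$resno,
      ifelse(at$insert == "", " ", at$insert),
      at$x, at$y, at$z, 1.00, 0.00, at$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Anchor IMGT positions onto author numbering via the CDR3beta sequence
#'
#' The conserved cysteine opening the CDR3 (IMGT 104) is located as the
#' first residue of the unique match of `cdr3_sequence` in the chosen
#' chain; IMGT 107, the G/S position under study, is the fourth residue
#' of that match.  The loop range extends from the match through IMGT
#' 119 (match start + 15) where the chain is long enough.  Y40 is found
#' either at an explicit author number or as the unique tyrosine within
#' an author-numbering window; position 42 is two residues downstream of
#' Y40 in chain order.  Chains lacking a locatable tyrosine get
#' `pos40 = NULL` (distance b is then NA downstream).
#'
#' @param struct a `"structure_model"`.
#' @param beta_chain_id chain id of the TCR beta chain.
#' @param cdr3_sequence one-letter CDR3beta sequence starting with C and
#'   occurring exactly once in the chain.
#' @param y40_author_number optional author residue number of Y40.
#' @param y40_window author-number window searched for a unique Tyr when
#'   `y40_author_number` is not given.
#' @return An object of class `"imgt_anchor"`: chain id, residue indices
#'   `pos104`, `pos107`, `loop_idx`, and `pos40`/`pos42` (NULL when
#'   absent), plus the residue table they index into.
#' @export
anchor_imgt <- function(struct, beta_chain_id, cdr3_sequence,
                        y40_author_number = NULL, y40_window = c(30, 50)) {
  stopifnot(inherits(struct, "structure_model"))
  cdr3_sequence <- toupper(cdr3_sequence)
  if (nchar(cdr3_sequence) < 4)
    stop("cdr3_sequence must have at least 4 residues")
  if (substr(cdr3_sequence, 1, 1) != "C")
    stop("cdr3_sequence must start with the conserved C (IMGT 104)")

  res <- chain_residues(struct, beta_chain_id)
  seq <- paste(res$aa, collapse = "")
  hits <- gregexpr(cdr3_sequence, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1)
    stop("CDR3 sequence ", cdr3_sequence, " not found in chain ",
         beta_chain_id, " of ", struct$pdb_id)
  if (length(hits) > 1)
    stop("CDR3 sequence ", cdr3_sequence, " is ambiguous (",
         length(hits), " matches) in chain ", beta_chain_id)
  i104 <- as.integer(hits[1])
  if (res$aa[i104] != "C")
    stop("anchored position 104 is not a cysteine")
  i107 <- i104 + 3L
  loop_end <- min(i104 + 15L, nrow(res))
  loop_idx <- i104:loop_end

  pos40 <- NULL
  if (!is.null(y40_author_number) && !is.na(y40_author_number)) {
    cand <- which(res$resno == y40_author_number)
    if (length(cand) == 1 && res$aa[cand] == "Y") pos40 <- cand
  } else {
    cand <- which(res$aa == "Y" & res$resno >= y40_window[1] &
                    res$resno <= y40_window[2])
    if (length(cand) == 1) pos40 <- cand
  }
  pos42 <- NULL
  if (!is.null(pos40) && pos40 + 2 <= nrow(res)) pos42 <- pos40 + 2L

  structure(list(beta_chain_id = beta_chain_id,
                 cdr3_sequence = cdr3_sequence,
                 residues = res,
                 pos104 = i104, pos107 = i107,
                 loop_idx = loop_idx,
                 pos40 = pos40, pos42 = pos42),
            class = "imgt_anchor")
}

#' @export
print.imgt_anchor <- function(x, ...) {
  cat(sprintf(
    "imgt_anchor chain %s: 104 -> %s%d (%s), 107 -> %s%d (%s), loop %d res%s\n",
    x$beta_chain_id, x$beta_chain_id, x$residues$resno[x$pos104],
    x$residues$aa[x$pos104], x$beta_chain_id, x$residues$resno[x$pos107],
    x$residues$aa[x$pos107], length(x$loop_idx),
    if (is.null(x$pos40)) ", Y40 absent" else
      sprintf(", Y40 -> %d", x$residues$resno[x$pos40])))
  invisible(x)
}
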