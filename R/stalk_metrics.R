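# The stalk distance triple and its group statistics.
#
# Per TCR, three distances are taken from the alpha carbon of the G/S
# residue at IMGT 107: (a) to the nearest backbone carbonyl carbon in
# the countercurrent (J-encoded, descending) strand of the CDR3beta;
# (b) to the Y40 side-chain hydroxyl oxygen, when that tyrosine exists;
# (c) to the alpha carbon of the V-region residue two positions
# downstream of Y40.

#' Classify a CDR3beta sequence by its position-107 residue
#'
#' @param cdr3_seq one-letter CDR3beta sequence, starting with the
#'   conserved C and at least 4 residues long.
#' @return `"G107"`, `"S107"` or `"other"` according to the 4th residue.
#' @examples
#' classify_position107("CASGDAGGGYEQYF")  # "G107"
#' classify_position107("CASSDWVSYEQYF")   # "S107"
#' @export
classify_position107 <- function(cdr3_seq) {
  cdr3_seq <- toupper(cdr3_seq)
  if (nchar(cdr3_seq) < 4)
    stop("CDR3 sequence must have at least 4 residues")
  if (substr(cdr3_seq, 1, 1) != "C")
    stop("CDR3 sequence must start with C")
  switch(substr(cdr3_seq, 4, 4), G = "G107", S = "S107", "other")
}

#' Measure the stalk distance triple for one anchored structure
#'
#' Distance a is minimised over the backbone carbonyl carbons of the
#' countercurrent-strand residues: anchored loop residues from IMGT
#' position `104 + ceiling(L/2)` through 119 (which excludes 104--108
#' and the apex), where L is the loop length.  The chosen partner and
#' the three nearest candidates are attached for diagnosis.  Distance b
#' uses the Y40 OH oxygen and is NA when the anchor has no Y40;
#' distance c uses the alpha carbon of position 42.
#'
#' @param struct a `"structure_model"`.
#' @param anchor an `"imgt_anchor"` for that structure.
#' @param model model number used for coordinates.
#' @param tcr_name optional display name.
#' @return One-row data frame of class `"stalk_distances"`: `tcr_name`,
#'   `pdb_id`, `cdr3_seq`, `is_g107`, `dist_a`, `dist_b`, `dist_c`, and
#'   `partner_a` (label of the carbonyl carbon chosen for a).  The
#'   attribute `"candidates_a"` lists the three nearest candidates.
#' @export
measure_stalk <- function(struct, anchor, model = 1, tcr_name = NULL) {
  stopifnot(inherits(struct, "structure_model"),
            inherits(anchor, "imgt_anchor"))
  ch <- anchor$beta_chain_id
  ca107 <- .residue_atom_coord(struct, ch, anchor$pos107, "CA", model)
  if (is.null(ca107))
    stop("residue at IMGT 107 lacks an alpha carbon")

  L <- length(anchor$loop_idx)
  from_imgt <- 104 + ceiling(L / 2)
  counter_idx <- anchor$loop_idx[(104 + seq_len(L) - 1) >= from_imgt]
  counter_idx <- setdiff(counter_idx, anchor$pos104:(anchor$pos104 + 4L))
  if (!length(counter_idx))
    stop("no countercurrent-strand residues in the anchored loop")

  cand <- do.call(rbind, lapply(counter_idx, function(i) {
    cc <- .residue_atom_coord(struct, ch, i, "C", model)
    if (is.null(cc)) return(NULL)
    data.frame(res_index = i,
               resno = anchor$residues$resno[i],
               aa = anchor$residues$aa[i],
               dist = vec_distance(ca107, cc),
               stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || !nrow(cand))
    stop("no backbone carbonyl carbons found in the countercurrent strand")
  cand <- cand[order(cand$dist), , drop = FALSE]
  dist_a <- cand$dist[1]
  partner_a <- sprintf("%s%d(%s)", ch, cand$resno[1], cand$aa[1])

  dist_b <- NA_real_
  if (!is.null(anchor$pos40)) {
    oh <- .residue_atom_coord(struct, ch, anchor$pos40, "OH", model)
    if (!is.null(oh)) dist_b <- vec_distance(ca107, oh)
  }
  dist_c <- NA_real_
  if (!is.null(anchor$pos42)) {
    ca42 <- .residue_atom_coord(struct, ch, anchor$pos42, "CA", model)
    if (!is.null(ca42)) dist_c <- vec_distance(ca107, ca42)
  }

  out <- data.frame(
    tcr_name = if (is.null(tcr_name)) struct$pdb_id else tcr_name,
    pdb_id = struct$pdb_id,
    cdr3_seq = anchor$cdr3_sequence,
    is_g107 = classify_position107(anchor$cdr3_sequence) == "G107",
    dist_a = dist_a, dist_b = dist_b, dist_c = dist_c,
    partner_a = partner_a,
    stringsAsFactors = FALSE)
  attr(out, "candidates_a") <- utils::head(cand, 3)
  class(out) <- c("stalk_distances", "data.frame")
  out
}

#' Group summary of stalk distance rows (mean and sample SD)
#'
#' Rows are split into the G107 and S107 groups; per distance the
#' NA-aware mean and the sample standard deviation (n-1 denominator)
#' are computed.  SD is NA for fewer than 2 non-NA values.
#'
#' @param rows data frame with columns `is_g107`, `dist_a`, `dist_b`,
#'   `dist_c` (e.g. stacked [measure_stalk()] rows).
#' @param digits decimals used for the reported values (the returned
#'   `*_raw` columns stay unrounded).
#' @return Data frame with one row per group: `group`, `n`, and for
#'   each distance `mean_*`, `sd_*` (rounded) plus unrounded `*_raw`
#'   twins.
#' @export
summarize_groups <- function(rows, digits = 2) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1,
            all(c("is_g107", "dist_a", "dist_b", "dist_c") %in% names(rows)))
  one <- function(sub, label) {
    cols <- lapply(c(a = "dist_a", b = "dist_b", c = "dist_c"), function(cn) {
      v <- sub[[cn]]
      v <- v[!is.na(v)]
      m <- if (length(v) >= 1) mean(v) else NA_real_
      s <- if (length(v) >= 2) stats::sd(v) else NA_real_
      c(mean = m, sd = s)
    })
    data.frame(group = label, n = nrow(sub),
               mean_a = round(cols$a["mean"], digits),
               sd_a = round(cols$a["sd"], digits),
               mean_b = round(cols$b["mean"], digits),
               sd_b = round(cols$b["sd"], digits),
               mean_c = round(cols$c["mean"], digits),
               sd_c = round(cols$c["sd"], digits),
               mean_a_raw = cols$a["mean"], sd_a_raw = cols$a["sd"],
               mean_b_raw = cols$b["mean"], sd_b_raw = cols$b["sd"],
               mean_c_raw = cols$c["mean"], sd_c_raw = cols$c["sd"],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  rbind(one(rows[rows$is_g107, , drop = FALSE], "G107"),
        one(rows[!rows$is_g107, , drop = FALSE], "S107"))
}

#' Reference stalk distances of the ten crystallographic TCR
#'
#' The published per-TCR distance triple for three CASG (G107) and seven
#' CASS (S107) receptors, keyed by PDB accession, as used for the group
#' statistics.  Distances in Angstrom; NA marks structures without a
#' locatable Y40 hydroxyl.
#'
#' @return Data frame with columns `tcr_name`, `trbv13_2`, `pdb_id`,
#'   `cdr3_seq`, `is_g107`, `dist_a`, `dist_b`, `dist_c`.
#' @export
reference_distances <- function() {
  out <- data.frame(
    tcr_name = c("D10", "172.10", "2C", "HA1.7", "AHIII 12.2", "N15",
                 "JM22", "1G4", "KK50.4", "3A6"),
    trbv13_2 = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 FALSE, FALSE),
    pdb_id = c("1D9K", "1U3H", "2OI9", "1FYT", "1LP9", "1NFD", "1OGA",
               "2BNQ", "2ESV", "1ZGL"),
    cdr3_seq = c("CASGGQGRAEQFF", "CASGDAGGGYEQYF", "CASGGGGTLYF",
                 "CASSSTGLPYGYTF", "CASSDWVSYEQYF", "CASSLRWGDEQYF",
                 "CASSRSSYEQYF", "CASSYVGNTGELFF", "CASSQDRDTQYF",
                 "CASSLADRVNTEAFF"),
    dist_a = c(4.81, 4.98, 5.12, 5.06, 5.17, 4.55, 4.59, 4.82, 4.84, 6.12),
    dist_b = c(5.73, 5.28, 5.25, NA, 4.95, NA, 6.04, NA, 5.67, NA),
    dist_c = c(5.40, 4.90, 4.85, 4.82, 4.88, 5.26, 4.96, 4.98, 4.93, 5.60),
    stringsAsFactors = FALSE)
  out$is_g107 <- out$trbv13_2
  out[, c("tcr_name", "trbv13_2", "pdb_id", "cdr3_seq", "is_g107",
          "dist_a", "dist_b", "dist_c")]
}
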