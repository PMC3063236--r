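# End-to-end runners over a manifest: the per-TCR stalk report,
# mutation scan of the G107 structures, and a two-ensemble entropy
# comparison.  Failures are row-scoped: one bad structure never aborts
# a run.

#' Read a structure manifest
#'
#' A manifest is a TSV with columns `pdb_id`, `tcr_name`, `beta_chain`,
#' `cdr3_seq`, `y40_author_number` (optional, NA allowed).  The package
#' ships one pre-filled for the ten crystallographic TCR at
#' `system.file("extdata", "tcr_manifest.tsv", package =
#' "cdr3stalk")`; chain assignments there are best-effort and are
#' re-validated against the CDR3beta sequence at run time, falling back
#' to a unique-match scan over all chains.
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pdb_id", "tcr_name", "beta_chain", "cdr3_seq")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(man$y40_author_number)) man$y40_author_number <- NA_integer_
  man
}

# Anchor a manifest row, falling back to a scan over all chains when
# the stated chain does not carry the CDR3 sequence uniquely.
.anchor_row <- function(struct, row) {
  y40 <- if (is.na(row$y40_author_number)) NULL else row$y40_author_number
  try1 <- try(anchor_imgt(struct, row$beta_chain, row$cdr3_seq,
                          y40_author_number = y40), silent = TRUE)
  if (!inherits(try1, "try-error")) return(try1)
  hits <- Filter(Negate(is.null), lapply(unique(struct$atom$chain),
    function(ch) {
      a <- try(anchor_imgt(struct, ch, row$cdr3_seq,
                           y40_author_number = y40), silent = TRUE)
      if (inherits(a, "try-error")) NULL else a
    }))
  if (length(hits) == 1) {
    message(struct$pdb_id, ": chain ", row$beta_chain,
            " does not carry the CDR3; using chain ",
            hits[[1]]$beta_chain_id)
    return(hits[[1]])
  }
  stop("cannot anchor ", row$cdr3_seq, " in ", struct$pdb_id, ": ",
       attr(try1, "condition")$message)
}

#' Reproduce the per-TCR stalk table and its group summary
#'
#' For every manifest row, parses `<pdb_dir>/<pdb_id>.pdb`, anchors the
#' CDR3beta, measures the distance triple and finally summarises the
#' G107 and S107 groups.  Rows that fail are reported and skipped.
#'
#' @param manifest data frame from [read_manifest()] (or compatible).
#' @param pdb_dir directory holding `<pdb_id>.pdb` files.
#' @param out_dir optional; when given, `stalk_table.tsv` and
#'   `stalk_summary.tsv` are written there.
#' @return List with `table` (per-TCR rows), `summary` (group means and
#'   SDs) and `failures` (data frame of row-level errors).
#' @export
run_stalk_table <- function(manifest, pdb_dir, out_dir = NULL) {
  stopifnot(is.data.frame(manifest), nrow(manifest) >= 1)
  rows <- list(); fails <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- try({
      path <- file.path(pdb_dir, paste0(row$pdb_id, ".pdb"))
      struct <- parse_structure(path, pdb_id = row$pdb_id)
      anchor <- .anchor_row(struct, row)
      measure_stalk(struct, anchor, tcr_name = row$tcr_name)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        pdb_id = row$pdb_id,
        error = conditionMessage(attr(res, "condition")),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows)) stop("no manifest row could be measured")
  tab <- do.call(rbind, rows)
  summ <- summarize_groups(tab)
  fails <- if (length(fails)) do.call(rbind, fails) else
    data.frame(pdb_id = character(), error = character())
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(tab, file.path(out_dir, "stalk_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summ, file.path(out_dir, "stalk_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(table = tab, summary = summ, failures = fails)
}

#' Scan G107 manifest rows for the G107S substitution verdict
#'
#' @inheritParams run_stalk_table
#' @param chi1_set chi1 rotamers scanned, degrees.
#' @param config a [geometry_config()].
#' @return List with `report` (per-structure verdicts and best-rotamer
#'   scores), `results` (named list of `"mutation_result"` objects) and
#'   `failures`.
#' @export
run_mutation_scan <- function(manifest, pdb_dir,
                              chi1_set = c(-60, 60, 180),
                              config = geometry_config(),
                              out_dir = NULL) {
  stopifnot(is.data.frame(manifest))
  g_rows <- manifest[vapply(manifest$cdr3_seq, classify_position107,
                            character(1)) == "G107", , drop = FALSE]
  if (!nrow(g_rows)) {
    warning("manifest has no G107 rows; nothing to scan")
    return(list(report = data.frame(), results = list(),
                failures = data.frame()))
  }
  report <- list(); results <- list(); fails <- list()
  for (i in seq_len(nrow(g_rows))) {
    row <- g_rows[i, ]
    res <- try({
      struct <- parse_structure(
        file.path(pdb_dir, paste0(row$pdb_id, ".pdb")),
        pdb_id = row$pdb_id)
      anchor <- .anchor_row(struct, row)
      place_serine(struct, anchor, chi1_set = chi1_set, config = config)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        pdb_id = row$pdb_id,
        error = conditionMessage(attr(res, "condition")),
        stringsAsFactors = FALSE)
      next
    }
    results[[row$pdb_id]] <- res
    best <- if (is.na(res$best)) NA else res$placements[res$best, ]
    report[[length(report) + 1L]] <- data.frame(
      pdb_id = row$pdb_id, tcr_name = row$tcr_name,
      verdict = res$verdict,
      best_chi1 = if (is.na(res$best)) NA_real_ else best$chi1,
      best_n_hbonds = if (is.na(res$best)) NA_integer_ else best$n_hbonds,
      best_clashes = if (is.na(res$best)) NA_integer_ else best$clash_count,
      stringsAsFactors = FALSE)
  }
  report <- if (length(report)) do.call(rbind, report) else data.frame()
  fails <- if (length(fails)) do.call(rbind, fails) else
    data.frame(pdb_id = character(), error = character())
  if (!is.null(out_dir) && nrow(report)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report, file.path(out_dir, "mutation_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(report = report, results = results, failures = fails)
}

#' Compare two trajectory ensembles: RMSD series and entropies
#'
#' @param traj_a,traj_b `"trajectory_ensemble"` objects with matching
#'   atom counts (e.g. wild-type and mutant loop backbones).
#' @param temperature Kelvin.
#' @param out_dir optional output directory for TSV reports.
#' @return List with `rmsd_a`, `rmsd_b`, `entropy_a`, `entropy_b` and
#'   `difference` (S_a - S_b, cal mol^-1 K^-1).
#' @export
run_entropy_compare <- function(traj_a, traj_b, temperature = 300,
                                out_dir = NULL) {
  stopifnot(inherits(traj_a, "trajectory_ensemble"),
            inherits(traj_b, "trajectory_ensemble"))
  if (traj_a$n_atoms != traj_b$n_atoms)
    stop("ensembles have different atom counts (",
         traj_a$n_atoms, " vs ", traj_b$n_atoms, ")")
  ra <- rmsd_series(traj_a); rb <- rmsd_series(traj_b)
  ea <- quasiharmonic_entropy(traj_a, temperature)
  eb <- quasiharmonic_entropy(traj_b, temperature)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(
      data.frame(frame = ra$frame, rmsd_a = ra$rmsd, rmsd_b = rb$rmsd),
      file.path(out_dir, "rmsd_series.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(ensemble = c("a", "b"),
                 entropy = c(ea$entropy, eb$entropy),
                 n_modes = c(ea$n_modes_used, eb$n_modes_used)),
      file.path(out_dir, "entropy_summary.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(rmsd_a = ra, rmsd_b = rb, entropy_a = ea, entropy_b = eb,
       difference = ea$entropy - eb$entropy)
}
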