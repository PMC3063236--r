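# Census of TRBV C-terminal motifs.  Germline V-gene protein C-termini
# end shortly after the conserved cysteine at IMGT 104; each sequence is
# classified CASS / CASG / other by the residues at IMGT 104-107.

#' Read V-gene C-terminal sequences from FASTA
#'
#' Headers must be `name|species` (e.g. `TRBV13-2|mouse`); duplicate
#' gene names within a file are rejected.
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Data frame with `gene_name`, `species`, `cterm_seq`.
#' @export
read_vgene_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) stop("no sequences in ", path)
  headers <- names(set)
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2)
  if (length(bad))
    stop("entry ", bad[1], " ('", headers[bad[1]],
         "'): header must be 'name|species'")
  gene <- vapply(parts, `[`, character(1), 1)
  species <- vapply(parts, `[`, character(1), 2)
  if (anyDuplicated(gene))
    stop("duplicate gene name(s): ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (any(!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seqs)))
    stop("non-amino-acid characters in sequence(s)")
  data.frame(gene_name = gene, species = species, cterm_seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Classify a V-gene C-terminus by its IMGT 104-107 motif
#'
#' The anchoring C104 is the last cysteine followed by alanine within
#' the final 16 residues (wide enough to anchor both germline
#' C-termini, which end a few residues after C104, and full rearranged
#' CDR3beta strings); the motif is that cysteine plus the next three
#' residues.  Sequences without an anchor (or too short after it)
#' are unclassifiable and counted as `"other"` with a warning.
#'
#' @param cterm_seq amino-acid string containing the conserved C104.
#' @return `"CASS"`, `"CASG"` or `"other"`.
#' @examples
#' classify_motif("GEGSGSQIVQCASSLG")  # "CASS"
#' @export
classify_motif <- function(cterm_seq) {
  s <- toupper(cterm_seq)
  n <- nchar(s)
  tail_start <- max(1L, n - 15L)
  tail <- substr(s, tail_start, n)
  m <- gregexpr("CA", tail, fixed = TRUE)[[1]]
  if (m[1] == -1) {
    warning("no C104 anchor (C followed by A) in '", cterm_seq,
            "'; counted as other")
    return("other")
  }
  pos <- tail_start + m[length(m)] - 1L   # last CA occurrence
  if (pos + 3L > n) {
    warning("anchor too close to the end of '", cterm_seq,
            "'; counted as other")
    return("other")
  }
  motif <- substr(s, pos, pos + 3L)
  if (motif == "CASS") "CASS" else if (motif == "CASG") "CASG" else "other"
}

#' Per-species census of CASS/CASG motifs
#'
#' @param records data frame from [read_vgene_fasta()].
#' @return Data frame with one row per species: `species`, `n_total`,
#'   `n_CASS`, `n_CASG`, `n_other`, and integer-rounded percentages
#'   `pct_CASS`, `pct_CASG`, `pct_other`.
#' @export
census <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("species", "cterm_seq") %in% names(records)))
  cls <- vapply(records$cterm_seq, classify_motif, character(1),
                USE.NAMES = FALSE)
  out <- do.call(rbind, lapply(split(cls, records$species), function(v) {
    data.frame(n_total = length(v),
               n_CASS = sum(v == "CASS"),
               n_CASG = sum(v == "CASG"),
               n_other = sum(v == "other"))
  }))
  out$species <- rownames(out)
  rownames(out) <- NULL
  for (k in c("CASS", "CASG", "other"))
    out[[paste0("pct_", k)]] <- round(100 * out[[paste0("n_", k)]] /
                                        out$n_total)
  out[, c("species", "n_total", "n_CASS", "n_CASG", "n_other",
          "pct_CASS", "pct_CASG", "pct_other")]
}
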