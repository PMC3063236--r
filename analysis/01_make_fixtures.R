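#!/usr/bin/env Rscript
# Generate every fixture the downstream analyses use: idealized CASG
# and CASS hairpin structures (plus a no-tyrosine control), a pair of
# Gaussian-fluctuation loop ensembles (floppy "wild-type" vs stiff
# "mutant"), and toy TRBV sequence sets with the reported species
# compositions.  All generators are deterministic.

suppressMessages(library(cdr3stalk))
seed <- 20260929L
out <- "results/fixtures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

manifests <- list()
for (cfg in list(
  list(spec = hairpin_spec(), name = "hp_casg"),
  list(spec = hairpin_spec(loop_sequence = "CASSDAGGGYEQYF"),
       name = "hp_cass"),
  list(spec = hairpin_spec(y40_aa = "A"), name = "hp_noy40"))) {
  hp <- make_hairpin(cfg$spec, seed = seed, name = cfg$name)
  write_structure(hp$struct, file.path(out, paste0(cfg$name, ".pdb")))
  manifests[[cfg$name]] <- hp$manifest
}
man <- do.call(rbind, manifests)
write.table(man, file.path(out, "fixture_manifest.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", nrow(man), "hairpin fixtures and their manifest\n")

# trajectory pair: same loop-sized selection, fluctuations 4x larger
# in the floppy ensemble
invisible(make_gaussian_trajectory(
  gaussian_traj_spec(n_atoms = 48, n_frames = 400, variances = 0.20),
  seed = seed, path = file.path(out, "traj_floppy.pdb")))
invisible(make_gaussian_trajectory(
  gaussian_traj_spec(n_atoms = 48, n_frames = 400, variances = 0.05),
  seed = seed + 1L, path = file.path(out, "traj_stiff.pdb")))
cat("wrote trajectory pair (400 frames x 48 pseudo-atoms)\n")

make_trbv_fasta(18, 1, 4, "mouse", seed = seed,
                path = file.path(out, "trbv_mouse.fasta"))
make_trbv_fasta(45, 1, 8, "human", seed = seed,
                path = file.path(out, "trbv_human.fasta"))
cat("wrote TRBV sets: mouse 18 CASS + 1 CASG + 4 other,",
    "human 45 + 1 + 8\n")
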