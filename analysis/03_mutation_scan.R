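#!/usr/bin/env Rscript
# G107S modelling on a rigid backbone.  On the CASG hairpin fixture the
# serine side chain must fit at a canonical chi1 rotamer without
# moving or clashing with any existing atom, hydrogen-bond the
# engineered Y40 hydroxyl, and fill the cavity the glycine leaves; an
# occluded pocket must flip the verdict.

suppressMessages(library(cdr3stalk))
dir.create("results", showWarnings = FALSE)

fx <- read_manifest("results/fixtures/fixture_manifest.tsv")
scan <- run_mutation_scan(fx, "results/fixtures",
                          out_dir = "results/mutation")
cat("Mutation scan over CASG fixtures:\n")
print(scan$report, row.names = FALSE)

hp <- parse_structure("results/fixtures/hp_casg.pdb")
a <- anchor_imgt(hp, "A", "CASGDAGGGYEQYF", y40_author_number = 40)
mr <- place_serine(hp, a)
cat("\nPer-rotamer detail on hp_casg:\n")
print(mr$placements[, c("chi1", "clash_count", "max_overlap",
                        "n_hbonds", "feasible")], row.names = FALSE)
cat("\nHydrogen-bond partners of the best rotamer:\n")
print(mr$hbonds[[mr$best]], row.names = FALSE)

env <- structure_atoms(hp)
env <- env[!(env$resno %in% 106:108), ]
og <- as.numeric(mr$placements[mr$best, c("og_x", "og_y", "og_z")])
pre <- probe_gap(og, env)
mut <- apply_placement(hp, a, mr)
env_mut <- structure_atoms(mut)
env_mut <- env_mut[!(env_mut$resno == 107 & env_mut$name != "OG"), ]
post <- probe_gap(og, env_mut)
cat(sprintf("\nCavity probe at the placed hydroxyl site: free radius %.2f A %s-> %.2f A %s\n",
            pre$max_free_radius,
            if (pre$gap_present) "(open) " else "(closed) ",
            post$max_free_radius,
            if (post$gap_present) "(open)" else "(filled)"))
write_structure(mut, "results/mutation/hp_casg_G107S.pdb")
cat("mutated fixture written to results/mutation/hp_casg_G107S.pdb\n")
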