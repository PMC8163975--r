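#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study inputs.
#
# Emulates the three data streams the downstream stages consume: a panel of
# two-chain complex structures with known (planted) interface contacts, the
# companion GTPase/effector alignments, and fluorescence-polarization
# titration tables at the affinities the binding analysis must resolve.
# Everything is seeded, so reruns are byte-identical.

suppressMessages(library(raseffector))

out_root <- "results/simulated"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

seed <- 20260930

# -- complex ensemble ---------------------------------------------------------
# 19 complexes (the size of a well-populated crystal-structure panel for one
# effector family), sharing two universal "hotspot" contacts plus sporadic
# peripheral contacts in 30% of complexes.
core <- data.frame(gtpase = c(3, 5), effector = c(7, 2))
ens <- synth_ensemble(core, peripheral_rate = 0.3, n_complexes = 19,
                      seed = seed, n_gtpase = 20, n_effector = 15,
                      out_dir = file.path(out_root, "structures"))
alns <- synth_ensemble_alignments(ens, n_decoys = 3, seed = seed + 1)
write_alignment(alns$gtpase, file.path(out_root, "gtpase.fasta"))
write_alignment(alns$effector, file.path(out_root, "effector.fasta"))
utils::write.table(
  data.frame(gtpase = which(ens$truth > 0, arr.ind = TRUE)[, 1],
             effector = which(ens$truth > 0, arr.ind = TRUE)[, 2],
             n_planted = ens$truth[ens$truth > 0]),
  file.path(out_root, "planted_truth.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("ensemble: %d complexes, %d planted pairs (%d universal)\n",
            ens$n_complexes, sum(ens$truth > 0), sum(ens$truth == 19)))

# -- titration panel ----------------------------------------------------------
# One curve per affinity band plus the printed headline affinities.
panel <- c(craf_like = 0.3, rit1_rassf9 = 27, rit1_rassf7 = 34,
           rala_rassf9to5 = 35, rit1_rassf2to1 = 65, rheb_like = 200)
tdir <- file.path(out_root, "titrations")
dir.create(tdir, showWarnings = FALSE)
for (i in seq_along(panel)) {
  d <- simulate_titration(titration_spec(panel[[i]], seed = seed + i))
  write_titration(d, file.path(tdir, paste0(names(panel)[i], ".csv")))
}
cat(sprintf("titrations: %d curves at Kd = %s uM -> %s\n",
            length(panel), paste(panel, collapse = ", "), tdir))
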