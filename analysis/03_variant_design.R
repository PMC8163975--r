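#!/usr/bin/env Rscript

# Stage 3: hotspot residue-swap variant design.
#
# Demonstrates the swap logic on alignment windows modeled after the
# RASSF RA-domain hotspot region: transplanting the donor's hotspot residues
# onto an acceptor produces the familiar slash-separated mutation strings,
# and applying a proposal is idempotent (re-proposing finds nothing left to
# swap). Windows are small alignment excerpts in each acceptor's construct
# numbering frame.

suppressMessages(library(raseffector))

dir.create("results/variants", recursive = TRUE, showWarnings = FALSE)

# Each case: an acceptor/donor window, the hotspot columns within it, and
# the offset placing column counts into the acceptor's construct numbering.
cases <- list(
  RASSF2_to_1 = list(acceptor = "RASSF2", donor = "RASSF1",
                     acc_seq = "AYSPVT", don_seq = "KDSPKH",
                     hotspots = c(1, 2, 5, 6), offset = 185),
  RASSF9_to_5 = list(acceptor = "RASSF9", donor = "RASSF5",
                     acc_seq = "VAGLPKR", don_seq = "DAIKPLH",
                     hotspots = c(1, 3, 4, 6, 7), offset = 39))

rows <- list()
for (nm in names(cases)) {
  cs <- cases[[nm]]
  aln <- msa(c(cs$acceptor, cs$donor), c(cs$acc_seq, cs$don_seq))
  p <- propose_swap(aln, cs$donor, cs$acceptor, cs$hotspots, cs$offset)
  cat(sprintf("%s: %s\n", nm, format_variant(p)))

  # round trip: applying the proposal leaves nothing to swap
  aln2 <- msa(c(aln$names, "variant"),
              c(unname(aln$seqs), apply_variant(aln, p)))
  p2 <- propose_swap(aln2, cs$donor, "variant", cs$hotspots, cs$offset)
  stopifnot(nrow(p2$substitutions) == 0)
  cat(sprintf("  round trip after applying swaps: %s\n", format_variant(p2)))

  rows[[nm]] <- data.frame(variant = nm, acceptor = cs$acceptor,
                           donor = cs$donor, mutations = format_variant(p),
                           n_substitutions = nrow(p$substitutions))
}

utils::write.table(do.call(rbind, rows), "results/variants/proposals.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

# The published RASSF4-to-5 string repeats position 188 with two different
# wild-type residues; the proposal validator refuses such input.
bad <- tryCatch(
  variant_proposal("RASSF5", "RASSF4",
                   data.frame(position = c(185, 187, 188, 188),
                              acceptor_aa = c("Y", "S", "V", "N"),
                              donor_aa = c("D", "I", "K", "L"))),
  error = function(e) conditionMessage(e))
cat("duplicated-position input rejected:", bad, "\n")
cat("artifacts: results/variants/proposals.tsv\n")
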