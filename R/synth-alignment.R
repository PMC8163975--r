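#' Generate an alignment with planted conserved and variable columns
#'
#' Builds a gap-free alignment in which every column in `conserved_cols`
#' carries residues from a single similarity group (so the conservation
#' classifier must label it conserved at any threshold) and every other
#' column carries residues from two distinct groups split as evenly as
#' possible (so at most `ceiling(n_rows/2)/n_rows < 0.9` of residues share a
#' group and the classifier must label it variable at the default threshold).
#'
#' @param n_rows Number of rows (at least 2).
#' @param n_cols Alignment width.
#' @param conserved_cols Integer set of planted conserved column indices.
#' @param groups Similarity groups, as [similarity_groups()].
#' @param seed Integer seed.
#' @param gap_positions Optional data frame (`row`, `col`) of explicit gaps,
#'   never in the reference (first) row; gaps that would leave a variable
#'   column with fewer than two groups are rejected.
#' @return An [msa()] whose first row (`"seq1"`) is the reference.
#' @export
synth_alignment <- function(n_rows, n_cols, conserved_cols = integer(),
                            groups = similarity_groups(), seed = 1L,
                            gap_positions = NULL) {
  if (!is_count(n_rows) || n_rows < 2)
    stop_config("n_rows must be at least 2")
  if (!is_count(n_cols) || n_cols < 1)
    stop_config("n_cols must be a positive integer")
  conserved_cols <- as.integer(conserved_cols)
  if (length(conserved_cols) &&
      (min(conserved_cols) < 1 || max(conserved_cols) > n_cols))
    stop_config("conserved_cols outside 1..n_cols")

  with_seed(seed, {
    m <- matrix("", n_rows, n_cols)
    for (j in seq_len(n_cols)) {
      if (j %in% conserved_cols) {
        g <- groups[[sample.int(length(groups), 1)]]
        m[, j] <- sample(g, n_rows, replace = TRUE)
      } else {
        gi <- sample.int(length(groups), 2)
        g1 <- groups[[gi[1]]]; g2 <- groups[[gi[2]]]
        half <- n_rows %/% 2
        col <- c(sample(g1, half, replace = TRUE),
                 sample(g2, n_rows - half, replace = TRUE))
        m[, j] <- sample(col)
      }
    }
    if (!is.null(gap_positions)) {
      gp <- as.data.frame(gap_positions)
      if (any(gp$row == 1))
        stop_config("gaps are not allowed in the reference row")
      lookup <- group_lookup(groups)
      for (k in seq_len(nrow(gp))) {
        j <- gp$col[k]
        trial <- m[, j]
        trial[gp$row[k]] <- "-"
        nz <- trial[trial != "-"]
        if (!(j %in% conserved_cols) && length(unique(lookup(nz))) < 2)
          stop_config("gap at (", gp$row[k], ",", j,
                      ") would break the planted variable column")
        m[, j] <- trial
      }
    }
    msa(paste0("seq", seq_len(n_rows)), apply(m, 1, paste, collapse = ""),
        reference_row = "seq1")
  })
}

#' Companion alignments for a synthetic complex ensemble
#'
#' Builds one GTPase-side and one effector-side alignment whose reference
#' rows are exactly the ensemble's chain sequences (so every structure
#' residue maps to its own column and the interaction matrix lands on
#' 1-based reference numbering). Decoy rows are group-preserving mutations of
#' the reference so conservation structure is non-trivial but mapping is
#' unambiguous.
#'
#' @param ens A [synth_ensemble()] result.
#' @param n_decoys Decoy rows added per alignment (at least 1, so the
#'   alignments have the 2 rows conservation calls require).
#' @param mutation_rate Per-position probability that a decoy row swaps the
#'   residue for another amino acid.
#' @param seed Integer seed.
#' @return List with `gtpase` and `effector` [msa()] objects; reference rows
#'   are named `"gtpase_ref"` and `"effector_ref"`.
#' @export
synth_ensemble_alignments <- function(ens, n_decoys = 2, mutation_rate = 0.3,
                                      seed = 1L) {
  stopifnot(inherits(ens, "synth_ensemble"))
  if (!is_count(n_decoys) || n_decoys < 1)
    stop_config("n_decoys must be at least 1")
  with_seed(seed, {
    mutate <- function(seq) {
      aa <- strsplit(seq, "")[[1]]
      hit <- stats::runif(length(aa)) < mutation_rate
      aa[hit] <- vapply(aa[hit],
                        function(a) sample(setdiff(AA1, a), 1), "")
      paste(aa, collapse = "")
    }
    build <- function(refname, refseq) {
      decoys <- vapply(seq_len(n_decoys), function(i) mutate(refseq), "")
      msa(c(refname, paste0(refname, "_decoy", seq_len(n_decoys))),
          c(refseq, decoys), reference_row = refname)
    }
    list(gtpase = build("gtpase_ref", ens$gtpase_seq),
         effector = build("effector_ref", ens$effector_seq))
  })
}
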