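#' Multiple sequence alignment container
#'
#' @param names Row names (unique).
#' @param seqs Gapped sequences (equal length, `-` for gaps).
#' @param reference_row Name of the reference row (e.g. HRAS for the GTPase
#'   alignment, CRAF or RASSF5 for the effector alignments).
#' @return Object of class `msa`: list with `names`, `seqs` (named character
#'   vector, uppercase), `width`, `reference_row`.
#' @export
msa <- function(names, seqs, reference_row = names[1]) {
  names <- as.character(names)
  seqs <- toupper(as.character(seqs))
  if (length(names) != length(seqs))
    stop_data("names and sequences differ in length")
  if (anyDuplicated(names))
    stop_data("duplicate row names: ",
              paste(unique(names[duplicated(names)]), collapse = ", "))
  w <- nchar(seqs)
  if (length(unique(w)) > 1)
    stop_data("ragged alignment rows: ",
              paste(names[w != w[1]], collapse = ", "))
  if (!reference_row %in% names)
    stop_data("reference row ", reference_row, " not in alignment")
  names(seqs) <- names
  structure(list(names = names, seqs = seqs, width = w[1],
                 reference_row = reference_row),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", length(x$names), "rows x", x$width, "columns (reference:",
      x$reference_row, ")\n")
  invisible(x)
}

# alignment as a character matrix (rows x columns)
msa_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$seqs), ""))
  rownames(m) <- aln$names
  m
}

#' Read a multiple sequence alignment (FASTA or Clustal)
#'
#' @param path File path.
#' @param format `"fasta"` or `"clustal"`.
#' @param reference_row Reference row name (defaults to the first row).
#' @return An [msa()] object.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"),
                           reference_row = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_data("alignment file not found: ", path)
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) stop_data("cannot parse ", path, ": ",
                                                  conditionMessage(e)))
    if (length(set) == 0) stop_data("no sequences in ", path)
    nm <- sub("\\s.*$", "", names(set))
    seqs <- as.character(set)
  } else {
    al <- tryCatch(Biostrings::readAAMultipleAlignment(path, format = "clustal"),
                   error = function(e) stop_data("cannot parse ", path, ": ",
                                                 conditionMessage(e)))
    set <- Biostrings::unmasked(al)
    nm <- names(set)
    seqs <- as.character(set)
  }
  if (is.null(reference_row)) reference_row <- nm[1]
  msa(nm, seqs, reference_row)
}

#' Write an alignment as FASTA or Clustal
#'
#' @param aln An `msa`.
#' @param path Output path.
#' @param format `"fasta"` or `"clustal"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "clustal")) {
  stopifnot(inherits(aln, "msa"))
  format <- match.arg(format)
  if (format == "fasta") {
    writeLines(as.vector(rbind(paste0(">", aln$names), unname(aln$seqs))),
               path)
  } else {
    wname <- max(nchar(aln$names)) + 3
    lines <- c("CLUSTAL W multiple sequence alignment", "")
    for (start in seq(1, aln$width, by = 60)) {
      end <- min(start + 59, aln$width)
      lines <- c(lines, "",
                 sprintf("%-*s%s", wname, aln$names,
                         substr(unname(aln$seqs), start, end)))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Default amino-acid similarity groups
#'
#' The reduced alphabet used for conservation calls, following the standard
#' substitution pairings seen in homolog comparisons (D/E, K/R, N/Q, S/T,
#' aliphatic, aromatic, small).
#'
#' @return Named list of character vectors partitioning the 20 amino acids.
#' @export
similarity_groups <- function() {
  list(acidic = c("D", "E"), basic = c("K", "R"), amide = c("N", "Q"),
       hydroxyl = c("S", "T"), aliphatic = c("I", "V", "L", "M"),
       aromatic = c("F", "Y", "W"), small = c("A", "G"),
       C = "C", H = "H", P = "P")
}

# residue -> group name lookup; residues outside the groups become their own
# singleton groups (so 'X' never merges columns)
group_lookup <- function(groups) {
  lk <- character()
  for (g in names(groups)) lk[groups[[g]]] <- g
  function(aa) {
    out <- lk[aa]
    miss <- is.na(out)
    out[miss] <- aa[miss]
    out
  }
}

#' Classify alignment columns as conserved or variable
#'
#' A column is conserved when at least `threshold` of its non-gap residues
#' fall in a single similarity group; all-gap columns are variable.
#'
#' @param aln An [msa()] with at least two rows.
#' @param groups Similarity groups, as [similarity_groups()].
#' @param threshold Fraction of non-gap residues required, default 0.9.
#' @return Data frame of class `conservation_label`: `column`, `label`
#'   (`"conserved"` or `"variable"`), `witness_group` (NA for variable),
#'   `n_nongap`.
#' @export
classify_columns <- function(aln, groups = similarity_groups(),
                             threshold = 0.9) {
  stopifnot(inherits(aln, "msa"))
  if (length(aln$names) < 2) stop_data("alignment needs at least 2 rows")
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold > 1)
    stop_config("threshold must be in (0, 1]")
  lookup <- group_lookup(groups)
  m <- msa_matrix(aln)
  out <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[col != "-" & col != "."]
    if (length(col) == 0)
      return(data.frame(column = j, label = "variable",
                        witness_group = NA_character_, n_nongap = 0L))
    tab <- table(lookup(col))
    best <- which.max(tab)
    if (tab[best] / length(col) >= threshold) {
      data.frame(column = j, label = "conserved",
                 witness_group = names(tab)[best], n_nongap = length(col))
    } else {
      data.frame(column = j, label = "variable",
                 witness_group = NA_character_, n_nongap = length(col))
    }
  })
  out <- do.call(rbind, out)
  class(out) <- c("conservation_label", "data.frame")
  out
}

#' Reference numbering for alignment columns
#'
#' Labels each column in the numbering of the reference row: the k-th non-gap
#' reference column gets `reference_start_number + k - 1` with the reference
#' amino acid (e.g. `"E37"`); columns gapped in the reference are insertion
#' columns anchored to the preceding number (`"37+1"`, `"37+2"`, ...).
#'
#' @param aln An [msa()].
#' @param reference_start_number Number of the first reference residue (e.g.
#'   1 for full-length HRAS, 51 for a CRAF construct starting at residue 51).
#' @return Data frame of class `reference_label`: `column`, `label`,
#'   `number` (anchor residue number), `insertion` (logical), `ref_aa`.
#' @export
reference_labels <- function(aln, reference_start_number = 1L) {
  stopifnot(inherits(aln, "msa"))
  ref <- strsplit(unname(aln$seqs[aln$reference_row]), "")[[1]]
  number <- integer(aln$width)
  label <- character(aln$width)
  insertion <- logical(aln$width)
  ref_aa <- character(aln$width)
  n <- as.integer(reference_start_number) - 1L
  ins <- 0L
  for (j in seq_along(ref)) {
    if (ref[j] == "-" || ref[j] == ".") {
      ins <- ins + 1L
      number[j] <- n
      insertion[j] <- TRUE
      ref_aa[j] <- NA_character_
      label[j] <- sprintf("%d+%d", n, ins)
    } else {
      n <- n + 1L
      ins <- 0L
      number[j] <- n
      ref_aa[j] <- ref[j]
      label[j] <- sprintf("%s%d", ref[j], n)
    }
  }
  out <- data.frame(column = seq_len(aln$width), label = label,
                    number = number, insertion = insertion, ref_aa = ref_aa)
  class(out) <- c("reference_label", "data.frame")
  out
}

# +1/-1 substitution matrix over the residue alphabet (incl. X), used for the
# structure-to-row matching below
swap_submat <- function() {
  alpha <- c(AA1, "X")
  m <- matrix(-1, length(alpha), length(alpha),
              dimnames = list(alpha, alpha))
  diag(m) <- 1
  m
}

#' Map structure residues to alignment columns
#'
#' Matches a chain's residue sequence (from the structure) to its row in the
#' alignment by global pairwise alignment (match +1, mismatch -1, gap open 5,
#' gap extend 0.5), then composes with the row's gap pattern to obtain, for
#' each structure residue, its alignment column. Author residue numbering in
#' the structure is never used for the matching, only for reporting. Residues
#' aligned to gaps in the row are reported as unmapped; aligned mismatches
#' (sequence/structure discrepancies) are kept and counted.
#'
#' @param residues Ordered residue table from [chain_residues()] (`resno`,
#'   `insert`, `aa`).
#' @param aln An [msa()].
#' @param row Name of the alignment row this chain corresponds to.
#' @param min_identity Identity guard over aligned (non-gap) positions;
#'   matches below this fraction fail, protecting against wrong-row
#'   assignment. Default 0.8.
#' @return Object of class `residue_column_map`: list with `entries` (data
#'   frame `resno`, `insert`, `aa`, `column`), `unmapped` (same columns minus
#'   `column`), `identity`, `row`.
#' @export
map_chain_to_row <- function(residues, aln, row, min_identity = 0.8) {
  stopifnot(inherits(aln, "msa"))
  if (!row %in% aln$names) stop_data("row ", row, " not in alignment")
  gapped <- strsplit(unname(aln$seqs[row]), "")[[1]]
  row_cols <- which(gapped != "-" & gapped != ".")
  row_seq <- paste(gapped[row_cols], collapse = "")
  chain_seq <- paste(residues$aa, collapse = "")
  if (nchar(row_seq) == 0) stop_data("row ", row, " is all gaps")

  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(chain_seq), Biostrings::AAString(row_seq),
    type = "global", substitutionMatrix = swap_submat(),
    gapOpening = 5, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]

  pi <- 0L; si <- 0L
  res_col <- rep(NA_integer_, nrow(residues))
  n_pair <- 0L; n_match <- 0L
  for (k in seq_along(p)) {
    if (p[k] != "-") pi <- pi + 1L
    if (s[k] != "-") si <- si + 1L
    if (p[k] != "-" && s[k] != "-") {
      n_pair <- n_pair + 1L
      if (p[k] == s[k]) n_match <- n_match + 1L
      res_col[pi] <- row_cols[si]
    }
  }
  identity <- if (n_pair > 0) n_match / n_pair else 0
  if (identity < min_identity)
    stop_data(sprintf(
      "chain/row identity %.1f%% below guard (%.0f%%) for row %s",
      100 * identity, 100 * min_identity, row))

  mapped <- !is.na(res_col)
  entries <- cbind(residues[mapped, , drop = FALSE],
                   column = res_col[mapped])
  rownames(entries) <- NULL
  unmapped <- residues[!mapped, , drop = FALSE]
  rownames(unmapped) <- NULL
  structure(list(entries = entries, unmapped = unmapped,
                 identity = identity, row = row),
            class = "residue_column_map")
}

#' @export
print.residue_column_map <- function(x, ...) {
  cat(sprintf("residue_column_map: row %s, %d mapped, %d unmapped, %.1f%% identity\n",
              x$row, nrow(x$entries), nrow(x$unmapped), 100 * x$identity))
  invisible(x)
}
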