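#' Read a protein complex structure (PDB or mmCIF)
#'
#' Thin wrapper around bio3d's parsers returning a uniform atom table with
#' the filtering conventions used throughout the package: heteroatoms (waters,
#' nucleotide analogs, ions) are flagged, hydrogens are flagged, and alternate
#' locations are resolved to the highest-occupancy conformer (ties broken by
#' altloc identifier order).
#'
#' @param path Path to the structure file.
#' @param format `"pdb"` or `"mmcif"` (`"cif"` accepted as a synonym).
#' @param model_index 1-based model to use for multi-model files.
#' @return An object of class `complex_structure`: a list with `atoms` (data
#'   frame: `chain`, `resno`, `insert`, `resid`, `aa`, `elety`, `elesy`, `x`,
#'   `y`, `z`, `het`, `hydrogen`), `n_models` and `path`.
#' @export
read_structure <- function(path, format = c("pdb", "mmcif", "cif"),
                           model_index = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_data("structure file not found: ", path)
  parsed <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    } else {
      bio3d::read.cif(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) stop_data("cannot parse ", path, ": ",
                                  conditionMessage(e)))
  a <- parsed$atom
  if (is.null(a) || nrow(a) == 0)
    stop_data("no ATOM records in ", path)
  n_models <- if (is.matrix(parsed$xyz)) nrow(parsed$xyz) else 1L
  if (model_index < 1 || model_index > n_models)
    stop_data("model_index ", model_index, " out of range (file has ",
              n_models, " models)")
  if (model_index > 1) {
    xyz <- matrix(parsed$xyz[model_index, ], ncol = 3, byrow = TRUE)
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  }
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  elesy <- if (!is.null(a$elesy) && !all(is.na(a$elesy))) {
    toupper(trimws(a$elesy))
  } else {
    toupper(substr(trimws(a$elety), 1, 1))
  }
  atoms <- data.frame(
    chain = a$chain, resno = a$resno, insert = a$insert, resid = a$resid,
    aa = aa_three_to_one(a$resid), elety = a$elety, elesy = elesy,
    alt = a$alt, occ = a$o, x = a$x, y = a$y, z = a$z,
    het = a$type == "HETATM" | a$resid %in% c("HOH", "WAT", "DOD"),
    hydrogen = elesy %in% c("H", "D"),
    stringsAsFactors = FALSE)
  atoms <- resolve_altloc(atoms)
  structure(list(atoms = atoms, n_models = n_models, path = path),
            class = "complex_structure")
}

# Keep, per (chain, residue, atom name), the highest-occupancy alternate
# location; ties broken by altloc identifier order ("" sorts first).
resolve_altloc <- function(atoms) {
  if (all(atoms$alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  ord <- order(key, -atoms$occ, atoms$alt)
  keep <- !duplicated(key[ord])
  atoms[sort(ord[keep]), , drop = FALSE]
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("complex_structure:", x$path, "\n")
  poly <- x$atoms[!x$atoms$het, ]
  for (ch in unique(poly$chain)) {
    n <- length(unique(poly$resno[poly$chain == ch]))
    cat("  chain", ch, "-", n, "residues\n")
  }
  invisible(x)
}

# Polymer heavy atoms of one chain; residues that end up with no heavy atoms
# are dropped with a warning rather than failing the complex.
chain_heavy_atoms <- function(struct, chain) {
  a <- struct$atoms
  if (!chain %in% a$chain)
    stop_data("chain ", chain, " not present in ", struct$path)
  a <- a[a$chain == chain & !a$het, , drop = FALSE]
  if (nrow(a) == 0)
    stop_data("chain ", chain, " has no polymer atoms in ", struct$path)
  all_res <- unique(a[c("resno", "insert")])
  a <- a[!a$hydrogen, , drop = FALSE]
  kept <- unique(a[c("resno", "insert")])
  if (nrow(kept) < nrow(all_res)) {
    lost <- nrow(all_res) - nrow(kept)
    warning(lost, " residue(s) in chain ", chain,
            " have no heavy atoms and were skipped", call. = FALSE)
  }
  if (nrow(a) == 0)
    stop_data("chain ", chain, " has no heavy atoms in ", struct$path)
  a
}

#' Ordered residues of a chain
#'
#' @param struct A `complex_structure`.
#' @param chain Chain identifier.
#' @return Data frame of the chain's polymer residues in file order:
#'   `resno`, `insert`, `aa`.
#' @export
chain_residues <- function(struct, chain) {
  a <- chain_heavy_atoms(struct, chain)
  res <- a[!duplicated(paste(a$resno, a$insert, sep = "\r")),
           c("resno", "insert", "aa")]
  rownames(res) <- NULL
  res
}

#' One-letter sequence of a chain
#'
#' @inheritParams chain_residues
#' @return Character scalar.
#' @export
chain_sequence <- function(struct, chain) {
  paste(chain_residues(struct, chain)$aa, collapse = "")
}

#' Minimum heavy-atom distance between two residues
#'
#' @param resA,resB Data frames of atom coordinates (columns `x`, `y`, `z`),
#'   one row per heavy atom. Symmetric in its arguments.
#' @return Minimum Euclidean distance over all atom pairs, in Angstrom.
#' @examples
#' residue_min_distance(data.frame(x = 0, y = 0, z = 0),
#'                      data.frame(x = 3, y = 4, z = 0))  # 5
#' @export
residue_min_distance <- function(resA, resB) {
  if (nrow(resA) == 0 || nrow(resB) == 0)
    stop_data("residue with no heavy atoms")
  A <- as.matrix(resA[, c("x", "y", "z")])
  B <- as.matrix(resB[, c("x", "y", "z")])
  # explicit coordinate differences: exact to machine precision, unlike the
  # expanded |a|^2 + |b|^2 - 2ab form
  best <- Inf
  for (i in seq_len(nrow(A))) {
    d2 <- (B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 + (B[, 3] - A[i, 3])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

#' Extract intermolecular residue contacts from a complex
#'
#' A GTPase residue and an effector residue are in contact when the minimum
#' distance over all their heavy-atom pairs is at or below `cutoff` (default
#' 4.0 Angstrom). Each residue pair is reported once regardless of how many
#' atom pairs qualify; intra-chain pairs and non-polymer entities (waters,
#' nucleotide analogs, ions) are never reported.
#'
#' Internally a center/radius spatial prefilter skips residue pairs whose
#' bounding spheres cannot approach within the cutoff; only survivors get the
#' exact all-atom-pair minimum. The result is identical to a brute-force scan.
#'
#' @param struct A `complex_structure` from [read_structure()].
#' @param gtpase_chain,effector_chain Chain identifiers (GTPase side first;
#'   sides are never swapped in the output).
#' @param cutoff Contact cutoff, Angstrom.
#' @return Data frame of class `residue_contacts`: `gtpase_resno`,
#'   `gtpase_insert`, `gtpase_aa`, `effector_resno`, `effector_insert`,
#'   `effector_aa`, `min_distance`, sorted by GTPase then effector residue.
#' @export
extract_contacts <- function(struct, gtpase_chain, effector_chain,
                             cutoff = 4.0) {
  stopifnot(inherits(struct, "complex_structure"))
  if (!is_scalar_number(cutoff) || cutoff <= 0)
    stop_config("cutoff must be a positive number")
  if (identical(gtpase_chain, effector_chain))
    stop_config("GTPase and effector chains must differ")
  ga <- chain_heavy_atoms(struct, gtpase_chain)
  ea <- chain_heavy_atoms(struct, effector_chain)

  res_split <- function(a) {
    key <- paste(a$resno, a$insert, sep = "\r")
    idx <- split(seq_len(nrow(a)), factor(key, levels = unique(key)))
    coords <- as.matrix(a[, c("x", "y", "z")])
    centers <- t(vapply(idx, function(i) colMeans(coords[i, , drop = FALSE]),
                        numeric(3)))
    radii <- vapply(seq_along(idx), function(k) {
      d <- sweep(coords[idx[[k]], , drop = FALSE], 2, centers[k, ], `-`)
      sqrt(max(rowSums(d^2)))
    }, numeric(1))
    first <- vapply(idx, `[[`, integer(1), 1L)
    list(idx = idx, coords = coords, centers = centers, radii = radii,
         resno = a$resno[first], insert = a$insert[first], aa = a$aa[first])
  }
  G <- res_split(ga)
  E <- res_split(ea)

  cd2 <- outer(rowSums(G$centers^2), rowSums(E$centers^2), `+`) -
    2 * G$centers %*% t(E$centers)
  cd <- sqrt(pmax(cd2, 0))
  lim <- outer(G$radii, E$radii, `+`) + cutoff
  cand <- which(cd <= lim, arr.ind = TRUE)

  if (nrow(cand) == 0) {
    out <- data.frame(gtpase_resno = integer(), gtpase_insert = character(),
                      gtpase_aa = character(), effector_resno = integer(),
                      effector_insert = character(), effector_aa = character(),
                      min_distance = numeric())
  } else {
    md <- vapply(seq_len(nrow(cand)), function(k) {
      gi <- cand[k, 1]; ei <- cand[k, 2]
      residue_min_distance(
        as.data.frame(G$coords[G$idx[[gi]], , drop = FALSE]),
        as.data.frame(E$coords[E$idx[[ei]], , drop = FALSE]))
    }, numeric(1))
    hit <- md <= cutoff
    gi <- cand[hit, 1]; ei <- cand[hit, 2]
    out <- data.frame(
      gtpase_resno = G$resno[gi], gtpase_insert = G$insert[gi],
      gtpase_aa = G$aa[gi],
      effector_resno = E$resno[ei], effector_insert = E$insert[ei],
      effector_aa = E$aa[ei], min_distance = md[hit])
    out <- out[order(out$gtpase_resno, out$gtpase_insert,
                     out$effector_resno, out$effector_insert), ]
    rownames(out) <- NULL
  }
  class(out) <- c("residue_contacts", "data.frame")
  attr(out, "cutoff") <- cutoff
  out
}
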