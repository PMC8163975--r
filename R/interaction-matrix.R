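#' Build the reference-numbered interaction matrix
#'
#' Aggregates per-complex contact sets, projected through each complex's
#' residue-to-column maps, into a GTPase x effector grid whose cell values
#' count the number of complexes in which that residue pair is in contact
#' (each complex contributes at most 1 to a cell, however many atom pairs
#' qualify). Rows carry GTPase reference labels (HRAS-style numbering),
#' columns carry effector reference labels. Contacts involving residues that
#' did not map to an alignment column are tallied per complex and reported,
#' never silently dropped into the matrix.
#'
#' @param contacts Named list of `residue_contacts` (one per complex; names
#'   are complex ids).
#' @param gtpase_maps,effector_maps Named lists of [map_chain_to_row()]
#'   results, parallel to `contacts`.
#' @param gtpase_labels,effector_labels [reference_labels()] for the GTPase
#'   and effector alignments.
#' @return Object of class `interaction_matrix`: list with `values` (integer
#'   matrix, labeled), `support` (list of supporting complex-id vectors keyed
#'   `"<row>|<col>"`), `n_complexes`, `row_labels`, `col_labels` (the label
#'   data frames), `unmapped` (data frame `complex_id`, `n_unmapped_contacts`).
#' @export
build_matrix <- function(contacts, gtpase_maps, effector_maps,
                         gtpase_labels, effector_labels) {
  ids <- names(contacts)
  if (is.null(ids) || any(ids == ""))
    stop_config("contacts must be a named list (complex ids)")
  if (!setequal(ids, names(gtpase_maps)) ||
      !setequal(ids, names(effector_maps)))
    stop_config("contacts and maps must cover the same complex ids")

  rl <- gtpase_labels$label
  cl <- effector_labels$label
  values <- matrix(0L, length(rl), length(cl), dimnames = list(rl, cl))
  support <- list()
  unmapped <- data.frame(complex_id = ids, n_unmapped_contacts = 0L)

  # complexes are ingested in sorted-id order so the result is independent of
  # list order
  for (id in sort(ids)) {
    cc <- contacts[[id]]
    if (nrow(cc) == 0) next
    gmap <- gtpase_maps[[id]]$entries
    emap <- effector_maps[[id]]$entries
    gcol <- gmap$column[match(paste(cc$gtpase_resno, cc$gtpase_insert),
                              paste(gmap$resno, gmap$insert))]
    ecol <- emap$column[match(paste(cc$effector_resno, cc$effector_insert),
                              paste(emap$resno, emap$insert))]
    ok <- !is.na(gcol) & !is.na(ecol)
    unmapped$n_unmapped_contacts[unmapped$complex_id == id] <- sum(!ok)
    if (!any(ok)) next
    pairs <- unique(data.frame(g = gcol[ok], e = ecol[ok]))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$g[k]; j <- pairs$e[k]
      values[i, j] <- values[i, j] + 1L
      key <- paste(rl[i], cl[j], sep = "|")
      support[[key]] <- c(support[[key]], id)
    }
  }
  structure(list(values = values, support = support,
                 n_complexes = length(ids),
                 row_labels = gtpase_labels, col_labels = effector_labels,
                 unmapped = unmapped),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("interaction_matrix:", nrow(x$values), "GTPase x", ncol(x$values),
      "effector residues over", x$n_complexes, "complexes;",
      sum(x$values > 0), "nonzero cells\n")
  invisible(x)
}

#' Cells with at least a minimum complex support
#'
#' @param mat An [build_matrix()] result.
#' @param min_support Minimum number of supporting complexes (1..n_complexes).
#' @return Data frame `gtpase_label`, `effector_label`, `value`, sorted by
#'   value descending, then row label, then column label.
#' @export
hotspot_cells <- function(mat, min_support) {
  stopifnot(inherits(mat, "interaction_matrix"))
  if (!is_count(min_support) || min_support < 1 ||
      min_support > mat$n_complexes)
    stop_config("min_support must be in 1..n_complexes")
  hit <- which(mat$values >= min_support, arr.ind = TRUE)
  out <- data.frame(gtpase_label = rownames(mat$values)[hit[, 1]],
                    effector_label = colnames(mat$values)[hit[, 2]],
                    value = mat$values[hit])
  out <- out[order(-out$value, out$gtpase_label, out$effector_label), ]
  rownames(out) <- NULL
  out
}

#' Default "major hotspot" support threshold
#'
#' A residue (or cell) counts as a major hotspot when supported by a majority
#' of the analyzed complexes.
#'
#' @param n_complexes Number of complexes in the matrix.
#' @return `ceiling(0.5 * n_complexes)`.
#' @export
default_min_support <- function(n_complexes) {
  as.integer(ceiling(0.5 * n_complexes))
}

#' Hotspot residues on one axis of the matrix
#'
#' A residue's support is the number of complexes in which it contacts at
#' least one partner residue (per-complex binarized: contacting three
#' partners within one complex still counts once), computed from the
#' supporting complex-id lists, not by summing cell values.
#'
#' @param mat An [build_matrix()] result.
#' @param axis `"gtpase"` (rows) or `"effector"` (columns).
#' @param min_support Minimum residue support; defaults to
#'   [default_min_support()].
#' @param conservation Optional [classify_columns()] result for the axis's
#'   alignment; conservation labels are joined by alignment column.
#' @return Data frame of class `hotspot_call`: `axis`, `label`, `support`,
#'   `conservation` (NA when not supplied), sorted by support descending then
#'   label.
#' @export
hotspot_residues <- function(mat, axis = c("gtpase", "effector"),
                             min_support = default_min_support(mat$n_complexes),
                             conservation = NULL) {
  stopifnot(inherits(mat, "interaction_matrix"))
  axis <- match.arg(axis)
  if (!is_count(min_support) || min_support < 1 ||
      min_support > mat$n_complexes)
    stop_config("min_support must be in 1..n_complexes")

  labels <- if (axis == "gtpase") mat$row_labels else mat$col_labels
  keyside <- if (axis == "gtpase") 1L else 2L
  keys <- strsplit(names(mat$support), "|", fixed = TRUE)
  side_label <- vapply(keys, `[[`, "", keyside)
  support_n <- vapply(labels$label, function(lab) {
    ids <- unique(unlist(mat$support[side_label == lab], use.names = FALSE))
    length(ids)
  }, integer(1))

  cons <- rep(NA_character_, nrow(labels))
  if (!is.null(conservation))
    cons <- conservation$label[match(labels$column, conservation$column)]
  out <- data.frame(axis = axis, label = labels$label, support = support_n,
                    conservation = cons)
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(-out$support, out$label), ]
  rownames(out) <- NULL
  class(out) <- c("hotspot_call", "data.frame")
  out
}

#' Write an interaction matrix as TSV and JSON
#'
#' The TSV has GTPase labels as row names and effector labels as columns; the
#' JSON carries the cell values together with the supporting complex-id lists
#' and the per-complex unmapped-contact counts.
#'
#' @param mat An [build_matrix()] result.
#' @param tsv_path,json_path Output paths (either may be NULL to skip).
#' @return Invisibly, the list of paths written.
#' @export
write_matrix <- function(mat, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(mat, "interaction_matrix"))
  written <- character()
  if (!is.null(tsv_path)) {
    df <- data.frame(gtpase = rownames(mat$values), mat$values,
                     check.names = FALSE)
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, tsv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_complexes = mat$n_complexes,
           rows = rownames(mat$values), cols = colnames(mat$values),
           values = mat$values, support = mat$support,
           unmapped = mat$unmapped),
      json_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, json_path)
  }
  invisible(written)
}
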