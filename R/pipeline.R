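#' Read a complex manifest
#'
#' Tab-separated table naming, per complex, the structure file and the chain
#' roles. Required columns: `complex_id`, `path`, `gtpase_chain`,
#' `effector_chain`, `effector_family` (`RA` or `RB`). Optional:
#' `model_index` (default 1), `gtpase_row` / `effector_row` (alignment row
#' names; default the alignment reference rows). Each crystallographically
#' independent copy of a complex is its own row with its own id.
#'
#' @param path Manifest file path.
#' @return Data frame with one row per complex.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_config("manifest not found: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("complex_id", "path", "gtpase_chain", "effector_chain",
            "effector_family")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop_config("manifest lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(m) == 0) stop_config("no complexes in manifest")
  if (anyDuplicated(m$complex_id))
    stop_config("duplicate complex ids in manifest")
  if (!all(m$effector_family %in% c("RA", "RB")))
    stop_config("effector_family must be RA or RB")
  if (any(m$gtpase_chain == m$effector_chain))
    stop_config("GTPase and effector chains must differ")
  if (is.null(m$model_index)) m$model_index <- 1L
  m
}

structure_format <- function(path) {
  if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
}

#' Run the interaction-matrix pipeline end to end
#'
#' For every complex in the manifest: read the structure, extract
#' intermolecular residue contacts at the cutoff, and map both chains to
#' their alignment rows; then aggregate everything into the
#' reference-numbered interaction matrix, call hotspots, classify column
#' conservation, and write all artifacts to `out_dir`. Any per-complex
#' failure aborts the run with the failing complex named, and files written
#' so far are removed. Outputs are byte-identical for identical inputs.
#'
#' @param config Named list (or path to a tab-less R-readable YAML-like
#'   `key: value` file is not supported; pass a list) with elements:
#'   `manifest` (path), `gtpase_alignment`, `effector_alignment` (FASTA
#'   paths), `gtpase_reference_row`, `effector_reference_row` (default:
#'   first rows), `gtpase_start`, `effector_start` (reference numbering
#'   starts, default 1), `cutoff` (default 4.0), `min_support` (default
#'   majority of complexes), `conservation_threshold` (default 0.9),
#'   `family` (optional `"RA"`/`"RB"` filter), `out_dir`.
#' @return Invisibly, a list with the `interaction_matrix`, hotspot tables,
#'   conservation tables and the paths written.
#' @export
run_matrix_pipeline <- function(config) {
  cfg <- config
  for (key in c("manifest", "gtpase_alignment", "effector_alignment",
                "out_dir"))
    if (is.null(cfg[[key]])) stop_config("config lacks ", key)
  cutoff <- cfg$cutoff %||% 4.0
  if (!is_scalar_number(cutoff) || cutoff <= 0)
    stop_config("cutoff must be positive")
  thr <- cfg$conservation_threshold %||% 0.9

  manifest <- read_manifest(cfg$manifest)
  if (!is.null(cfg$family)) {
    manifest <- manifest[manifest$effector_family == cfg$family, ,
                         drop = FALSE]
    if (nrow(manifest) == 0) stop_config("no complexes in family ", cfg$family)
  }
  if (!all(file.exists(manifest$path)))
    stop_config("missing structure files: ",
                paste(manifest$path[!file.exists(manifest$path)],
                      collapse = ", "))

  g_aln <- read_alignment(cfg$gtpase_alignment, "fasta",
                          reference_row = cfg$gtpase_reference_row)
  e_aln <- read_alignment(cfg$effector_alignment, "fasta",
                          reference_row = cfg$effector_reference_row)
  g_labels <- reference_labels(g_aln, cfg$gtpase_start %||% 1L)
  e_labels <- reference_labels(e_aln, cfg$effector_start %||% 1L)
  g_cons <- classify_columns(g_aln, threshold = thr)
  e_cons <- classify_columns(e_aln, threshold = thr)

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  on_fail_cleanup <- function() unlink(written)

  contacts <- list(); g_maps <- list(); e_maps <- list()
  log_lines <- character()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      struct <- read_structure(row$path, structure_format(row$path),
                               model_index = row$model_index)
      cc <- extract_contacts(struct, row$gtpase_chain, row$effector_chain,
                             cutoff = cutoff)
      pick <- function(v, default)
        if (is.null(v) || is.na(v) || v == "") default else v
      gm <- map_chain_to_row(chain_residues(struct, row$gtpase_chain), g_aln,
                             pick(row$gtpase_row, g_aln$reference_row))
      em <- map_chain_to_row(chain_residues(struct, row$effector_chain),
                             e_aln,
                             pick(row$effector_row, e_aln$reference_row))
      list(cc = cc, gm = gm, em = em)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      on_fail_cleanup()
      stop_data("complex ", row$complex_id, " failed: ",
                conditionMessage(res))
    }
    contacts[[row$complex_id]] <- res$cc
    g_maps[[row$complex_id]] <- res$gm
    e_maps[[row$complex_id]] <- res$em
    p <- file.path(cfg$out_dir, paste0("contacts_", row$complex_id, ".tsv"))
    utils::write.table(as.data.frame(res$cc), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, p)
    log_lines <- c(log_lines, sprintf(
      "%s: %d contacts, %d unmapped GTPase residues, %d unmapped effector residues",
      row$complex_id, nrow(res$cc), nrow(res$gm$unmapped),
      nrow(res$em$unmapped)))
  }

  mat <- build_matrix(contacts, g_maps, e_maps, g_labels, e_labels)
  min_support <- cfg$min_support %||% default_min_support(mat$n_complexes)
  cells <- hotspot_cells(mat, min_support)
  g_hot <- hotspot_residues(mat, "gtpase", min_support, g_cons)
  e_hot <- hotspot_residues(mat, "effector", min_support, e_cons)

  paths <- list(matrix_tsv = file.path(cfg$out_dir, "matrix.tsv"),
                matrix_json = file.path(cfg$out_dir, "matrix.json"),
                hotspot_cells = file.path(cfg$out_dir, "hotspot_cells.tsv"),
                hotspot_residues = file.path(cfg$out_dir,
                                             "hotspot_residues.tsv"),
                conservation = file.path(cfg$out_dir, "conservation.tsv"),
                log = file.path(cfg$out_dir, "run.log"))
  write_matrix(mat, paths$matrix_tsv, paths$matrix_json)
  utils::write.table(cells, paths$hotspot_cells, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(rbind(as.data.frame(g_hot), as.data.frame(e_hot)),
                     paths$hotspot_residues, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cons <- rbind(cbind(axis = "gtpase", as.data.frame(g_cons)),
                cbind(axis = "effector", as.data.frame(e_cons)))
  utils::write.table(cons, paths$conservation, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(log_lines, paths$log)

  invisible(list(matrix = mat, hotspot_cells = cells,
                 gtpase_hotspots = g_hot, effector_hotspots = e_hot,
                 conservation = cons, min_support = min_support,
                 paths = c(written, unlist(paths))))
}

#' Run the affinity-fitting pipeline over a set of titration files
#'
#' Fits each CSV with the quadratic ligand-depletion model and writes a fit
#' report plus an affinity-band summary. Unreadable or unfittable files are
#' recorded as errors and the run continues; the returned `status` is 0 only
#' when every file fitted.
#'
#' @param files Character vector of titration CSV paths (at least one).
#' @param receptor_total Labeled receptor concentration shared by the panel,
#'   uM.
#' @param out_dir Output directory (NULL to skip writing).
#' @param comparisons Optional data frame (`label_a`, `label_b`) of
#'   wild-type/variant fit pairs (by file label) to compare with
#'   [compare_fits()].
#' @return List: `fits` (data frame: `label`, `kd`, `kd_se`, `p_free`,
#'   `p_bound`, `rss`, `band`, `converged`), `band_summary` (counts per
#'   band), `comparisons` (data frame or NULL), `errors` (named character),
#'   `status` (0 ok, 3 when any file failed).
#' @export
run_affinity_pipeline <- function(files, receptor_total = 1, out_dir = NULL,
                                  comparisons = NULL) {
  if (length(files) < 1) stop_config("need at least one titration file")
  fits <- list(); errors <- character()
  for (f in files) {
    res <- tryCatch(fit_titration(read_titration(f, receptor_total)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors[basename(f)] <- conditionMessage(res)
    } else {
      fits[[res$label]] <- res
    }
  }
  fit_df <- do.call(rbind, lapply(fits, function(f)
    data.frame(label = f$label, kd = f$kd, kd_se = f$se[["kd"]],
               p_free = f$p_free, p_bound = f$p_bound, rss = f$rss,
               band = as.character(f$band), converged = f$converged)))
  if (!is.null(fit_df)) rownames(fit_df) <- NULL
  band_levels <- levels(classify_affinity(1))
  band_summary <- as.data.frame(table(
    band = factor(if (is.null(fit_df)) character() else fit_df$band,
                  levels = band_levels)))
  names(band_summary) <- c("band", "n")

  comp_df <- NULL
  if (!is.null(comparisons) && length(fits)) {
    comp_df <- do.call(rbind, lapply(seq_len(nrow(comparisons)), function(i) {
      a <- fits[[comparisons$label_a[i]]]
      b <- fits[[comparisons$label_b[i]]]
      if (is.null(a) || is.null(b)) return(NULL)
      cmp <- compare_fits(a, b)
      data.frame(label_a = comparisons$label_a[i],
                 label_b = comparisons$label_b[i],
                 fold_change = cmp$fold_change, z = cmp$z,
                 p_value = cmp$p_value)
    }))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(fit_df))
      utils::write.table(fit_df, file.path(out_dir, "fits.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    utils::write.table(band_summary, file.path(out_dir, "band_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(comp_df))
      utils::write.table(comp_df, file.path(out_dir, "comparisons.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(fits = fit_df, band_summary = band_summary, comparisons = comp_df,
       errors = errors, status = if (length(errors)) 3L else 0L)
}
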