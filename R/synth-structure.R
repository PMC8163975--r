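#' Specification for a toy two-chain complex with planted contacts
#'
#' Describes a synthetic GTPase/effector complex in which a chosen set of
#' intermolecular residue pairs is guaranteed to be in contact (minimum
#' heavy-atom distance at or below the cutoff) and every other intermolecular
#' pair is guaranteed to be far (more than cutoff + 2 Angstrom). The geometry
#' is deliberately unphysical: residues are rigid five-atom fragments
#' (N, CA, C, O, CB, all within 1 Angstrom of the residue center) placed on a
#' line lattice with 10 Angstrom spacing, and each planted contact is realised
#' by translating one effector fragment next to its GTPase partner. This is
#' all the heavy-atom contact definition needs; no fold, rotamers or ligands
#' are modelled.
#'
#' Geometric feasibility requires that each effector residue takes part in at
#' most one planted contact and each GTPase residue in at most four (the four
#' placement directions around a lattice site); requests violating this fail.
#'
#' @param n_gtpase,n_effector Residues per chain (chain A = GTPase, B = effector).
#' @param contacts Data frame with columns `gtpase`, `effector` (1-based residue
#'   indices) and `distance` (target CA-CA distance, Angstrom, must be positive
#'   and below `cutoff`). Zero-row data frame plants no contacts.
#' @param cutoff Contact cutoff in force, Angstrom (must be below 6 so the
#'   far-pair guarantee `> cutoff + 2` holds on the 10 Angstrom lattice).
#' @param seed Integer seed controlling residue identities and fragment
#'   orientations; output is byte-identical for a fixed seed.
#' @return An object of class `planted_complex_spec`.
#' @seealso [synth_complex()]
#' @export
planted_complex_spec <- function(n_gtpase, n_effector,
                                 contacts = empty_contact_plan(),
                                 cutoff = 4.0, seed = 1L) {
  if (!is_count(n_gtpase) || !is_count(n_effector) ||
      n_gtpase < 1 || n_effector < 1)
    stop_config("chain lengths must be positive integers")
  if (!is_scalar_number(cutoff) || cutoff <= 0 || cutoff >= 6)
    stop_config("cutoff must be in (0, 6) Angstrom for the toy lattice geometry")
  contacts <- as.data.frame(contacts)
  if (nrow(contacts) > 0) {
    stopifnot(all(c("gtpase", "effector", "distance") %in% names(contacts)))
    if (any(contacts$gtpase < 1 | contacts$gtpase > n_gtpase) ||
        any(contacts$effector < 1 | contacts$effector > n_effector))
      stop_config("planted contact indices outside chain lengths")
    if (any(contacts$distance <= 0) || any(contacts$distance >= cutoff))
      stop_config("planted distances must be in (0, cutoff)")
    if (anyDuplicated(contacts[c("gtpase", "effector")]))
      stop_config("duplicate planted pairs")
    if (anyDuplicated(contacts$effector))
      stop_config("infeasible geometry: an effector residue can carry at most ",
                  "one planted contact")
    if (any(table(contacts$gtpase) > 4))
      stop_config("infeasible geometry: at most 4 planted contacts per ",
                  "GTPase residue")
  }
  structure(list(n_gtpase = as.integer(n_gtpase),
                 n_effector = as.integer(n_effector),
                 contacts = contacts, cutoff = cutoff,
                 seed = as.integer(seed)),
            class = "planted_complex_spec")
}

#' @rdname planted_complex_spec
#' @export
empty_contact_plan <- function() {
  data.frame(gtpase = integer(), effector = integer(), distance = numeric())
}

# Five-atom rigid fragment template, all atoms within 1 Angstrom of the
# center; CA sits exactly at the center so a planted pair's CA-CA distance
# equals the target distance.
fragment_template <- function() {
  m <- rbind(N  = c(-0.90,  0.30, 0.00),
             CA = c( 0.00,  0.00, 0.00),
             C  = c( 0.90,  0.30, 0.00),
             O  = c( 0.60, -0.60, 0.30),
             CB = c( 0.00, -0.50, 0.80))
  colnames(m) <- c("x", "y", "z")
  m
}

# Uniform random 3x3 rotation matrix (quaternion method).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Build a toy two-chain complex with planted contacts
#'
#' Realises a [planted_complex_spec()] as an atom table: exactly the planted
#' residue pairs have minimum heavy-atom distance at or below the cutoff, and
#' every other intermolecular pair is farther than cutoff + 2 Angstrom.
#'
#' @param spec A `planted_complex_spec`.
#' @return An object of class `planted_complex` with elements `atoms` (data
#'   frame: `chain`, `resno`, `resid`, `elety`, `x`, `y`, `z`), `spec`,
#'   `gtpase_seq` and `effector_seq` (one-letter chain sequences).
#' @examples
#' spec <- planted_complex_spec(10, 8,
#'   contacts = data.frame(gtpase = 3, effector = 7, distance = 3.5))
#' cx <- synth_complex(spec)
#' table(cx$atoms$chain)
#' @export
synth_complex <- function(spec) {
  stopifnot(inherits(spec, "planted_complex_spec"))
  with_seed(spec$seed, {
    gt_aa <- sample(AA1, spec$n_gtpase, replace = TRUE)
    ef_aa <- sample(AA1, spec$n_effector, replace = TRUE)

    # chain A centers on a 10 A line; chain B default centers on a parallel
    # line 1000 A away (never in contact)
    a_centers <- cbind(x = 10 * (seq_len(spec$n_gtpase) - 1), y = 0, z = 0)
    b_centers <- cbind(x = 10 * (seq_len(spec$n_effector) - 1), y = 1000, z = 0)

    # planted effector fragments move next to their GTPase partner; up to four
    # share one site via the +/-y, +/-z directions
    dirs <- rbind(c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    if (nrow(spec$contacts) > 0) {
      slot_used <- integer(spec$n_gtpase)
      for (k in seq_len(nrow(spec$contacts))) {
        g <- spec$contacts$gtpase[k]
        e <- spec$contacts$effector[k]
        d <- spec$contacts$distance[k]
        slot_used[g] <- slot_used[g] + 1L
        b_centers[e, ] <- a_centers[g, ] + d * dirs[slot_used[g], ]
      }
    }

    tmpl <- fragment_template()
    place <- function(center) {
      rot <- random_rotation()
      sweep(tmpl %*% t(rot), 2, center, `+`)
    }
    build_chain <- function(chain, centers, aa) {
      do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
        xyz <- place(centers[i, ])
        data.frame(chain = chain, resno = i, resid = aa_one_to_three(aa[i]),
                   elety = rownames(tmpl),
                   x = round(xyz[, 1], 3), y = round(xyz[, 2], 3),
                   z = round(xyz[, 3], 3), row.names = NULL)
      }))
    }
    atoms <- rbind(build_chain("A", a_centers, gt_aa),
                   build_chain("B", b_centers, ef_aa))
    structure(list(atoms = atoms, spec = spec,
                   gtpase_seq = paste(gt_aa, collapse = ""),
                   effector_seq = paste(ef_aa, collapse = "")),
              class = "planted_complex")
  })
}

#' Write a toy complex as PDB or mmCIF
#'
#' @param x A `planted_complex`.
#' @param path Output file path.
#' @param format `"pdb"` (ATOM records, two chain IDs, sequential numbering)
#'   or `"cif"` (minimal `atom_site` loop).
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, format = c("pdb", "cif")) {
  stopifnot(inherits(x, "planted_complex"))
  format <- match.arg(format)
  a <- x$atoms
  elem <- substr(a$elety, 1, 1)
  if (format == "pdb") {
    lines <- sprintf(
      "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)), sprintf(" %-3s", a$elety), a$resid, a$chain, a$resno,
      a$x, a$y, a$z, 1.00, 0.00, elem)
    lines <- c(lines, "END")
  } else {
    hdr <- c("data_synthetic", "#", "loop_",
             paste0("_atom_site.", c(
               "group_PDB", "id", "type_symbol", "label_atom_id",
               "label_alt_id", "label_comp_id", "label_asym_id",
               "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
               "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
               "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
               "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")))
    rows <- sprintf(
      "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s %s %s 1",
      seq_len(nrow(a)), elem, a$elety, a$resid, a$chain, a$resno,
      a$x, a$y, a$z, a$resno, a$resid, a$chain, a$elety)
    lines <- c(hdr, rows, "#")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate an ensemble of toy complexes with shared core contacts
#'
#' Emulates a panel of crystal structures of homologous complexes: all
#' complexes share the same chain lengths and sequences, every `core_contacts`
#' pair is planted in all of them, and each member of a fixed candidate set of
#' peripheral pairs (one randomly assigned GTPase partner per effector residue
#' not used by the core) is planted independently with probability
#' `peripheral_rate` in each complex. The generator records its own per-pair
#' planting counts, which downstream matrix construction must reproduce.
#'
#' @param core_contacts Data frame with columns `gtpase`, `effector` (indices).
#' @param peripheral_rate Probability in \[0, 1\] of planting each candidate
#'   peripheral pair in each complex.
#' @param n_complexes Number of complexes to generate.
#' @param seed Integer seed.
#' @param n_gtpase,n_effector Chain lengths shared by all complexes.
#' @param out_dir If non-NULL, PDB files and a tab-separated manifest are
#'   written there.
#' @return An object of class `synth_ensemble`: `complexes` (named list of
#'   `planted_complex`), `manifest` (data frame: `complex_id`, `path`,
#'   `gtpase_chain`, `effector_chain`, `effector_family`, `model_index`),
#'   `truth` (integer matrix of per-pair planting counts, GTPase residues x
#'   effector residues), `gtpase_seq`, `effector_seq`, `n_complexes`.
#' @export
synth_ensemble <- function(core_contacts, peripheral_rate, n_complexes,
                           seed = 1L, n_gtpase = 20L, n_effector = 15L,
                           out_dir = NULL) {
  if (!is_scalar_number(peripheral_rate) ||
      peripheral_rate < 0 || peripheral_rate > 1)
    stop_config("peripheral_rate must be in [0, 1]")
  if (!is_count(n_complexes) || n_complexes < 1)
    stop_config("n_complexes must be a positive integer")
  core <- as.data.frame(core_contacts)
  if (nrow(core) > 0 && anyDuplicated(core$effector))
    stop_config("infeasible core: one planted contact per effector residue")
  if (nrow(core) > 0 && any(table(core$gtpase) > 4))
    stop_config("infeasible core: at most 4 contacts per GTPase residue")

  with_seed(seed, {
    free_eff <- setdiff(seq_len(n_effector), core$effector)
    candidates <- data.frame(
      gtpase = if (length(free_eff)) sample(seq_len(n_gtpase),
                                            length(free_eff),
                                            replace = TRUE) else integer(),
      effector = free_eff)
    truth <- matrix(0L, n_gtpase, n_effector)
    complexes <- vector("list", n_complexes)
    for (i in seq_len(n_complexes)) {
      extra <- candidates[stats::runif(nrow(candidates)) < peripheral_rate, ,
                          drop = FALSE]
      planted <- rbind(core[, c("gtpase", "effector"), drop = FALSE], extra)
      planted$distance <- if (nrow(planted))
        stats::runif(nrow(planted), 2.5, 3.8) else numeric()
      # cap at 4 planted pairs per GTPase site (lattice slot limit)
      if (nrow(planted)) {
        keep <- unlist(lapply(split(seq_len(nrow(planted)), planted$gtpase),
                              utils::head, 4L), use.names = FALSE)
        planted <- planted[sort(keep), , drop = FALSE]
      }
      # same residue identities in every complex: reuse the ensemble seed for
      # sequence sampling, distinct placement seeds would reshuffle sequences,
      # so synth_complex reuses seed `seed` for all complexes and only the
      # planted set varies
      cx <- synth_complex(planted_complex_spec(
        n_gtpase, n_effector, contacts = planted, seed = seed))
      complexes[[i]] <- cx
      if (nrow(planted))
        truth[cbind(planted$gtpase, planted$effector)] <-
          truth[cbind(planted$gtpase, planted$effector)] + 1L
    }
    ids <- sprintf("cx%03d", seq_len(n_complexes))
    names(complexes) <- ids
    manifest <- data.frame(complex_id = ids, path = NA_character_,
                           gtpase_chain = "A", effector_chain = "B",
                           effector_family = "RA", model_index = 1L)
    ens <- structure(list(complexes = complexes, manifest = manifest,
                          truth = truth,
                          gtpase_seq = complexes[[1]]$gtpase_seq,
                          effector_seq = complexes[[1]]$effector_seq,
                          n_complexes = n_complexes),
                     class = "synth_ensemble")
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      ens$manifest$path <- file.path(out_dir, paste0(ids, ".pdb"))
      for (i in seq_len(n_complexes))
        write_structure(complexes[[i]], ens$manifest$path[i], "pdb")
      utils::write.table(ens$manifest,
                         file.path(out_dir, "manifest.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    ens
  })
}
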