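# Independent oracles and random-case generators shared across tests.
# These deliberately use plain nested loops / exhaustive scans so they stay
# independent of the package's vectorized, prefiltered implementations.

# Brute-force all-residue-pair contact scan over two chains of a
# complex_structure: double loop over residue pairs, exhaustive all-atom-pair
# minimum per pair.
brute_force_contacts <- function(struct, gtpase_chain, effector_chain,
                                 cutoff = 4.0) {
  a <- struct$atoms
  a <- a[!a$het & !a$hydrogen, , drop = FALSE]
  split_res <- function(chain) {
    ca <- a[a$chain == chain, , drop = FALSE]
    key <- paste(ca$resno, ca$insert, sep = "\r")
    lapply(split(seq_len(nrow(ca)), factor(key, levels = unique(key))),
           function(i) list(resno = ca$resno[i[1]], insert = ca$insert[i[1]],
                            xyz = as.matrix(ca[i, c("x", "y", "z")])))
  }
  G <- split_res(gtpase_chain)
  E <- split_res(effector_chain)
  hits <- list()
  for (g in G) {
    for (e in E) {
      best <- Inf
      for (i in seq_len(nrow(g$xyz))) {
        d2 <- (e$xyz[, 1] - g$xyz[i, 1])^2 + (e$xyz[, 2] - g$xyz[i, 2])^2 +
          (e$xyz[, 3] - g$xyz[i, 3])^2
        best <- min(best, min(d2))
      }
      if (sqrt(best) <= cutoff) {
        hits[[length(hits) + 1]] <- data.frame(
          gtpase_resno = g$resno, gtpase_insert = g$insert,
          effector_resno = e$resno, effector_insert = e$insert,
          min_distance = sqrt(best))
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(gtpase_resno = integer(), gtpase_insert = character(),
                      effector_resno = integer(),
                      effector_insert = character(),
                      min_distance = numeric()))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$gtpase_resno, out$gtpase_insert,
                   out$effector_resno, out$effector_insert), ]
  rownames(out) <- NULL
  out
}

# Random feasible planted-complex spec: chain sizes in [n_min, n_max], up to
# max_pairs planted contacts respecting the one-per-effector-residue and
# four-per-GTPase-residue feasibility rules.
random_complex_spec <- function(seed, n_min = 5, n_max = 30, max_pairs = 6) {
  withr::with_seed(seed, {
    ng <- sample(n_min:n_max, 1)
    ne <- sample(n_min:n_max, 1)
    k <- sample(0:min(max_pairs, ne), 1)
    eff <- sample(ne, k)
    gt <- integer(0)
    counts <- integer(ng)
    for (i in seq_len(k)) {
      open <- which(counts < 4)
      g <- if (length(open) == 1) open else sample(open, 1)
      counts[g] <- counts[g] + 1L
      gt <- c(gt, g)
    }
    contacts <- if (k > 0) {
      data.frame(gtpase = gt, effector = eff,
                 distance = runif(k, 2.2, 3.9))
    } else {
      empty_contact_plan()
    }
    planted_complex_spec(ng, ne, contacts = contacts, seed = seed)
  })
}

# Write a planted complex to a temp PDB and read it back.
reread_complex <- function(cx) {
  path <- tempfile(fileext = ".pdb")
  write_structure(cx, path, "pdb")
  read_structure(path, "pdb")
}

# Independent recount of an interaction matrix from raw per-complex contact
# lists: binarize each complex's projected pairs, then sum.
recount_matrix <- function(contacts, gtpase_maps, effector_maps,
                           n_rows, n_cols) {
  m <- matrix(0L, n_rows, n_cols)
  for (id in names(contacts)) {
    cc <- contacts[[id]]
    if (nrow(cc) == 0) next
    gm <- gtpase_maps[[id]]$entries
    em <- effector_maps[[id]]$entries
    seen <- character()
    for (r in seq_len(nrow(cc))) {
      gi <- gm$column[gm$resno == cc$gtpase_resno[r] &
                        gm$insert == cc$gtpase_insert[r]]
      ei <- em$column[em$resno == cc$effector_resno[r] &
                        em$insert == cc$effector_insert[r]]
      if (length(gi) != 1 || length(ei) != 1) next
      key <- paste(gi, ei)
      if (key %in% seen) next
      seen <- c(seen, key)
      m[gi, ei] <- m[gi, ei] + 1L
    }
  }
  m
}

# Ensemble fixture used by several matrix tests.
make_test_ensemble <- function(seed = 7, rate = 0.3, n = 10,
                               n_gtpase = 12, n_effector = 10,
                               core = data.frame(gtpase = c(3, 4),
                                                 effector = c(7, 8))) {
  td <- withr::local_tempdir(.local_envir = parent.frame())
  ens <- synth_ensemble(core, rate, n, seed = seed, n_gtpase = n_gtpase,
                        n_effector = n_effector, out_dir = td)
  alns <- synth_ensemble_alignments(ens, seed = seed + 1)
  structs <- lapply(ens$manifest$path, read_structure)
  names(structs) <- ens$manifest$complex_id
  contacts <- lapply(structs, extract_contacts, gtpase_chain = "A",
                     effector_chain = "B")
  gmaps <- lapply(structs, function(s)
    map_chain_to_row(chain_residues(s, "A"), alns$gtpase, "gtpase_ref"))
  emaps <- lapply(structs, function(s)
    map_chain_to_row(chain_residues(s, "B"), alns$effector, "effector_ref"))
  list(ens = ens, alns = alns, contacts = contacts,
       gmaps = gmaps, emaps = emaps,
       g_labels = reference_labels(alns$gtpase),
       e_labels = reference_labels(alns$effector))
}
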