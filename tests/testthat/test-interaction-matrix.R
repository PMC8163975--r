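test_that("single complex, single contact fills a single cell", {
  fx <- make_test_ensemble(seed = 3, rate = 0, n = 1, n_gtpase = 8,
                           n_effector = 6,
                           core = data.frame(gtpase = 3, effector = 5))
  mat <- build_matrix(fx$contacts, fx$gmaps, fx$emaps, fx$g_labels,
                      fx$e_labels)
  expect_equal(sum(mat$values), 1)
  expect_equal(unname(mat$values[3, 5]), 1)
  expect_equal(mat$n_complexes, 1)
})

test_that("core contacts present in all complexes reach full support", {
  fx <- make_test_ensemble(seed = 5, rate = 0, n = 5, n_gtpase = 8,
                           n_effector = 6,
                           core = data.frame(gtpase = 3, effector = 5))
  mat <- build_matrix(fx$contacts, fx$gmaps, fx$emaps, fx$g_labels,
                      fx$e_labels)
  expect_equal(sum(mat$values > 0), 1)
  expect_equal(unname(mat$values[3, 5]), 5)
  key <- paste(fx$g_labels$label[3], fx$e_labels$label[5], sep = "|")
  expect_length(mat$support[[key]], 5)
})

test_that("random ensembles match the independent recount oracle", {
  fx <- make_test_ensemble(seed = 29, rate = 0.35, n = 10)
  mat <- build_matrix(fx$contacts, fx$gmaps, fx$emaps, fx$g_labels,
                      fx$e_labels)
  oracle <- recount_matrix(fx$contacts, fx$gmaps, fx$emaps,
                           nrow(mat$values), ncol(mat$values))
  expect_identical(unname(mat$values), oracle)
  expect_identical(unname(mat$values), fx$ens$truth)
  # every cell's support list length equals its value
  for (key in names(mat$support)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    expect_length(mat$support[[key]], mat$values[parts[1], parts[2]])
  }
  # total over cells = sum over complexes of distinct projected pairs
  expect_equal(sum(mat$values),
               sum(vapply(fx$contacts, function(cc)
                 nrow(unique(cc[c("gtpase_resno", "effector_resno")])),
                 integer(1))))
})

test_that("matrix is order-invariant and duplicate complexes increment by one", {
  fx <- make_test_ensemble(seed = 17, rate = 0.3, n = 6)
  mat <- build_matrix(fx$contacts, fx$gmaps, fx$emaps, fx$g_labels,
                      fx$e_labels)
  perm <- withr::with_seed(1, sample(names(fx$contacts)))
  mat2 <- build_matrix(fx$contacts[perm], fx$gmaps[perm], fx$emaps[perm],
                       fx$g_labels, fx$e_labels)
  expect_identical(mat$values, mat2$values)
  # duplicate one complex under a new id
  id <- names(fx$contacts)[2]
  contacts <- c(fx$contacts, list(dup = fx$contacts[[id]]))
  gmaps <- c(fx$gmaps, list(dup = fx$gmaps[[id]]))
  emaps <- c(fx$emaps, list(dup = fx$emaps[[id]]))
  mat3 <- build_matrix(contacts, gmaps, emaps, fx$g_labels, fx$e_labels)
  delta <- mat3$values - mat$values
  cc <- fx$contacts[[id]]
  expect_equal(sum(delta), nrow(unique(cc[c("gtpase_resno",
                                            "effector_resno")])))
  expect_true(all(delta %in% c(0L, 1L)))
  expect_equal(mat3$n_complexes, 7)
})

test_that("hotspot cells equal an exhaustive filter", {
  fx <- make_test_ensemble(seed = 23, rate = 0.5, n = 9)
  mat <- build_matrix(fx$contacts, fx$gmaps, fx$emaps, fx$g_labels,
                      fx$e_labels)
  for (ms in c(1, 3, 9)) {
    cells <- hotspot_cells(mat, ms)
    brute <- which(mat$values >= ms, arr.ind = TRUE)
    expect_equal(nrow(cells), nrow(brute))
    if (nrow(cells))
      expect_true(all(mat$values[cbind(cells$gtpase_label,
                                       cells$effector_label)] >= ms))
    expect_true(all(diff(cells$value) <= 0))
  }
  # min_support = 1 returns all nonzero cells
  expect_equal(nrow(hotspot_cells(mat, 1)), sum(mat$values > 0))
  expect_error(hotspot_cells(mat, 0), "min_support")
  expect_error(hotspot_cells(mat, mat$n_complexes + 1), "min_support")
})

test_that("residue support is per-complex binarized", {
  # one complex where GTPase residue 3 contacts three partners
  fx <- make_test_ensemble(seed = 41, rate = 0, n = 1, n_gtpase = 8,
                           n_effector = 6,
                           core = data.frame(gtpase = c(3, 3, 3),
                                             effector = c(1, 4, 6)))
  mat <- build_matrix(fx$contacts, fx$gmaps, fx$emaps, fx$g_labels,
                      fx$e_labels)
  hs <- hotspot_residues(mat, "gtpase", min_support = 1)
  expect_equal(hs$support[hs$label == fx$g_labels$label[3]], 1)
  # in a single complex every contacting residue has support exactly 1
  expect_true(all(hs$support == 1))
})

test_that("ensemble residue supports match generator bookkeeping", {
  fx <- make_test_ensemble(seed = 37, rate = 0.4, n = 8)
  mat <- build_matrix(fx$contacts, fx$gmaps, fx$emaps, fx$g_labels,
                      fx$e_labels)
  g_cons <- classify_columns(fx$alns$gtpase)
  hs <- hotspot_residues(mat, "gtpase", min_support = 1,
                         conservation = g_cons)
  # oracle: per complex, binarize residues with >= 1 contact, then count
  want <- integer(12)
  for (cc in fx$contacts) want[unique(cc$gtpase_resno)] <-
    want[unique(cc$gtpase_resno)] + 1L
  for (r in which(want > 0)) {
    lab <- fx$g_labels$label[r]
    expect_equal(hs$support[hs$label == lab], want[r])
  }
  # sanity bounds: support <= n_complexes and >= max cell value in the row
  expect_true(all(hs$support <= mat$n_complexes))
  for (r in which(want > 0)) {
    lab <- fx$g_labels$label[r]
    expect_gte(hs$support[hs$label == lab], max(mat$values[lab, ]))
  }
  # conservation labels joined from the alignment classification
  expect_true(all(hs$conservation %in% c("conserved", "variable")))
})

test_that("matrix writers produce a readable TSV and JSON", {
  fx <- make_test_ensemble(seed = 2, rate = 0.2, n = 4, n_gtpase = 6,
                           n_effector = 5,
                           core = data.frame(gtpase = 2, effector = 3))
  mat <- build_matrix(fx$contacts, fx$gmaps, fx$emaps, fx$g_labels,
                      fx$e_labels)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_matrix(mat, tsv, js)
  back <- utils::read.delim(tsv, check.names = FALSE)
  expect_equal(unname(as.matrix(back[-1])),
               unname(mat$values), ignore_attr = TRUE)
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(j$n_complexes, 4)
  expect_equal(unname(as.matrix(j$values)), unname(mat$values),
               ignore_attr = TRUE)
})
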