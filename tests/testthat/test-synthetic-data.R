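test_that("planted complex specs validate their invariants", {
  expect_error(planted_complex_spec(0, 5), "positive")
  expect_error(planted_complex_spec(5, 5,
    data.frame(gtpase = 9, effector = 1, distance = 3)), "outside")
  expect_error(planted_complex_spec(5, 5,
    data.frame(gtpase = 1, effector = 1, distance = 5)), "cutoff")
  expect_error(planted_complex_spec(5, 5,
    data.frame(gtpase = c(1, 1), effector = c(2, 2), distance = c(3, 3))),
    "duplicate")
  # infeasible geometry: one effector residue in two planted pairs
  expect_error(planted_complex_spec(5, 5,
    data.frame(gtpase = c(1, 2), effector = c(3, 3), distance = c(3, 3))),
    "infeasible")
  # infeasible geometry: five planted pairs on one GTPase residue
  expect_error(planted_complex_spec(8, 8,
    data.frame(gtpase = rep(1, 5), effector = 1:5, distance = rep(3, 5))),
    "infeasible")
})

test_that("synth_complex plants exactly the requested contacts", {
  # no contacts planted -> empty extraction
  cx0 <- synth_complex(planted_complex_spec(8, 6, seed = 3))
  s0 <- reread_complex(cx0)
  expect_equal(nrow(extract_contacts(s0, "A", "B")), 0)

  # one planted pair -> exactly that pair at 4.0 A
  cx1 <- synth_complex(planted_complex_spec(10, 9,
    data.frame(gtpase = 3, effector = 7, distance = 3.5), seed = 4))
  c1 <- extract_contacts(reread_complex(cx1), "A", "B")
  expect_equal(nrow(c1), 1)
  expect_equal(c1$gtpase_resno, 3)
  expect_equal(c1$effector_resno, 7)

  # five planted pairs confirmed by the brute-force all-pairs oracle
  spec5 <- planted_complex_spec(12, 10,
    data.frame(gtpase = c(1, 2, 5, 5, 9), effector = c(3, 7, 1, 8, 10),
               distance = c(2.5, 3.0, 3.5, 3.9, 2.8)), seed = 1)
  s5 <- reread_complex(synth_complex(spec5))
  bf <- brute_force_contacts(s5, "A", "B", 4.0)
  expect_equal(nrow(bf), 5)
  expect_setequal(paste(bf$gtpase_resno, bf$effector_resno),
                  paste(spec5$contacts$gtpase, spec5$contacts$effector))
})

test_that("synth_complex is byte-identical for a fixed seed", {
  spec <- planted_complex_spec(7, 7,
    data.frame(gtpase = 2, effector = 4, distance = 3.1), seed = 42)
  p1 <- tempfile(fileext = ".pdb"); p2 <- tempfile(fileext = ".pdb")
  write_structure(synth_complex(spec), p1)
  write_structure(synth_complex(spec), p2)
  expect_identical(readLines(p1), readLines(p2))
  # different seed changes coordinates
  spec2 <- planted_complex_spec(7, 7,
    data.frame(gtpase = 2, effector = 4, distance = 3.1), seed = 43)
  p3 <- tempfile(fileext = ".pdb")
  write_structure(synth_complex(spec2), p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("generator output re-parsed through the reader matches the planted set", {
  for (seed in 1:40) {
    spec <- random_complex_spec(seed)
    struct <- reread_complex(synth_complex(spec))
    got <- extract_contacts(struct, "A", "B", cutoff = spec$cutoff)
    expect_setequal(paste(got$gtpase_resno, got$effector_resno),
                    paste(spec$contacts$gtpase, spec$contacts$effector))
  }
})

test_that("synth_ensemble honors core contacts and its own bookkeeping", {
  # core in all complexes, nothing else
  ens <- synth_ensemble(data.frame(gtpase = 3, effector = 7), 0, 5,
                        seed = 1, n_gtpase = 10, n_effector = 8)
  expect_equal(sum(ens$truth > 0), 1)
  expect_equal(ens$truth[3, 7], 5)
  # empty core, zero rate -> all-zero truth
  ens0 <- synth_ensemble(empty_contact_plan()[c("gtpase", "effector")], 0, 3,
                         seed = 2, n_gtpase = 6, n_effector = 6)
  expect_true(all(ens0$truth == 0))
  # peripheral planting counts recorded by the generator match the structures
  fx <- make_test_ensemble(seed = 7, rate = 0.3, n = 10)
  counted <- matrix(0L, 12, 10)
  for (cc in fx$contacts) {
    if (nrow(cc) == 0) next
    counted[cbind(cc$gtpase_resno, cc$effector_resno)] <-
      counted[cbind(cc$gtpase_resno, cc$effector_resno)] + 1L
  }
  expect_identical(counted, fx$ens$truth)
})

test_that("synth_alignment plants conservation ground truth", {
  # all columns conserved
  a1 <- synth_alignment(5, 8, conserved_cols = 1:8, seed = 1)
  expect_true(all(classify_columns(a1)$label == "conserved"))
  # no conserved columns
  a2 <- synth_alignment(4, 10, conserved_cols = integer(), seed = 2)
  expect_true(all(classify_columns(a2)$label == "variable"))
  # planted set recovered exactly
  a3 <- synth_alignment(6, 20, conserved_cols = c(2, 5, 9), seed = 3)
  cl <- classify_columns(a3)
  expect_identical(cl$column[cl$label == "conserved"], c(2L, 5L, 9L))
  expect_error(synth_alignment(1, 5), "at least 2")
})

test_that("simulate_titration follows the closed-form model exactly at zero noise", {
  spec <- titration_spec(10, concentrations = c(1e-6, 0.01, 1, 10, 100, 300),
                         noise_sd = 0)
  d <- simulate_titration(spec)
  model <- spec$p_free + (spec$p_bound - spec$p_free) *
    fraction_bound(1, spec$concentrations, 10)
  expect_lt(max(abs(d$polarization - model)), 1e-9)
  # conc -> 0 gives p_free; kd -> 0 with conc >> receptor gives p_bound
  tiny <- simulate_titration(titration_spec(10,
    concentrations = c(1e-12, 1, 2, 3, 4, 5), noise_sd = 0))
  expect_equal(tiny$polarization[1], 100, tolerance = 1e-9)
  sat <- simulate_titration(titration_spec(1e-9,
    concentrations = c(0.01, 1, 10, 50, 100, 300), noise_sd = 0))
  expect_equal(sat$polarization[6], 250, tolerance = 1e-6)
})

test_that("titration simulation is reproducible per seed and round-trips Kd", {
  s <- titration_spec(27, seed = 9)
  expect_identical(simulate_titration(s), simulate_titration(s))
  # noiseless round-trip through the fitting module: >= 6 significant digits
  d <- simulate_titration(titration_spec(10, noise_sd = 0))
  f <- fit_titration(d)
  expect_equal(f$kd, 10, tolerance = 1e-7)
})

test_that("titration specs validate", {
  expect_error(titration_spec(-1), "positive")
  expect_error(titration_spec(1, concentrations = c(2, 1, 3)), "increasing")
  expect_error(titration_spec(1, p_free = 5, p_bound = 5), "differ")
})
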