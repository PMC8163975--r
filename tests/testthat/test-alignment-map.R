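make_fasta <- function(names, seqs) {
  p <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", names), seqs)), p)
  p
}

test_that("FASTA and Clustal renderings load as the same alignment", {
  aln <- synth_alignment(4, 30, conserved_cols = c(3, 10), seed = 6)
  pf <- tempfile(fileext = ".fasta"); pc <- tempfile(fileext = ".aln")
  write_alignment(aln, pf, "fasta")
  write_alignment(aln, pc, "clustal")
  a1 <- read_alignment(pf, "fasta")
  a2 <- read_alignment(pc, "clustal")
  expect_identical(a1$seqs, a2$seqs)
  expect_identical(a1$names, a2$names)
  expect_equal(a1$width, 30)
})

test_that("malformed alignments fail with informative errors", {
  expect_error(read_alignment(make_fasta(c("a", "b"), c("ACD-", "ACD")),
                              "fasta"), "ragged.*b")
  expect_error(read_alignment(make_fasta(c("a", "a"), c("ACD", "ACD")),
                              "fasta"), "duplicate.*a")
  empty <- tempfile(fileext = ".fasta"); file.create(empty)
  expect_error(read_alignment(empty, "fasta"), "no sequences|parse")
  expect_error(read_alignment(tempfile(), "fasta"), "not found")
  expect_error(msa(c("a", "b"), c("ACD", "ACD"), reference_row = "z"),
               "reference")
})

test_that("identical chain and row map one-to-one", {
  aln <- msa(c("ref", "other"), c("MTEYKLVVVG", "MTEYKLVIVG"), "ref")
  residues <- data.frame(resno = 1:10, insert = "",
                         aa = strsplit("MTEYKLVVVG", "")[[1]])
  m <- map_chain_to_row(residues, aln, "ref")
  expect_equal(nrow(m$unmapped), 0)
  expect_identical(m$entries$column, 1:10)
  expect_equal(m$identity, 1)
})

test_that("disordered interior residues leave their columns unmapped", {
  # row has 12 residues; the structure lacks residues 5 and 6 (loop)
  row_seq <- "MTEYKLVVVGAG"
  chain_aa <- strsplit(row_seq, "")[[1]][-c(5, 6)]
  residues <- data.frame(resno = c(1:4, 7:12), insert = "", aa = chain_aa)
  aln <- msa(c("ref", "dec"), c(row_seq, "MTEYRLVVVGAG"), "ref")
  m <- map_chain_to_row(residues, aln, "ref")
  expect_equal(nrow(m$unmapped), 0)
  expect_identical(m$entries$column, c(1:4, 7:12))
  # hand-checked: residue numbered 7 in the structure is row residue 7
  expect_equal(m$entries$column[m$entries$resno == 7], 7)
})

test_that("author numbering offsets never affect the mapping", {
  aln <- msa(c("ref", "dec"), c("MTEYKLVVVG", "MTEYRLVVIG"), "ref")
  aa <- strsplit("MTEYKLVVVG", "")[[1]]
  base <- map_chain_to_row(data.frame(resno = 1:10, insert = "", aa = aa),
                           aln, "ref")
  offset <- map_chain_to_row(data.frame(resno = 6:15, insert = "", aa = aa),
                             aln, "ref")
  expect_identical(base$entries$column, offset$entries$column)
})

test_that("the identity guard rejects wrong-row assignment", {
  aln <- msa(c("ref", "other"), c("MTEYKLVVVG", "WWWWWWHHHH"), "ref")
  residues <- data.frame(resno = 1:10, insert = "",
                         aa = strsplit("WWWWWWHHHH", "")[[1]])
  expect_error(map_chain_to_row(residues, aln, "ref"), "identity.*ref")
})

test_that("reference labels follow the numbering rule", {
  aln <- msa(c("r", "s"), c("AC-D", "ACED"), "r")
  rl <- reference_labels(aln, 30)
  expect_identical(rl$label, c("A30", "C31", "31+1", "D32"))
  expect_identical(rl$insertion, c(FALSE, FALSE, TRUE, FALSE))
  # gap-free reference, start 1 -> labels 1..width
  aln2 <- synth_alignment(3, 12, seed = 2)
  rl2 <- reference_labels(aln2, 1)
  expect_identical(rl2$number, 1:12)
  # labels strictly increasing along non-gap reference columns
  expect_true(!is.unsorted(rl$number[!rl$insertion], strictly = TRUE))
})

test_that("reference labels can place a switch-I-like motif at 30-40", {
  # 40-column alignment whose reference starts at residue 1: columns 30-40
  # then carry numbers 30-40 (the switch I window in GTPase numbering)
  aln <- synth_alignment(4, 40, conserved_cols = 30:40, seed = 12)
  rl <- reference_labels(aln, 1)
  expect_identical(rl$number[30:40], 30:40)
  cl <- classify_columns(aln)
  expect_true(all(cl$label[30:40] == "conserved"))
})

test_that("column conservation follows the similarity groups", {
  aln <- msa(c("a", "b", "c", "d"),
             c("DDKA", "DDKG", "EDDA", "DDKA"))
  cl <- classify_columns(aln, threshold = 0.9)
  # col 1: D/D/E/D all acidic -> conserved; col 3: K,K,D,K -> 75% basic,
  # variable at 0.9; col 4: A/G/A/A all small -> conserved
  expect_identical(cl$label, c("conserved", "conserved", "variable",
                               "conserved"))
  expect_identical(cl$witness_group[1], "acidic")
  # half D half K is variable
  aln2 <- msa(c("a", "b"), c("D", "K"))
  expect_identical(classify_columns(aln2)$label, "variable")
})

test_that("conservation is row-order invariant and threshold-monotone", {
  aln <- synth_alignment(8, 25, conserved_cols = c(1, 9, 17), seed = 21)
  perm <- msa(rev(aln$names), rev(unname(aln$seqs)),
              reference_row = aln$names[1])
  expect_identical(classify_columns(aln)$label, classify_columns(perm)$label)
  sets <- lapply(c(0.5, 0.7, 0.9, 1.0), function(t) {
    cl <- classify_columns(aln, threshold = t)
    cl$column[cl$label == "conserved"]
  })
  for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("mapping composed with reference labels is injective", {
  fx <- make_test_ensemble(seed = 13, rate = 0.4, n = 3)
  for (m in fx$gmaps) {
    expect_false(anyDuplicated(m$entries$column) > 0)
    labs <- fx$g_labels$label[m$entries$column]
    expect_false(anyDuplicated(labs) > 0)
  }
})
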