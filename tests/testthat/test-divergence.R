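# build a recoded_seq whose symbols are exactly `sym` using representative
# residues (K->G, N->S, I->F, M->K, T->D)
rep_residues <- c("G", "S", "F", "K", "D")
as_rseq <- function(sym, id = "toy") {
  recode_sequence(paste(rep_residues[sym], collapse = ""), id = id)
}

test_that("a gapless local alignment slices into one row per period", {
  unit <- c(1L, 4L, 2L)
  rseq <- as_rseq(rep(unit, 4))
  probe <- build_probe(3, 12)
  aln <- local_align(pattern_matrix(unit), probe, rseq)
  rma <- repeats_from_alignment(aln, rseq)
  expect_equal(rma$k, 4L)
  expect_equal(rma$n1, 3L)
  # every complete row repeats the unit (position 1 of row 1 precedes the path)
  for (r in 2:4) expect_equal(rma$sym[r, ], unit)
  expect_equal(rma$res[3, ], rep_residues[unit])
})

test_that("insertions open extra columns and short alignments error", {
  unit <- c(1L, 4L, 2L)
  sym <- append(rep(unit, 4), 2L, after = 6L) # insertion after period 2
  rseq <- as_rseq(sym)
  aln <- local_align(pattern_matrix(unit), build_probe(3, length(sym)), rseq)
  rma <- repeats_from_alignment(aln, rseq)
  expect_equal(rma$n1, 4L) # one insertion column
  expect_equal(sum(is.na(rma$sym)), 3L + 1L) # other rows gap the insertion column
  # fewer than two complete periods
  short <- as_rseq(rep(unit, 2))
  a2 <- local_align(pattern_matrix(unit), build_probe(3, 6), short)
  expect_error(repeats_from_alignment(a2, short), "2 complete")
})

test_that("identical repeats have zero divergence in both symbol spaces", {
  unit <- c(1L, 4L, 2L, 5L)
  rseq <- as_rseq(rep(unit, 6))
  aln <- local_align(pattern_matrix(unit), build_probe(4, 24), rseq)
  rma <- repeats_from_alignment(aln, rseq)
  for (space in c("residues20", "groups5")) {
    d <- divergence_degree(rma, symbol_space = space)
    expect_equal(d$S, 0)
    expect_equal(d$v, d$v1)
  }
})

test_that("divergence arithmetic matches a manual recount on seeded alignments", {
  set.seed(77)
  for (trial in 1:15) {
    k <- sample(4:10, 1); n1 <- sample(5:9, 1)
    mat <- matrix(sample(c("A", "C", "D", "G", NA), k * n1, TRUE,
                         prob = c(0.3, 0.25, 0.2, 0.15, 0.1)), k, n1)
    rma <- structure(list(sym = NULL, res = mat, n = n1, n1 = n1, k = k),
                     class = "repeat_alignment")
    alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    oracle <- divergence_recount_oracle(mat, alphabet)
    d <- divergence_degree(rma, symbol_space = "residues20")
    expect_equal(d$S, oracle, tolerance = 1e-12)
    expect_true(d$S >= 0 && d$S <= 1)
    # row permutation invariance
    perm <- mat[sample(k), , drop = FALSE]
    rma2 <- structure(list(sym = NULL, res = perm, n = n1, n1 = n1, k = k),
                      class = "repeat_alignment")
    expect_equal(divergence_degree(rma2, symbol_space = "residues20")$S, d$S)
  }
})

test_that("the column filter keeps columns at exactly k/2 occupancy", {
  # k = 4; column 1 has 2 residues (= k/2, retained), column 2 has 1 (dropped)
  mat <- rbind(c("A", NA, "G"),
               c("A", NA, "G"),
               c(NA, "C", "G"),
               c(NA, NA, "G"))
  rma <- structure(list(sym = NULL, res = mat, n = 3, n1 = 3, k = 4),
                   class = "repeat_alignment")
  d <- divergence_degree(rma, symbol_space = "residues20")
  expect_identical(d$retained_columns, c(1L, 3L))
  expect_equal(d$v1, 6)
  expect_equal(d$v, 6) # both retained columns are unanimous
  expect_equal(d$S, 0)
  # dropping everything errors
  empty <- matrix(NA_character_, 4, 2); empty[1, 1] <- "A"
  rme <- structure(list(sym = NULL, res = empty, n = 2, n1 = 2, k = 4),
                   class = "repeat_alignment")
  expect_error(divergence_degree(rme, symbol_space = "residues20"), "filtered")
})

test_that("S reflects planted consensus mismatches", {
  # 10 copies x 7 columns, 40% of cells flipped away from the consensus 'A'
  set.seed(8)
  mat <- matrix("A", 10, 7)
  flips <- sample(70, 28)
  mat[flips] <- "W"
  # consensus per column is the modal letter; recount independently
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  oracle <- divergence_recount_oracle(mat, alphabet)
  rma <- structure(list(sym = NULL, res = mat, n = 7, n1 = 7, k = 10),
                   class = "repeat_alignment")
  expect_equal(divergence_degree(rma, symbol_space = "residues20")$S, oracle)
})

test_that("alignment rendering uses the dot convention", {
  unit <- c(1L, 4L, 2L)
  rseq <- as_rseq(rep(unit, 4))
  aln <- local_align(pattern_matrix(unit), build_probe(3, 12), rseq)
  rma <- repeats_from_alignment(aln, rseq)
  lines5 <- format_repeat_alignment(rma, "groups5")
  lines20 <- format_repeat_alignment(rma, "residues20")
  expect_length(lines5, 4)
  expect_match(lines5[2], "^2\\t[KNIMT.]+$")
  expect_match(lines20[2], "^2\\t[A-Z.]+$")
})
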