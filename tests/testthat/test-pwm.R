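test_that("the periodic probe cycles 1..n", {
  expect_identical(as.integer(build_probe(3, 7)), c(1L, 2L, 3L, 1L, 2L, 3L, 1L))
  expect_identical(as.integer(build_probe(2, 4)), c(1L, 2L, 1L, 2L))
  p <- build_probe(5, 5000)
  expect_length(p, 5000)
  expect_identical(attr(p, "n"), 5L)
  expect_error(build_probe(1, 10), "n")
  expect_error(build_probe(5, 3), "L")
})

test_that("pair counting follows the update rule and conserves the total", {
  m <- count_pairs(build_probe(2, 4), c(1L, 1L, 2L, 1L))
  # i=2: row 2, k=1; i=3: row 1, k=1+5*(2-1)=6; i=4: row 2, k=2+5*0=2
  expected <- matrix(0L, 2, 25)
  expected[2, 1] <- 1L; expected[1, 6] <- 1L; expected[2, 2] <- 1L
  expect_equal(unclass(m), expected, ignore_attr = TRUE)
  expect_identical(attr(m, "total"), 3L)

  set.seed(5)
  for (trial in 1:10) {
    n <- sample(2:9, 1); L <- sample(20:200, 1)
    s <- sample.int(5L, L, TRUE)
    expect_identical(attr(count_pairs(build_probe(n, L), s), "total"), L - 1L)
  }
  # single-symbol input: no pairs
  p1 <- structure(1L, n = 2L, class = "periodic_probe")
  m1 <- count_pairs(p1, 3L)
  expect_identical(attr(m1, "total"), 0L)
  expect_true(all(unclass(m1) == 0L))
  expect_error(count_pairs(build_probe(2, 4), c(1L, 2L)), "length")
})

test_that("pair counting along an alignment skips gapped columns", {
  unit <- c(1L, 4L, 2L)
  s <- rep(unit, 8)
  probe <- build_probe(3, length(s))
  aln <- local_align(pattern_matrix(unit), probe, s)
  m <- count_pairs_from_alignment(aln)
  # gapless alignment of m columns -> total m - 1
  expect_identical(attr(m, "total"), length(aln$moves) - 1L)

  # hand-built 6-column path with a gap between two aligned runs:
  # match, match, gap_in_seq, match, match, gap_in_probe
  fake <- structure(list(
    mF = 1, n = 3, del = 25,
    moves = c(1L, 1L, 2L, 1L, 1L, 3L),
    seq_pos = c(2L, 3L, NA, 4L, 5L, 6L),
    probe_pos = c(1L, 2L, 3L, 4L, 5L, NA),
    seq_symbol = c(1L, 4L, NA, 2L, 1L, 4L),
    probe_symbol = c(1L, 2L, 3L, 1L, 2L, NA)
  ), class = "local_alignment")
  mf <- count_pairs_from_alignment(fake)
  # counted pairs: cols 1->2 (row 2, k=1+5*3=16) and 4->5 (row 2, k=2+5*0=2)
  expect_identical(attr(mf, "total"), 2L)
  expect_identical(unclass(mf)[2, 16], 1L)
  expect_identical(unclass(mf)[2, 2], 1L)

  one <- fake; one$moves <- 1L; one$seq_pos <- 2L; one$probe_pos <- 1L
  one$seq_symbol <- 1L; one$probe_symbol <- 1L
  expect_identical(attr(count_pairs_from_alignment(one), "total"), 0L)
})

test_that("count-to-weight conversion matches a cell-by-cell recomputation", {
  # counts exactly at their margin expectation vanish
  m1 <- matrix(4L, 3, 25)
  m1 <- structure(m1, total = sum(m1), class = c("count_matrix", "matrix", "array"))
  expect_true(all(abs(weight_from_counts(m1)) < 1e-12))

  set.seed(31)
  for (trial in 1:25) {
    counts <- matrix(rpois(75, 5), 3, 25)
    counts[1, 1] <- counts[1, 1] + 1L # ensure non-degenerate
    cm <- structure(counts, total = sum(counts),
                    class = c("count_matrix", "matrix", "array"))
    w <- weight_from_counts(cm)
    expect_equal(unclass(w), eq3_oracle(counts), tolerance = 1e-10,
                 ignore_attr = TRUE)
    # the transform is not scale-free
    cm4 <- structure(counts * 4L, total = sum(counts) * 4L,
                     class = c("count_matrix", "matrix", "array"))
    w4 <- weight_from_counts(cm4)
    expect_equal(unclass(w4), eq3_oracle(counts * 4L), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_gt(max(abs(unclass(w4) - unclass(w))), 1e-8)
  }

  degen <- matrix(0L, 3, 25); degen[2, 5] <- 10L
  degen <- structure(degen, total = 10L,
                     class = c("count_matrix", "matrix", "array"))
  expect_error(weight_from_counts(degen), "degenerate")
})

test_that("normalization fixes R2 = 110 n and Kd = -1 and is idempotent", {
  set.seed(7)
  for (n in c(2L, 7L, 20L)) {
    for (trial in 1:20) {
      w <- matrix(rnorm(n * 25), n, 25)
      out <- normalize_matrix(w)
      expect_equal(matrix_r2(out), 110 * n, tolerance = 1e-9)
      expect_equal(matrix_kd(out), -1, tolerance = 1e-9)
      # fixed point: renormalizing changes nothing
      again <- normalize_matrix(out)
      expect_equal(unclass(again), unclass(out), tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  }
  expect_error(normalize_matrix(matrix(3, 4, 25)), "variance")
})

test_that("random matrix sets are seeded, normalized and extendable", {
  q1 <- generate_matrix_set(7, count = 3, seed = 1, probe_copies = 200)
  q2 <- generate_matrix_set(7, count = 3, seed = 1, probe_copies = 200)
  expect_equal(q1, q2)
  q5 <- generate_matrix_set(7, count = 5, seed = 1, probe_copies = 200)
  for (i in 1:3) expect_equal(unclass(q5[[i]]), unclass(q1[[i]]))

  qn2 <- generate_matrix_set(2, count = 20, seed = 3, probe_copies = 500)
  for (m in qn2) {
    expect_equal(matrix_r2(m), 220, tolerance = 1e-8)
    expect_equal(matrix_kd(m), -1, tolerance = 1e-8)
  }
  # members differ pairwise
  for (i in 1:5) for (j in seq_len(i - 1))
    expect_gt(sqrt(sum((qn2[[i]] - qn2[[j]])^2)), 1e-6)
})

test_that("raw pair counts from uniform sequences match their expectation", {
  n <- 5L; L <- 1000L * n
  probe <- build_probe(n, L)
  reps <- 100L
  tracked <- matrix(NA_real_, reps, 3) # three arbitrary fixed cells
  for (r in seq_len(reps)) {
    set.seed(100 + r)
    s2 <- sample.int(5L, L, TRUE)
    cm <- unclass(count_pairs(probe, s2))
    tracked[r, ] <- c(cm[1, 1], cm[3, 17], cm[5, 25])
  }
  expected <- (L - 1) / (n * 25) # E[M1(i,j)] under the uniform model
  for (c in 1:3) {
    se <- stats::sd(tracked[, c]) / sqrt(reps)
    expect_lt(abs(mean(tracked[, c]) - expected), 3 * se)
  }
})

test_that("weight matrices serialize losslessly", {
  m <- random_norm_matrix(4, seed = 9)
  jf <- tempfile(fileext = ".json"); tf <- tempfile(fileext = ".tsv")
  write_matrix_json(m, jf)
  back <- read_matrix_json(jf)
  expect_identical(unclass(back)[, ], unclass(m)[, ])
  write_matrix_tsv(m, tf)
  tab <- utils::read.table(tf, sep = "\t", header = TRUE, check.names = FALSE)
  expect_identical(dim(tab), c(4L, 26L))
  expect_equal(as.numeric(tab[2, 5]), unclass(m)[2, 4], tolerance = 1e-15)
})
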