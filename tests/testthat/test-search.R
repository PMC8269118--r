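make_fake_period <- function(n, z, seq_start, seq_end, member = 1L) {
  structure(list(
    n = n, F_max = z * 10, member = member, Z = z,
    M_max = NULL, significance = NULL,
    local = structure(list(mF = z * 10, n = n,
                           moves = rep(1L, seq_end - seq_start + 1L),
                           seq_start = seq_start, seq_end = seq_end,
                           probe_start = seq_start, probe_end = seq_end,
                           del = 25),
                      class = "local_alignment")
  ), class = "period_result")
}

test_that("refinement never loses the best score and improves planted repeats", {
  unit <- c(1L, 4L, 2L, 2L, 5L, 3L, 1L)
  set.seed(41)
  for (trial in 1:12) {
    s <- rep(unit, 10)
    subs <- sample(length(s), round(0.5 * length(s)), replace = TRUE)
    s[subs] <- sample.int(5L, length(subs), TRUE)
    probe <- build_probe(7, length(s))
    mt0 <- random_norm_matrix(7, seed = 1000 + trial)
    first <- local_align(mt0, probe, s)
    ref <- refine_alignment(mt0, probe, s)
    expect_gte(ref$mF, first$mF)
    expect_equal(ref$mF, ref$local$mF)
  }
})

test_that("refinement at a fixed point stops immediately", {
  unit <- c(1L, 4L, 2L)
  s <- rep(unit, 12)
  probe <- build_probe(3, length(s))
  mt <- pattern_matrix(unit, hi = 50, lo = -50)
  ref <- refine_alignment(mt, probe, s)
  expect_gte(ref$mF, local_align(mt, probe, s)$mF)
  # empty first alignment short-circuits
  neg <- structure(matrix(-3, 3, 25), class = c("norm_weight_matrix", "matrix", "array"))
  ref0 <- refine_alignment(neg, probe, s)
  expect_equal(ref0$mF, 0)
  expect_length(ref0$local$moves, 0)
})

test_that("the best-over-set selection is an argmax with monotone growth", {
  set.seed(2)
  s <- sample.int(5L, 80, TRUE)
  probe <- build_probe(5, 80)
  q1 <- generate_matrix_set(5, count = 1, seed = 11, probe_copies = 200)
  single <- best_over_set(q1, probe, s)
  expect_equal(single$F_max, refine_alignment(q1[[1]], probe, s)$mF)
  expect_equal(single$member, 1L)

  q6 <- generate_matrix_set(5, count = 6, seed = 11, probe_copies = 200)
  r6 <- best_over_set(q6, probe, s)
  each <- vapply(seq_along(q6), function(i)
    refine_alignment(q6[[i]], probe, s)$mF, numeric(1))
  expect_equal(r6$F_max, max(each))
  expect_true(all(r6$F_max >= each))

  q12 <- generate_matrix_set(5, count = 12, seed = 11, probe_copies = 200)
  r12 <- best_over_set(q12, probe, s)
  expect_gte(r12$F_max, r6$F_max) # superset never decreases F_max
})

test_that("Monte-Carlo significance matches its own null summaries", {
  unit <- c(1L, 4L, 2L, 2L, 5L)
  s <- rep(unit, 16)
  probe <- build_probe(5, length(s))
  q <- generate_matrix_set(5, count = 5, seed = 4, probe_copies = 200)
  res <- best_over_set(q, probe, s)
  sig <- significance_z(res, s, shuffles = 20, seed = 9)
  expect_equal(sig$Z, (res$F_max - mean(sig$scores)) / stats::sd(sig$scores))
  expect_equal(sig$mean, mean(sig$scores))
  expect_gt(sig$Z, 6) # a clean 16-copy tandem is unambiguous
  expect_error(significance_z(res, s, shuffles = 1), "shuffles")
})

test_that("scanning recovers the period of a clean tandem, stably across seeds", {
  unit <- c(1L, 4L, 2L, 2L, 5L)
  s <- rep(unit, 20)
  best_n <- sapply(c(21, 22), function(sd) {
    sp <- scan_sequence(s, n_min = 2, n_max = 8, set_size = 30, shuffles = 20,
                        seed = sd, probe_copies = 200)
    zs <- vapply(sp, function(r) r$Z, numeric(1))
    sp[[which.max(zs)]]$n
  })
  expect_equal(best_n[1], 5L)
  expect_equal(best_n[2], 5L)
  expect_error(scan_sequence(sample.int(5L, 13, TRUE)), "too short")
})

test_that("period filtering removes redundant multiples and keeps separated calls", {
  sp <- list(
    make_fake_period(5L, z = 12, seq_start = 10, seq_end = 109),
    make_fake_period(10L, z = 8, seq_start = 12, seq_end = 105), # same span
    make_fake_period(3L, z = 7, seq_start = 300, seq_end = 380), # separate
    make_fake_period(4L, z = 2, seq_start = 40, seq_end = 90)    # below z0
  )
  ann <- filter_periods(sp, z0 = 6)
  expect_equal(sort(ann$n0), c(3L, 5L))
  expect_equal(ann$Z[ann$n0 == 5L], 12)

  # 40% overlap of the shorter span: both survive
  sp2 <- list(
    make_fake_period(5L, z = 12, seq_start = 1, seq_end = 100),
    make_fake_period(7L, z = 9, seq_start = 61, seq_end = 160)
  )
  ann2 <- filter_periods(sp2, z0 = 6)
  expect_equal(nrow(ann2), 2L)

  # spans shorter than 14 residues are dropped
  sp3 <- list(make_fake_period(2L, z = 20, seq_start = 5, seq_end = 17))
  expect_equal(nrow(filter_periods(sp3, z0 = 6)), 0L)
  sp4 <- list(make_fake_period(2L, z = 20, seq_start = 5, seq_end = 18))
  expect_equal(nrow(filter_periods(sp4, z0 = 6)), 1L)
})

test_that("FDR follows the shuffled-over-real identification", {
  expect_equal(round(100 * estimate_fdr(3720, 1284), 1), 34.5)
  expect_equal(estimate_fdr(100, 0), 0)
  expect_equal(estimate_fdr(100, 100), 1)
  expect_error(estimate_fdr(0, 0), "undefined")
  expect_error(estimate_fdr(10, 11), "shuffled_hits")
})

test_that("shuffled sequences rarely reach the significance threshold", {
  set.seed(55)
  hits <- 0L
  for (trial in 1:8) {
    s <- sample.int(5L, 120, TRUE)
    sp <- scan_sequence(s, n_min = 4, n_max = 6, set_size = 20, shuffles = 20,
                        seed = 300 + trial, probe_copies = 200)
    if (any(vapply(sp, function(r) r$Z, numeric(1)) >= 6)) hits <- hits + 1L
  }
  expect_lte(hits, 2L)
})
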