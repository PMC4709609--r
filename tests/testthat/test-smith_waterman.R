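test_that("known alignments score and trace as expected", {
  # empty query: all-zero matrix
  m <- sw_fill_serial("", "ACGT")
  expect_equal(m$best_score, 0L)
  expect_true(all(m$Z == 0L))

  # identical sequences: full-length identity
  sc <- sw_scheme(1, -3, 5, 2)
  aln <- sw_align("ACGT", "ACGT", sc)
  expect_equal(aln$score, 4L)
  expect_equal(aln$ops, "4M")
  expect_equal(aln$q0_interval, c(0L, 4L))
  expect_equal(aln$q1_interval, c(0L, 4L))

  # AAAG vs AAAT: best is the 3-match prefix
  sc2 <- sw_scheme(1, -1, 2, 1)
  m2 <- sw_fill_serial("AAAG", "AAAT", sc2)
  expect_equal(m2$best_score, 3L)
  bt <- sw_backtrack(m2)
  expect_equal(bt$score, 3L)
  expect_equal(bt$q0_interval, c(0L, 3L))
  expect_equal(bt$q1_interval, c(0L, 3L))
  expect_equal(bt$ops, "3M")

  # engineered 3-base gap: one deletion run of length 3
  aln3 <- sw_align("ACGTACGT", "ACGTTTTACGT", sw_scheme(2, -3, 2, 1))
  expect_equal(aln3$score, 12L)
  runs <- regmatches(aln3$ops, gregexpr("[0-9]+D", aln3$ops))[[1L]]
  expect_equal(runs, "3D")
})

test_that("matrix invariants hold on random fills", {
  set.seed(11)
  for (k in 1:30) {
    q0 <- rand_dna(sample(1:20, 1)); q1 <- rand_dna(sample(1:20, 1))
    m <- sw_fill_serial(q0, q1)
    expect_true(all(m$Z[1, ] == 0L))
    expect_true(all(m$Z[, 1] == 0L))
    expect_true(all(m$Z >= 0L))
    expect_equal(dim(m$Z), c(nchar(q0) + 1L, nchar(q1) + 1L))
    # best_cell really is the (row-major first) maximum
    expect_equal(m$best_score, max(m$Z))
    expect_equal(m$Z[m$best_cell[1] + 1L, m$best_cell[2] + 1L], m$best_score)
  }
})

test_that("the enumeration oracle and the gap-length oracle agree on tiny pairs", {
  set.seed(12)
  sc <- sw_scheme(1, -2, 3, 1)
  for (k in 1:40) {
    q0 <- rand_dna(sample(1:4, 1)); q1 <- rand_dna(sample(1:4, 1))
    expect_equal(local_affine_oracle(q0, q1, sc),
                 enum_local_oracle(q0, q1, sc),
                 info = paste(q0, q1))
  }
})

test_that("serial fill matches the independent affine oracle", {
  set.seed(13)
  schemes <- list(sw_scheme(), sw_scheme(1, -1, 2, 1), sw_scheme(2, -3, 3, 1))
  for (k in 1:150) {
    sc <- schemes[[sample(3, 1)]]
    q0 <- rand_dna(sample(1:6, 1)); q1 <- rand_dna(sample(1:6, 1))
    expect_equal(sw_fill_serial(q0, q1, sc)$best_score,
                 local_affine_oracle(q0, q1, sc),
                 info = paste(q0, q1))
  }
})

test_that("wavefront fill is bit-identical to serial for every lane count", {
  set.seed(14)
  for (k in 1:40) {
    q0 <- rand_dna(sample(1:48, 1)); q1 <- rand_dna(sample(1:48, 1))
    s <- sw_fill_serial(q0, q1)
    for (ln in c(1L, 2L, 4L, 8L)) {
      w <- sw_fill_wavefront(q0, q1, lanes = ln)
      expect_identical(w$Z, s$Z)
      expect_identical(w$I, s$I)
      expect_identical(w$J, s$J)
      expect_identical(w$best_cell, s$best_cell)
    }
  }
  expect_error(sw_fill_wavefront("ACGT", "ACGT", lanes = 0), "lanes")
})

test_that("named example pair scores equally in both fill modes", {
  s <- sw_fill_serial("BANANA", "ANANAS")
  for (ln in c(1L, 3L, 7L))
    expect_equal(sw_fill_wavefront("BANANA", "ANANAS", lanes = ln)$best_score,
                 s$best_score)
})

test_that("backtracked alignments re-score to their stated score", {
  set.seed(15)
  sc <- sw_scheme(2, -3, 4, 1)
  for (k in 1:50) {
    q0 <- rand_dna(sample(5:40, 1)); q1 <- rand_dna(sample(5:40, 1))
    aln <- sw_align(q0, q1, sc)
    if (aln$score == 0L) {
      expect_equal(aln$q0_interval[1], aln$q0_interval[2])
      next
    }
    expect_equal(rescore_ops(aln$ops,
                             substr(q0, aln$q0_interval[1] + 1L,
                                    aln$q0_interval[2]),
                             substr(q1, aln$q1_interval[1] + 1L,
                                    aln$q1_interval[2]), sc),
                 aln$score)
  }
})

test_that("score is monotone under shared extension and symmetric", {
  set.seed(16)
  for (k in 1:25) {
    q0 <- rand_dna(sample(1:15, 1)); q1 <- rand_dna(sample(1:15, 1))
    base <- sw_fill_serial(q0, q1)$best_score
    ext <- rand_dna(3)
    expect_gte(sw_fill_serial(paste0(q0, ext), paste0(q1, ext))$best_score,
               base)
    expect_equal(sw_fill_serial(q1, q0)$best_score, base)
  }
})

test_that("N is never rewarded", {
  m <- sw_fill_serial("NNNN", "NNNN")
  expect_equal(m$best_score, 0L)
})
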