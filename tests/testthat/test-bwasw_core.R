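# heuristics disabled: the seeding scores must be exact
exact_params <- function(...) seed_params(max_interval_width = Inf,
                                          min_seed_score = 1e-9,
                                          seed_x_drop = Inf, ...)

test_that("seeding DP attains the Smith-Waterman best score when pruning is off", {
  # letter example: N is an ordinary symbol here
  scl <- sw_scheme(special_n = FALSE)
  dg <- build_prefix_dawg("ANA")
  fm <- build_fm_index("BANANA$")
  pr <- bwasw_dp(dg, fm, scl, exact_params())
  expect_equal(attr(pr, "best_score"), 3L)
  expect_equal(attr(pr, "best_score"),
               sw_fill_serial("ANA", "BANANA", scl)$best_score)
  sc <- sw_scheme()

  # nothing in common: no positive state survives
  dg2 <- build_prefix_dawg("CCCC")
  fm2 <- build_fm_index("GGGG$")
  pr2 <- bwasw_dp(dg2, fm2, sc, exact_params())
  expect_equal(nrow(pr2), 0L)
  expect_equal(attr(pr2, "best_score"), 0L)

  set.seed(31)
  for (k in 1:30) {
    q <- rand_dna(sample(10:40, 1)); r <- rand_dna(sample(30:120, 1))
    pr <- bwasw_dp(build_prefix_dawg(q), build_fm_index(paste0(r, "$")), sc,
                   exact_params())
    expect_equal(attr(pr, "best_score"),
                 sw_fill_serial(q, r, sc)$best_score, info = paste(q, r))
  }
})

test_that("seed interval pairs expand to the right concrete seeds", {
  sc <- sw_scheme(special_n = FALSE)
  dg <- build_prefix_dawg("ANA")
  fm <- build_fm_index("BANANA$")
  pr <- bwasw_dp(dg, fm, sc, seed_params(max_interval_width = Inf,
                                         min_seed_score = 3,
                                         seed_x_drop = Inf))
  sd <- seeds_from_pairs(pr, fm, dg)
  # the full "ANA" match must seed at reference positions 1 and 3
  full <- sd[sd$q_len == 3L & sd$score == 3L, ]
  expect_setequal(full$r_pos, c(1L, 3L))
  expect_true(all(full$q_pos == 0L))

  expect_equal(nrow(seeds_from_pairs(pr[0, ], fm, dg)), 0L)

  # seed count equals sum(interval width x class positions) absent duplicates
  q <- "ACG"; r <- "TTACGTT"
  dg3 <- build_prefix_dawg(q)
  fm3 <- build_fm_index(paste0(r, "$"))
  pr3 <- bwasw_dp(dg3, fm3, sc, seed_params(max_interval_width = Inf,
                                            min_seed_score = 3,
                                            seed_x_drop = Inf))
  sd3 <- seeds_from_pairs(pr3, fm3, dg3)
  # per-pair candidate volume, before (q_pos, r_pos) deduplication
  volume <- sum(vapply(seq_len(nrow(pr3)), function(i)
    (pr3$hi[i] - pr3$lo[i]) * length(dawg_positions(dg3, pr3$node[i])),
    numeric(1)))
  expect_gte(volume, nrow(sd3))
  expect_true(any(sd3$q_pos == 0L & sd3$r_pos == 2L & sd3$q_len == 3L))
})

test_that("duplicate (q_pos, r_pos) seeds collapse to one", {
  sc <- sw_scheme()
  q <- "ACGTACGT"  # repeated 4-mer: several pairs place seeds identically
  r <- paste0("TT", q, "TT")
  dg <- build_prefix_dawg(q)
  fm <- build_fm_index(paste0(r, "$"))
  pr <- bwasw_dp(dg, fm, sc, exact_params())
  sd <- seeds_from_pairs(pr, fm, dg)
  expect_false(any(duplicated(paste(sd$q_pos, sd$r_pos))))
})

test_that("seed extension windows, thresholds and clipping behave", {
  set.seed(32)
  sc <- sw_scheme()
  core <- rand_dna(20)
  q <- paste0(rand_dna(30), core, rand_dna(30))
  r <- paste0(rand_dna(50), core, rand_dna(50))
  seed <- list(q_pos = 30L, r_pos = 50L, q_len = 20L, r_len = 20L)
  rec <- extend_seed(seed, q, r, sc, seed_params(min_report_score = 20L))
  expect_false(is.null(rec))
  expect_gte(rec$score, 20L * sc$match)
  expect_lte(rec$r_start, 50L)
  expect_gte(rec$r_end, 70L)
  expect_equal(rescore_record(rec, q, r, sc), rec$score)

  # below the reporting threshold: nothing
  expect_null(extend_seed(seed, q, r, sc,
                          seed_params(min_report_score = 1000L)))

  # seed at the origin of both chunks: clipped window is fine
  seed0 <- list(q_pos = 0L, r_pos = 0L, q_len = 10L, r_len = 10L)
  q0 <- paste0(substr(r, 1, 10), rand_dna(20))
  rec0 <- extend_seed(seed0, q0, r, sc, seed_params(min_report_score = 10L))
  expect_false(is.null(rec0))
  expect_equal(rec0$r_start, 0L)
})

test_that("long-read alignment recovers planted slices on both strands", {
  set.seed(33)
  ref <- generate_reference(3000, seed = 41)[[1L]]
  q <- substr(ref, 1001, 1200)
  recs <- align_long_read(q, ref, query_id = "fwd")
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$r_start, 1000L)
  expect_equal(recs$r_end, 1200L)
  expect_equal(recs$strand, "+")
  expect_equal(recs$score, 200L)

  rc <- revcomp(q)
  recs2 <- align_long_read(rc, ref, query_id = "rev")
  expect_equal(nrow(recs2), 1L)
  expect_equal(recs2$strand, "-")
  expect_equal(recs2$r_start, 1000L)
  expect_equal(recs2$r_end, 1200L)
  # reverse-strand records keep query coordinates in the read frame
  expect_equal(recs2$q_start, 0L)
  expect_equal(recs2$q_end, 200L)

  # without the reverse strand the reverse-complemented read is invisible
  expect_equal(nrow(align_long_read(rc, ref, both_strands = FALSE)), 0L)

  # unrelated chunks: any record must clear the reporting threshold
  r2 <- rand_dna(400); q2 <- rand_dna(80)
  recs3 <- align_long_read(q2, r2)
  if (nrow(recs3) > 0L)
    expect_true(all(recs3$score >= seed_params()$min_report_score))
})

test_that("strand handling is involutive", {
  set.seed(34)
  ref <- generate_reference(2000, seed = 42)[[1L]]
  q <- substr(ref, 301, 600)
  fwd <- align_long_read(q, ref, query_id = "x")
  rev <- align_long_read(revcomp(q), ref, query_id = "x")
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(fwd$r_start, rev$r_start)
  expect_equal(fwd$r_end, rev$r_end)
  expect_setequal(rev$strand, "-")
  # coordinate map: read-frame query intervals mirror each other
  expect_equal(rev$q_start, fwd$q_len - fwd$q_end)
  expect_equal(rev$q_end, fwd$q_len - fwd$q_start)
})

test_that("tightening the seeding heuristics never adds records", {
  set.seed(35)
  ref <- generate_reference(4000, seed = 43)
  rs <- sample_reads(ref, 3, 250, sub_rate = 0.03, seed = 44)
  for (i in seq_along(rs$reads)) {
    loose <- align_long_read(rs$reads[[i]], ref[[1L]],
                             params = seed_params(max_interval_width = 8,
                                                  min_seed_score = 12))
    tight_w <- align_long_read(rs$reads[[i]], ref[[1L]],
                               params = seed_params(max_interval_width = 1,
                                                    min_seed_score = 12))
    tight_s <- align_long_read(rs$reads[[i]], ref[[1L]],
                               params = seed_params(max_interval_width = 8,
                                                    min_seed_score = 40))
    expect_lte(nrow(tight_w), nrow(loose))
    expect_lte(nrow(tight_s), nrow(loose))
  }
})

test_that("reported records re-score to their stated scores", {
  set.seed(36)
  ref <- generate_reference(3000, seed = 45)
  rs <- sample_reads(ref, 4, 300, sub_rate = 0.02, ins_rate = 0.003,
                     del_rate = 0.003, seed = 46)
  for (i in seq_along(rs$reads)) {
    recs <- align_long_read(rs$reads[[i]], ref[[1L]],
                            query_id = names(rs$reads)[i])
    for (j in seq_len(nrow(recs)))
      expect_equal(rescore_record(recs[j, ], rs$reads[[i]], ref[[1L]]),
                   recs$score[j])
  }
})
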