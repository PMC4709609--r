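test_that("reference chunking follows the overlap convention", {
  ch <- split_reference(strrep("A", 100), 40, 10)
  expect_equal(t(vapply(ch, function(x) c(x$start, x$end), integer(2))),
               matrix(c(0L, 40L, 30L, 70L, 60L, 100L), ncol = 2,
                      byrow = TRUE))
  # coverage and exact overlap sharing
  for (i in seq_along(ch)[-1])
    expect_equal(ch[[i - 1]]$end - ch[[i]]$start, 10L)
  expect_equal(ch[[length(ch)]]$end, 100L)
  # disjoint partition at overlap 0
  ch0 <- split_reference(strrep("A", 100), 25, 0)
  expect_equal(vapply(ch0, `[[`, integer(1), "start"), c(0L, 25L, 50L, 75L))
  # short reference: one chunk
  ch1 <- split_reference(strrep("A", 35), 40, 10)
  expect_length(ch1, 1L)
  expect_equal(c(ch1[[1]]$start, ch1[[1]]$end), c(0L, 35L))
  expect_error(split_reference(strrep("A", 100), 40, 40), "overlap")
  # chunk-local residues round-trip to global coordinates
  ref <- rand_dna(100)
  for (c2 in split_reference(ref, 40, 10))
    expect_equal(c2$residues, substr(ref, c2$start + 1L, c2$end))
})

test_that("query chunking mirrors the reference convention", {
  q <- strrep("C", 1000)
  expect_length(split_query(q, 1000), 1L)
  qs <- split_query(q, 600, 200, query_id = "r1")
  expect_equal(vapply(qs, `[[`, integer(1), "offset"), c(0L, 400L))
  expect_equal(nchar(qs[[2]]$residues), 600L)
  expect_error(split_query(q, 600, 600), "overlap")
})

test_that("map tasks emit globally-addressed intermediate records", {
  set.seed(51)
  ref <- generate_reference(1200, seed = 52)[[1L]]
  chunks <- split_reference(ref, 500, 200)
  q <- substr(ref, 601, 800)  # exactly the [600, 800) overlap zone
  qrec <- split_query(q, NULL, 0L, query_id = "q1")
  sc <- sw_scheme(); par <- seed_params()
  # the query lies wholly inside the overlap of chunks [300,800) and
  # [600,1100): both map tasks must emit the identical global record
  hits <- list()
  for (ch in chunks) {
    mt <- map_task(ch, qrec, sc, par)
    if (nrow(mt$records) > 0L) hits[[length(hits) + 1L]] <- mt$records
    expect_true(all(c("t_get", "t_qi", "t_align", "t_store") %in%
                      names(mt$timing)))
  }
  hits <- do.call(rbind, hits)
  expect_gte(nrow(hits), 2L)
  key <- paste(hits$q_start, hits$q_end, hits$r_start, hits$r_end,
               hits$strand, hits$score, hits$ops)
  expect_equal(length(unique(key)), 1L)
  expect_equal(hits$r_start[1L], 600L)

  # unrelated query: empty
  mt0 <- map_task(chunks[[1L]], split_query(rand_dna(100)), sc, par)
  expect_equal(nrow(mt0$records), 0L)
})

test_that("shuffle groups by query and sorts deterministically", {
  a <- rec_df(list(query = "q2", r_start = 50L, r_end = 90L, score = 10L,
                   chunk = 1L),
              list(query = "q1", r_start = 10L, r_end = 30L, score = 5L,
                   chunk = 0L),
              list(query = "q1", r_start = 10L, r_end = 30L, score = 9L,
                   chunk = 2L),
              list(query = "q1", r_start = 10L, r_end = 25L, score = 9L,
                   chunk = 1L))
  g <- shuffle_sort(a)
  expect_equal(names(g), c("q1", "q2"))
  # same start: higher score first, then chunk id
  expect_equal(g$q1$score, c(9L, 9L, 5L))
  expect_equal(g$q1$chunk, c(1L, 2L, 0L))
  expect_length(shuffle_sort(empty_records()), 0L)
  set.seed(53)
  for (k in 1:10) {
    perm <- a[sample(nrow(a)), ]
    expect_identical(shuffle_sort(perm), g)
  }
})

test_that("reduce keeps nonredundant, nonoverlapping records", {
  # exact duplicates from adjacent chunks collapse
  dup <- rec_df(list(query = "q", r_start = 10L, r_end = 60L, score = 40L,
                     chunk = 0L),
                list(query = "q", r_start = 10L, r_end = 60L, score = 40L,
                     chunk = 1L))
  expect_equal(nrow(reduce_task(shuffle_sort(dup)$q)), 1L)

  # disjoint records both survive
  dis <- rec_df(list(query = "q", r_start = 0L, r_end = 40L, score = 30L),
                list(query = "q", r_start = 100L, r_end = 140L, score = 31L))
  expect_equal(nrow(reduce_task(shuffle_sort(dis)$q)), 2L)

  # 90% overlap: only the better-scoring record survives
  ab <- rec_df(list(query = "q", r_start = 0L, r_end = 100L, score = 50L),
               list(query = "q", r_start = 10L, r_end = 100L, score = 40L))
  out <- reduce_task(shuffle_sort(ab)$q, redundancy_fraction = 0.5)
  expect_equal(out$score, 50L)

  # opposite strands never conflict
  st <- rec_df(list(query = "q", r_start = 0L, r_end = 100L, score = 50L,
                    strand = "+"),
               list(query = "q", r_start = 10L, r_end = 100L, score = 40L,
                    strand = "-"))
  expect_equal(nrow(reduce_task(shuffle_sort(st)$q)), 2L)
})

test_that("greedy reduce matches the enumeration oracle on small groups", {
  set.seed(54)
  for (k in 1:30) {
    n <- sample(2:7, 1)
    rows <- lapply(seq_len(n), function(i) {
      s <- sample(0:150, 1)
      list(query = "q", r_start = s, r_end = s + sample(10:60, 1),
           score = sample(10:60, 1),
           strand = sample(c("+", "-"), 1), chunk = sample(0:2, 1))
    })
    g <- shuffle_sort(do.call(rec_df, rows))$q
    frac <- sample(c(0.25, 0.5, 0.75), 1)
    got <- reduce_task(g, redundancy_fraction = frac)
    want <- reduce_oracle(g, frac)
    expect_equal(got[, setdiff(names(got), "chunk")],
                 want[, setdiff(names(want), "chunk")], info = k)
  }
})

test_that("the pipeline is invariant to workers, chunking and phase overlap", {
  set.seed(55)
  ref <- generate_reference(2500, seed = 56)
  rs <- sample_reads(ref, 4, 300, sub_rate = 0.02, ins_rate = 0.002,
                     del_rate = 0.002, seed = 57)
  base_cfg <- run_config(chunking = list(chunk_len = 1000L, overlap = 450L))
  base <- run_pipeline(ref, rs$reads, base_cfg)

  # degenerate single-chunk single-worker pipeline equals the direct call
  one_cfg <- run_config(chunking = list(chunk_len = 5000L, overlap = 0L))
  one <- run_pipeline(ref, rs$reads, one_cfg)
  direct <- do.call(rbind, lapply(names(rs$reads), function(qid)
    align_long_read(rs$reads[[qid]], ref[[1L]], query_id = qid,
                    ref_name = "ref")))
  direct <- do.call(rbind, lapply(shuffle_sort(direct), reduce_task))
  expect_identical(normalize_records(one$records, drop_chunk = TRUE),
                   normalize_records(direct, drop_chunk = TRUE))

  # worker-count invariance
  for (w in c(2L, 4L)) {
    cfg <- run_config(chunking = list(chunk_len = 1000L, overlap = 450L),
                      workers = list(w = w))
    expect_identical(run_pipeline(ref, rs$reads, cfg)$records, base$records,
                     info = paste("w =", w))
  }

  # chunked (overlap > alignment span) vs unchunked
  expect_identical(normalize_records(base$records, drop_chunk = TRUE),
                   normalize_records(one$records, drop_chunk = TRUE))

  # phase overlap changes only the makespan report
  cfg_no <- run_config(chunking = list(chunk_len = 1000L, overlap = 450L),
                       workers = list(phase_overlap = FALSE))
  no <- run_pipeline(ref, rs$reads, cfg_no)
  expect_identical(no$records, base$records)
  expect_false(no$makespan$phase_overlap)
})

test_that("alignments inside overlap zones appear exactly once", {
  set.seed(58)
  ref <- generate_reference(1500, seed = 59)[[1L]]
  # plant the query wholly inside the [500, 1000) overlap zone
  q <- substr(ref, 601, 900)
  cfg <- run_config(chunking = list(chunk_len = 1000L, overlap = 500L),
                    output = list(both_strands = FALSE))
  out <- run_pipeline(setNames(ref, "ref"), c(q1 = q), cfg)
  hit <- out$records[out$records$r_start == 600L & out$records$r_end == 900L, ]
  expect_equal(nrow(hit), 1L)
})

test_that("spill-to-disk intermediates reproduce the in-memory run", {
  set.seed(60)
  ref <- generate_reference(1200, seed = 61)
  rs <- sample_reads(ref, 2, 200, sub_rate = 0.01, seed = 62)
  dir <- tempfile("spill")
  cfg_mem <- run_config(chunking = list(chunk_len = 800L, overlap = 300L))
  cfg_disk <- run_config(chunking = list(chunk_len = 800L, overlap = 300L),
                         spill_dir = dir)
  mem <- run_pipeline(ref, rs$reads, cfg_mem)
  disk <- run_pipeline(ref, rs$reads, cfg_disk)
  expect_identical(disk$records, mem$records)
  expect_true(length(list.files(dir, pattern = "jsonl")) > 0L)
  unlink(dir, recursive = TRUE)
})

test_that("makespan aggregates are the worker means and their sum", {
  rep2 <- makespan_report(
    map_workers = list(
      list(makespan = 2, t_get = 0, t_qi = 0, t_align = 2, t_store = 0,
           n_tasks = 1),
      list(makespan = 4, t_get = 0, t_qi = 0, t_align = 4, t_store = 0,
           n_tasks = 1)),
    reduce_workers = list(
      list(makespan = 1, t_get = 1, t_fn = 0, t_store = 0),
      list(makespan = 1, t_get = 1, t_fn = 0, t_store = 0)),
    w = 2L)
  s <- makespan_summary(rep2)
  expect_equal(s$t_map, 3)
  expect_equal(s$t_reduce, 1)
  expect_equal(s$t_vm_config, 0)
  expect_equal(s$t_total, 4)

  # single worker: aggregates equal that worker's terms
  rep1 <- makespan_report(
    map_workers = list(list(makespan = 5, t_get = 1, t_qi = 1, t_align = 2,
                            t_store = 1, n_tasks = 2)),
    reduce_workers = list(list(makespan = 2, t_get = 1, t_fn = 0.5,
                               t_store = 0.5)))
  s1 <- makespan_summary(rep1)
  expect_equal(s1$t_map, 5)
  expect_equal(s1$t_reduce, 2)

  expect_error(makespan_summary(structure(list(map_workers = list(),
                                               reduce_workers = list()),
                                          class = "makespan_report")))
})

test_that("real pipeline timings decompose consistently", {
  set.seed(63)
  ref <- generate_reference(1500, seed = 64)
  rs <- sample_reads(ref, 2, 200, sub_rate = 0.01, seed = 65)
  out <- run_pipeline(ref, rs$reads,
                      run_config(chunking = list(chunk_len = 800L,
                                                 overlap = 300L)))
  rep <- out$makespan
  s <- makespan_summary(rep)
  expect_equal(s$t_total, s$t_map + s$t_reduce)
  expect_equal(s$t_vm_config, 0)
  for (wk in rep$map_workers)
    expect_gte(wk$makespan + 1e-9,
               wk$t_get + wk$t_qi + wk$t_align + wk$t_store)
  js <- jsonlite::fromJSON(makespan_json(rep))
  expect_equal(js$t_total, s$t_total)
})
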