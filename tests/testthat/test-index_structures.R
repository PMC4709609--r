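test_that("suffix arrays match hand-derived and naive results", {
  expect_equal(build_suffix_array("BANANA$"), c(6L, 5L, 3L, 1L, 0L, 4L, 2L))
  expect_equal(build_suffix_array("A$"), c(1L, 0L))
  expect_equal(build_suffix_array("AAAA$"), c(4L, 3L, 2L, 1L, 0L))
  expect_error(build_suffix_array("ACGT"), "sentinel")
  set.seed(21)
  for (k in 1:25) {
    text <- paste0(rand_dna(sample(2:120, 1)), "$")
    expect_equal(build_suffix_array(text), naive_suffix_array(text),
                 info = text)
  }
})

test_that("FM-index construction satisfies its invariants", {
  fm <- build_fm_index("BANANA$")
  expect_equal(fm$bwt, "ANNB$AA")
  expect_equal(lf_reconstruct(fm), "BANANA$")
  expect_equal(build_fm_index("A$")$bwt, "A$")
  expect_error(build_fm_index("AC-G$"), "illegal symbol")
  set.seed(22)
  for (k in 1:15) {
    text <- paste0(rand_dna(sample(2:200, 1)), "$")
    fm <- build_fm_index(text)
    # bwt[i] == text[sa[i] - 1] with wraparound
    n <- fm$n
    prev <- ifelse(fm$sa == 0L, n - 1L, fm$sa - 1L)
    expect_equal(fm$bwt, paste(strsplit(text, "")[[1L]][prev + 1L],
                               collapse = ""))
    expect_equal(lf_reconstruct(fm), text)
  }
})

test_that("backward extension widths equal naive substring counts", {
  fm <- build_fm_index("BANANA$")
  iv_na <- backward_search(fm, "NA")
  iv_ana <- backward_extend(fm, iv_na, "A")
  expect_equal(iv_ana[2] - iv_ana[1], 2L)   # "ANA" occurs twice
  # absent symbol: empty interval from the full range
  expect_equal(diff(backward_extend(fm, full_interval(fm), "C")), 0L)
  expect_error(backward_extend(fm, full_interval(fm), "-"), "illegal")
  set.seed(23)
  for (k in 1:15) {
    body <- rand_dna(sample(10:200, 1))
    fm <- build_fm_index(paste0(body, "$"))
    for (s in all_substrings(body, 3L)) {
      iv <- backward_search(fm, s)
      expect_equal(iv[2] - iv[1], naive_count(body, s), info = s)
    }
  }
})

test_that("locate returns sorted text positions of the interval", {
  fm <- build_fm_index("BANANA$")
  expect_equal(locate(fm, backward_search(fm, "ANA")), c(1L, 3L))
  expect_equal(locate(fm, c(3L, 3L)), integer(0))
  expect_equal(locate(fm, backward_search(fm, "$")), 6L)
  set.seed(24)
  body <- rand_dna(150)
  fm <- build_fm_index(paste0(body, "$"))
  for (s in sample(all_substrings(body, 4L), 40L)) {
    pos <- locate(fm, backward_search(fm, s))
    expect_equal(length(pos), naive_count(body, s))
    expect_true(all(substring(body, pos + 1L, pos + nchar(s)) == s))
    expect_false(is.unsorted(pos))
  }
})

test_that("prefix DAWG accepts exactly the substrings of the query", {
  dg <- build_prefix_dawg("BANANA")
  for (s in c("ANA", "NAN", "BANANA", "B", "NA"))
    expect_true(dawg_accepts(dg, s), info = s)
  for (s in c("AB", "NN", "BANANAB", "AAN"))
    expect_false(dawg_accepts(dg, s), info = s)
  expect_lte(dg$n_nodes, 2L * 6L)
  expect_equal(build_prefix_dawg("A")$n_nodes, 2L)
  expect_error(build_prefix_dawg(""), "nonempty")

  set.seed(25)
  for (k in 1:10) {
    q <- rand_dna(50)
    dg <- build_prefix_dawg(q)
    expect_lte(dg$n_nodes, 2L * 50L)
    subs <- all_substrings(q, 4L)
    # exhaustive language equality at length <= 4 over the DNA alphabet
    for (len in 1:4) {
      univ <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), len)), 1,
                    paste, collapse = "")
      for (s in univ)
        expect_equal(dawg_accepts(dg, s), s %in% subs, info = s)
    }
  }
})

test_that("DAWG node positions and intervals describe the same classes", {
  q <- "BANANA"
  dg <- build_prefix_dawg(q)
  # walk to the class of "ANA" (transitions prepend: consume right-to-left)
  code <- function(ch) match(ch, LETTERS)
  walk <- function(s) {
    v <- 0L
    for (ch in rev(strsplit(s, "")[[1L]])) {
      v <- dg$trans[v + 1L, code(ch)]
      if (v < 0L) return(NA_integer_)
    }
    v
  }
  node_ana <- walk("ANA")
  expect_equal(dawg_positions(dg, node_ana), c(1L, 3L))
  # "AN" has the same start set as "ANA": same class
  expect_equal(walk("AN"), node_ana)
  # every node's interval width equals its start-position count
  for (v in seq_len(dg$n_nodes) - 1L) {
    if (v == 0L) next
    width <- dg$intervals[v + 1L, 2L] - dg$intervals[v + 1L, 1L]
    expect_equal(width, length(dawg_positions(dg, v)), info = v)
  }
})

test_that("index serialization round-trips through the JSON container", {
  set.seed(26)
  body <- rand_dna(300)
  fm <- build_fm_index(paste0(body, "$"), name = "chr1")
  path <- tempfile(fileext = ".json")
  write_index(fm, path)
  fm2 <- read_index(path)
  expect_identical(fm2$sa, fm$sa)
  expect_identical(fm2$bwt, fm$bwt)
  expect_identical(fm2$text, fm$text)
  expect_identical(fm2$name, "chr1")
  unlink(path)
})
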