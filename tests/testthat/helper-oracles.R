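# Independent oracles used across the suite.  None of them share code with
# the package implementation paths they check.

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# naive suffix array: sort the actual suffix strings (byte order via radix,
# which collates '$' below letters)
naive_suffix_array <- function(text) {
  n <- nchar(text)
  suf <- substring(text, seq_len(n))
  order(suf, method = "radix") - 1L
}

# naive overlapping occurrence count of s in text
naive_count <- function(text, s) {
  k <- nchar(s)
  n <- nchar(text)
  if (k == 0L || k > n) return(if (k == 0L) n + 1L else 0L)
  sum(substring(text, 1:(n - k + 1L), k:n) == s)
}

# all distinct substrings of text with length <= k
all_substrings <- function(text, k) {
  n <- nchar(text)
  out <- character(0)
  for (len in seq_len(min(k, n)))
    out <- c(out, substring(text, 1:(n - len + 1L), len:n))
  unique(out)
}

# gap-length-enumeration formulation of affine local alignment
# (Waterman-Smith-Beyer): H[i,j] = max(0, H[i-1,j-1] + s, max_k H[i-k,j] -
# w(k), max_l H[i,j-l] - w(l)) with w(k) = open + (k-1) * extend.  A
# different algorithm from the three-matrix recursion it is used to check.
local_affine_oracle <- function(q0, q1, scheme) {
  n <- nchar(q0); m <- nchar(q1)
  a <- strsplit(q0, "")[[1L]]; b <- strsplit(q1, "")[[1L]]
  H <- matrix(0, n + 1L, m + 1L)
  w <- function(k) scheme$gap_open + (k - 1L) * scheme$gap_extend
  best <- 0L
  special_n <- isTRUE(scheme$special_n)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    hit <- a[i] == b[j] && !(special_n && a[i] == "N")
    s <- if (hit) scheme$match else scheme$mismatch
    cand <- H[i, j] + s
    ks <- seq_len(i)                      # gap of k rows ending here
    cand <- max(cand, H[i + 1L - ks, j + 1L] - w(ks))
    ls <- seq_len(j)                      # gap of l columns ending here
    cand <- max(cand, H[i + 1L, j + 1L - ls] - w(ls))
    H[i + 1L, j + 1L] <- max(0L, cand)
    if (H[i + 1L, j + 1L] > best) best <- H[i + 1L, j + 1L]
  }
  as.integer(best)
}

# exhaustive path enumeration on tiny strings: every local alignment is a
# sequence of M/I/D ops over a pair of substrings; recursion enumerates all
# of them.  Used to validate local_affine_oracle itself.
enum_local_oracle <- function(q0, q1, scheme) {
  a <- strsplit(q0, "")[[1L]]; b <- strsplit(q1, "")[[1L]]
  best <- 0L
  rec <- function(i, j, score, prev) {
    # may stop at any point: local alignment
    if (score > best) best <<- score
    if (i <= length(a) && j <= length(b)) {
      hit <- a[i] == b[j] && !(isTRUE(scheme$special_n) && a[i] == "N")
      s <- if (hit) scheme$match else scheme$mismatch
      rec(i + 1L, j + 1L, score + s, "M")
    }
    if (i <= length(a))
      rec(i + 1L, j, score - if (prev == "I") scheme$gap_extend
                             else scheme$gap_open, "I")
    if (j <= length(b))
      rec(i, j + 1L, score - if (prev == "D") scheme$gap_extend
                             else scheme$gap_open, "D")
  }
  for (i in seq_len(length(a) + 1L))
    for (j in seq_len(length(b) + 1L))
      rec(i, j, 0L, "M")
  best
}

# map a record to the read's inferred reference origin (what the truth
# table stores for a read)
inferred_read_start <- function(rec) {
  ifelse(rec$strand == "+", rec$r_start - rec$q_start,
         rec$r_start - (rec$q_len - rec$q_end))
}

# order-normalised record comparison (chunk ids may legitimately differ
# between runs with different chunking)
normalize_records <- function(df, drop_chunk = FALSE) {
  if (drop_chunk) df$chunk <- NULL
  df <- df[do.call(order, unname(as.list(df))), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# retention oracle for the reduce rule: a record is retained iff it does
# not conflict with any retained record of higher priority, where priority
# is (-score, r_start, strand, q_start) and conflict is same-strand overlap
# exceeding the redundancy fraction of the shorter interval.  Computed by
# explicit enumeration over all subsets (the unique fixpoint).
reduce_oracle <- function(group, frac) {
  key <- paste(group$query, group$strand, group$q_start, group$q_end,
               group$r_start, group$r_end, group$score, group$ops)
  group <- group[!duplicated(key), , drop = FALSE]
  n <- nrow(group)
  prio <- order(-group$score, group$r_start, group$strand, group$q_start)
  conflicts <- function(i, j) {
    if (group$strand[i] != group$strand[j]) return(FALSE)
    ov <- min(group$r_end[i], group$r_end[j]) -
      max(group$r_start[i], group$r_start[j])
    if (ov <= 0) return(FALSE)
    shorter <- min(group$r_end[i] - group$r_start[i],
                   group$r_end[j] - group$r_start[j])
    shorter <= 0 || ov > frac * shorter
  }
  best <- NULL
  for (mask in 0:(2^n - 1L)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    ok <- TRUE
    for (r in seq_len(n)) {
      higher <- prio[seq_len(which(prio == r) - 1L)]
      conflicted <- any(vapply(intersect(higher, S), conflicts,
                               logical(1L), i = r))
      if ((r %in% S) == conflicted) { ok <- FALSE; break }
    }
    if (ok) { best <- S; break }
  }
  out <- group[sort(best), , drop = FALSE]
  out <- out[order(out$r_start, -out$score, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# small record data frame for reduce tests
rec_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    alignment_record(query = r$query %||% "q", q_start = r$q_start %||% 0L,
                     q_end = r$q_end %||% (r$r_end - r$r_start),
                     q_len = r$q_len %||% 100L, ref = "ref",
                     r_start = r$r_start, r_end = r$r_end,
                     strand = r$strand %||% "+", score = r$score,
                     ops = r$ops %||% paste0(r$r_end - r$r_start, "M"),
                     chunk = r$chunk %||% 0L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
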