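# Seed-and-extend long-read alignment: the seeding dynamic programme over
# PrefixDawg(query) x implicit prefix trie(reference), expansion of seed
# interval pairs into concrete seeds via the suffix array, and local
# Smith-Waterman extension of seeds into alignment records.

# symbol codes (1..26) actually present in an indexed text, derived from
# the cumulative counts; the DP only ever extends by these.
present_symbols <- function(index) {
  freq <- diff(c(index$counts, index$n))
  codes <- which(freq > 0L) - 1L            # 0-based symbol codes
  as.integer(codes[codes > 0L])             # drop the sentinel
}

#' Seeding dynamic programme over DAWG and prefix trie
#'
#' Computes, for pairs of (query-DAWG node, reference trie node), the best
#' affine-gap score `E` between any substring of the node's class and the
#' reference substring of the trie node, visiting DAWG nodes in reverse
#' postorder and expanding trie nodes lazily by backward extension.  States
#' whose best score is not positive are discarded.  A seed interval pair is
#' recorded where `E >= min_seed_score` and the trie interval is at most
#' `max_interval_width` wide.
#'
#' @param dawg a [build_prefix_dawg()] of the query chunk.
#' @param index a [build_fm_index()] of the reference chunk.
#' @param scheme a [sw_scheme()].
#' @param params a [seed_params()].
#' @return A data frame of seed interval pairs (class `seed_pairs`) with
#'   columns `node`, `lo`, `hi`, `score`, `q_len`, `r_len`, and attribute
#'   `best_score`: the best `E` over *all* retained states (independent of
#'   the pair thresholds; with the heuristics disabled this equals the best
#'   local Smith-Waterman score between query and reference).
#' @examples
#' dg <- build_prefix_dawg("ANA")
#' fm <- build_fm_index("BANANA$")
#' pr <- bwasw_dp(dg, fm, sw_scheme(), seed_params(max_interval_width = Inf))
#' attr(pr, "best_score")
#' @export
bwasw_dp <- function(dawg, index, scheme = sw_scheme(),
                     params = seed_params()) {
  stopifnot(inherits(dawg, "prefix_dawg"), inherits(index, "fm_index"),
            inherits(scheme, "sw_scheme"), inherits(params, "seed_params"))
  res <- bwasw_dp_cpp(dawg, index$counts, index$occ, index$n,
                      present_symbols(index), scheme$match, scheme$mismatch,
                      scheme$gap_open, scheme$gap_extend, scheme$special_n,
                      params$max_interval_width, params$min_seed_score,
                      params$seed_x_drop, collect_pairs = TRUE)
  pairs <- as.data.frame(res$pairs)
  class(pairs) <- c("seed_pairs", "data.frame")
  attr(pairs, "best_score") <- res$best_score
  pairs
}

#' Expand seed interval pairs into concrete seeds
#'
#' Each pair contributes one candidate seed per (reference position from
#' [locate()] on its interval) x (query start position of its DAWG node's
#' class); duplicates on `(q_pos, r_pos)` collapse to the best-scoring
#' (then longest) seed.
#'
#' @param pairs a `seed_pairs` data frame from [bwasw_dp()].
#' @param index the `fm_index` the pairs were computed against.
#' @param dawg the `prefix_dawg` the pairs were computed against.
#' @return A data frame of seeds: `q_pos`, `r_pos` (0-based starts),
#'   `q_len`, `r_len` (spans on each sequence), `score`.
#' @export
seeds_from_pairs <- function(pairs, index, dawg) {
  stopifnot(inherits(index, "fm_index"), inherits(dawg, "prefix_dawg"))
  if (nrow(pairs) == 0L)
    return(data.frame(q_pos = integer(0), r_pos = integer(0),
                      q_len = integer(0), r_len = integer(0),
                      score = integer(0)))
  as.data.frame(seeds_from_pairs_cpp(pairs$node, pairs$lo, pairs$hi,
                                     pairs$score, pairs$q_len, pairs$r_len,
                                     index$sa, dawg))
}

#' Extend one seed into an alignment record
#'
#' Runs local Smith-Waterman on windows of `params$extension_window` bases
#' flanking the seed on both sequences (clipped at the chunk boundaries)
#' and reports a record only when the alignment score reaches
#' `params$min_report_score`.  Record coordinates are translated back to
#' chunk coordinates.
#'
#' @param seed one-row data frame (or list) with `q_pos`, `r_pos`, `q_len`,
#'   `r_len`.
#' @param q_chunk,r_chunk the query and reference chunk residues.
#' @param scheme a [sw_scheme()].
#' @param params a [seed_params()].
#' @param query_id,ref_name identifiers carried into the record.
#' @return A one-row alignment record data frame, or `NULL` when the
#'   extension scores below the reporting threshold.
#' @export
extend_seed <- function(seed, q_chunk, r_chunk, scheme = sw_scheme(),
                        params = seed_params(), query_id = "query",
                        ref_name = "ref") {
  W <- params$extension_window
  qn <- nchar(q_chunk); rn <- nchar(r_chunk)
  repeat {
    q0s <- max(0L, seed$q_pos - W)
    q0e <- min(qn, seed$q_pos + seed$q_len + W)
    r0s <- max(0L, seed$r_pos - W)
    r0e <- min(rn, seed$r_pos + seed$r_len + W)
    aln <- sw_align_cpp(substr(q_chunk, q0s + 1L, q0e),
                        substr(r_chunk, r0s + 1L, r0e),
                        scheme$match, scheme$mismatch, scheme$gap_open,
                        scheme$gap_extend, scheme$special_n,
                        wavefront = FALSE, lanes = 1L)
    # if the local alignment runs into a window edge that is not a chunk
    # boundary the window was too small: double it and re-extend
    clipped <-
      (aln$q0_interval[1L] == 0L && q0s > 0L) ||
      (aln$q0_interval[2L] == q0e - q0s && q0e < qn) ||
      (aln$q1_interval[1L] == 0L && r0s > 0L) ||
      (aln$q1_interval[2L] == r0e - r0s && r0e < rn)
    if (!clipped || W >= max(qn, rn)) break
    W <- 2L * W
  }
  if (aln$score < params$min_report_score) return(NULL)
  alignment_record(query = query_id,
                   q_start = q0s + aln$q0_interval[1L],
                   q_end = q0s + aln$q0_interval[2L],
                   q_len = qn,
                   ref = ref_name,
                   r_start = r0s + aln$q1_interval[1L],
                   r_end = r0s + aln$q1_interval[2L],
                   strand = "+", score = aln$score, ops = aln$ops)
}

# collapse collinear seeds: a long shared substring produces a qualifying
# seed at every depth along one diagonal, and indels shift the diagonals
# of consecutive anchors of one locus by a few positions; extending each
# is redundant because the extension windows coincide.  Cluster seeds
# whose diagonals fall within a narrow band and whose query spans lie
# within one extension window, and keep one representative per cluster
# (the longest, then the leftmost).
collapse_seeds <- function(seeds, window, band = 32L) {
  one_pass <- function(s, tol) {
    if (nrow(s) <= 1L) return(s)
    diag <- s$r_pos - s$q_pos
    ord <- order(diag, s$q_pos)
    s <- s[ord, , drop = FALSE]
    diag <- diag[ord]
    keep <- logical(nrow(s))
    i <- 1L
    while (i <= nrow(s)) {
      j <- i
      while (j < nrow(s) && diag[j + 1L] - diag[j] <= tol &&
             s$q_pos[j + 1L] - s$q_pos[j] <= window) j <- j + 1L
      grp <- i:j
      best <- grp[order(-s$q_len[grp], s$q_pos[grp])][1L]
      keep[best] <- TRUE
      i <- j + 1L
    }
    s[keep, , drop = FALSE]
  }
  seeds <- one_pass(seeds, 0L)      # same-diagonal chains
  one_pass(seeds, as.integer(band)) # near-diagonal anchors of one locus
}

#' Align a long read against a reference chunk
#'
#' The full seed-and-extend composition: build the prefix DAWG of the
#' query chunk, run the seeding dynamic programme against the reference
#' index, expand seed interval pairs into seeds, and extend seeds by local
#' Smith-Waterman.  With `both_strands` the reverse complement of the
#' query is aligned as well and its records are flagged `-`, with query
#' coordinates mapped back to the original read frame.
#'
#' @param q_chunk,r_chunk query and reference chunk residues (character
#'   scalars, uppercase).
#' @param scheme a [sw_scheme()].
#' @param params a [seed_params()].
#' @param both_strands also align the reverse complement (default `TRUE`).
#' @param query_id,ref_name identifiers carried into the records.
#' @param index optional pre-built `fm_index` of `r_chunk` (it is built on
#'   the fly otherwise).
#' @return An alignment record data frame sorted by `(r_start, -score)`;
#'   may have zero rows.
#' @examples
#' ref <- strrep("ACGT", 30)
#' aln <- align_long_read(substr(ref, 41, 80), ref,
#'                        params = seed_params(min_report_score = 20))
#' @export
align_long_read <- function(q_chunk, r_chunk, scheme = sw_scheme(),
                            params = seed_params(), both_strands = TRUE,
                            query_id = "query", ref_name = "ref",
                            index = NULL) {
  if (!is.character(q_chunk) || nchar(q_chunk) == 0L ||
      !is.character(r_chunk) || nchar(r_chunk) == 0L)
    stop("chunks must be nonempty character scalars")
  if (is.null(index))
    index <- build_fm_index(paste0(r_chunk, SENTINEL), name = ref_name)
  strands <- if (both_strands) c("+", "-") else "+"
  out <- list()
  qn <- nchar(q_chunk)
  for (strand in strands) {
    qs <- if (strand == "+") q_chunk else revcomp(q_chunk)
    dawg <- build_prefix_dawg(qs)
    pairs <- bwasw_dp(dawg, index, scheme, params)
    seeds <- seeds_from_pairs(pairs, index, dawg)
    seeds <- collapse_seeds(seeds, params$extension_window)
    if (nrow(seeds) == 0L) next
    recs <- lapply(seq_len(nrow(seeds)), function(i)
      extend_seed(seeds[i, ], qs, r_chunk, scheme, params,
                  query_id = query_id, ref_name = ref_name))
    recs <- do.call(rbind, recs[!vapply(recs, is.null, logical(1L))])
    if (is.null(recs) || nrow(recs) == 0L) next
    if (strand == "-") {
      # map query coordinates from the reverse-complement frame back to
      # the original read frame; ops stay in reference orientation
      qs_start <- qn - recs$q_end
      qs_end <- qn - recs$q_start
      recs$q_start <- qs_start
      recs$q_end <- qs_end
      recs$strand <- "-"
    }
    out[[strand]] <- recs
  }
  recs <- do.call(rbind, out)
  if (is.null(recs))
    return(empty_records())
  recs <- unique(recs)
  recs <- recs[order(recs$r_start, -recs$score, recs$q_start,
                     recs$strand), , drop = FALSE]
  rownames(recs) <- NULL
  recs
}
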