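# Prefix DAWG of the query: the minimal automaton accepting exactly the
# substrings of the query, obtained by collapsing prefix-trie nodes that
# share a suffix-array interval.  Transitions prepend symbols (trie
# navigation direction), so structurally this is the suffix automaton of
# the reversed query; the state count is bounded by 2|Q|.

#' Build the prefix DAWG of a query sequence
#'
#' Nodes are equivalence classes of query substrings with identical
#' suffix-array intervals in the query's own index (equivalently, identical
#' start-position sets).  The object carries, per node: the class's longest
#' substring length (`len`), symbol-labelled transitions, parent sets, a
#' reverse-postorder listing in which every parent precedes every child
#' (the traversal order of the seeding dynamic programme), and the node's
#' suffix-array interval in the query's own FM-index.
#'
#' @param query character scalar, nonempty and sentinel-free.
#' @return An object of class `prefix_dawg`.
#' @examples
#' dg <- build_prefix_dawg("BANANA")
#' dawg_accepts(dg, "ANA")
#' dawg_accepts(dg, "NN")
#' @export
build_prefix_dawg <- function(query) {
  if (!is.character(query) || length(query) != 1L || is.na(query) ||
      nchar(query) == 0L)
    stop("query must be a nonempty character string")
  query <- toupper(query)
  if (grepl("\\$", query)) stop("query must be sentinel-free")
  dg <- build_dawg_cpp(query)
  qfm <- build_fm_cpp(paste0(query, SENTINEL))
  dg$intervals <- dawg_intervals_cpp(dg, qfm$counts, qfm$occ, query)
  dg$query <- query
  class(dg) <- "prefix_dawg"
  dg
}

#' @export
print.prefix_dawg <- function(x, ...) {
  cat(sprintf("<prefix_dawg> query of length %d, %d nodes (bound %d)\n",
              x$query_len, x$n_nodes, 2L * x$query_len))
  invisible(x)
}

#' Does the prefix DAWG accept a string?
#'
#' Acceptance means `s` is a substring of the query.  Transitions prepend
#' symbols, so the automaton consumes `s` right-to-left.
#' @param dawg a `prefix_dawg`.
#' @param s character scalar.
#' @return logical scalar.
#' @export
dawg_accepts <- function(dawg, s) {
  stopifnot(inherits(dawg, "prefix_dawg"))
  if (!is.character(s) || length(s) != 1L) stop("s must be a character scalar")
  if (nchar(s) == 0L) return(TRUE)
  dawg_accepts_cpp(dawg, toupper(s))
}

#' Start positions represented by a DAWG node
#'
#' All substrings in one node's equivalence class share the same set of
#' start positions in the query; this returns that set (0-based, sorted).
#' @param dawg a `prefix_dawg`.
#' @param node 0-based node id (0 is the root).
#' @return sorted integer vector of query start positions.
#' @export
dawg_positions <- function(dawg, node) {
  stopifnot(inherits(dawg, "prefix_dawg"))
  dawg_positions_cpp(dawg, as.integer(node))
}
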