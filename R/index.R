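# Text indexes: suffix array, BWT and FM-index over the sentinel-terminated
# text.  The reference prefix trie is never materialised: a trie node is a
# suffix-array interval and child navigation is backward extension.

#' Build the suffix array of a sentinel-terminated text
#'
#' Positions (0-based) of all suffixes of `text`, in lexicographic order of
#' the suffixes; the sentinel `$` collates strictly below every residue.
#'
#' @param text character scalar of uppercase letters terminated by `$`
#'   (DNA in real use; any of `A`--`Z` is indexable, which keeps the classic
#'   worked examples such as `"BANANA$"` available).
#' @return integer vector, a permutation of `0:(nchar(text) - 1)`.
#' @examples
#' build_suffix_array("BANANA$")
#' @export
build_suffix_array <- function(text) {
  check_indexable(text)
  build_suffix_array_cpp(toupper(text))
}

check_indexable <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("text must be a single character string")
  if (nchar(text) < 1L || substr(text, nchar(text), nchar(text)) != SENTINEL)
    stop("text must be terminated by the '$' sentinel")
  invisible(text)
}

#' Build an FM-index
#'
#' Suffix array, Burrows-Wheeler transform, cumulative symbol counts and a
#' per-position occurrence table for a sentinel-terminated text.  Together
#' these implicitly represent the text's prefix trie: every trie node is a
#' suffix-array interval and [backward_extend()] navigates to a child.
#'
#' @param text character scalar over A/C/G/T/N terminated by `$`.
#' @param name optional sequence name carried along for output.
#' @return An object of class `fm_index` with fields `n`, `sa`, `bwt`,
#'   `counts`, `occ` and `text`.
#' @examples
#' fm <- build_fm_index("ACGTACGT$")
#' fm$bwt
#' @export
build_fm_index <- function(text, name = NULL) {
  check_indexable(text)
  text <- toupper(text)
  fm <- build_fm_cpp(text)
  structure(list(name = name, text = text, n = fm$n, sa = fm$sa,
                 bwt = fm$bwt, counts = fm$counts, occ = fm$occ),
            class = "fm_index")
}

#' @export
print.fm_index <- function(x, ...) {
  cat(sprintf("<fm_index> %stext of length %d (incl. sentinel)\n",
              if (is.null(x$name)) "" else paste0("'", x$name, "', "), x$n))
  invisible(x)
}

#' The suffix-array interval of the whole index
#'
#' The root of the implicit prefix trie: the interval `[0, n)` representing
#' the empty string.
#' @param index an `fm_index`.
#' @return integer vector `c(lo, hi)` (half-open ranks).
#' @export
full_interval <- function(index) {
  stopifnot(inherits(index, "fm_index"))
  c(0L, index$n)
}

check_interval <- function(index, interval) {
  if (!is.numeric(interval) || length(interval) != 2L ||
      anyNA(interval))
    stop("interval must be an integer vector c(lo, hi)")
  interval <- as.integer(interval)
  if (interval[1L] < 0L || interval[2L] > index$n ||
      interval[1L] > interval[2L])
    stop("interval out of range for this index")
  interval
}

#' Backward extension: prepend a symbol to an indexed string
#'
#' Given the interval of a string `s`, returns the interval of `symbol . s`.
#' The width of the result equals the occurrence count of the extended
#' string; an empty interval (`lo == hi`) means the extended string does not
#' occur.  This is child navigation in the implicit prefix trie.
#'
#' @param index an `fm_index`.
#' @param interval integer `c(lo, hi)`, a valid interval for `index`.
#' @param symbol single character in A/C/G/T/N (or `$`).
#' @return integer `c(lo, hi)`.
#' @examples
#' fm <- build_fm_index("ACACAG$")
#' iv <- backward_extend(fm, full_interval(fm), "C")
#' backward_extend(fm, iv, "A") # interval of "AC", width 2
#' @export
backward_extend <- function(index, interval, symbol) {
  stopifnot(inherits(index, "fm_index"))
  interval <- check_interval(index, interval)
  if (!is.character(symbol) || nchar(symbol) != 1L)
    stop("symbol must be a single character")
  if (!symbol %in% c(DNA_ALPHABET, SENTINEL))
    stop(sprintf("illegal symbol '%s' (alphabet is A/C/G/T/N + '$')", symbol))
  backward_extend_cpp(index$counts, index$occ, interval[1L], interval[2L],
                      symbol)
}

#' Backward search of a whole string
#'
#' Convenience composition of [backward_extend()] over the symbols of `s`,
#' right to left.
#' @param index an `fm_index`.
#' @param s character scalar.
#' @return integer `c(lo, hi)`; empty interval if `s` does not occur.
#' @export
backward_search <- function(index, s) {
  iv <- full_interval(index)
  if (nchar(s) == 0L) return(iv)
  for (i in rev(seq_len(nchar(s)))) {
    iv <- backward_extend(index, iv, substr(s, i, i))
    if (iv[2L] <= iv[1L]) return(iv)
  }
  iv
}

#' Locate the text positions of an interval
#'
#' @param index an `fm_index`.
#' @param interval integer `c(lo, hi)`.
#' @return sorted integer vector of 0-based text positions; length equals
#'   the interval width.
#' @examples
#' fm <- build_fm_index("ACACAG$")
#' locate(fm, backward_search(fm, "AC"))
#' @export
locate <- function(index, interval) {
  stopifnot(inherits(index, "fm_index"))
  interval <- check_interval(index, interval)
  if (interval[2L] <= interval[1L]) return(integer(0))
  sort(index$sa[(interval[1L] + 1L):interval[2L]])
}

#' Reconstruct the text from its BWT by LF-mapping
#'
#' Walks the last-to-first mapping from the sentinel row; on a valid index
#' this reproduces the original text exactly (an FM-index invariant used by
#' the test-suite and by [read_index()] to avoid storing the text).
#' @param index an `fm_index`.
#' @return the reconstructed text (character scalar).
#' @export
lf_reconstruct <- function(index) {
  stopifnot(inherits(index, "fm_index"))
  lf_reconstruct_cpp(index$bwt, index$counts)
}
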