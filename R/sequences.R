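# Sequences are plain uppercase character scalars over A/C/G/T/N, optionally
# carrying a name attribute; the '$' sentinel is appended only for indexing.

#' Validate a DNA sequence
#'
#' @param x character scalar of residues.
#' @param sentinel `"forbid"` (default), `"require"` (must end in exactly one
#'   terminal `$`) or `"allow"`.
#' @param allow_empty allow the empty string.
#' @return `x`, invisibly, or an error describing the violation.
#' @export
check_sequence <- function(x, sentinel = c("forbid", "require", "allow"),
                           allow_empty = FALSE) {
  sentinel <- match.arg(sentinel)
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("sequence must be a single character string")
  body <- x
  if (sentinel != "forbid") {
    has <- grepl("\\$$", x)
    if (sentinel == "require" && !has)
      stop("sequence must be terminated by the '$' sentinel")
    if (has) body <- substr(x, 1L, nchar(x) - 1L)
  }
  if (!allow_empty && nchar(body) == 0L)
    stop("sequence must be nonempty")
  if (grepl("\\$", body, fixed = FALSE))
    stop("sentinel '$' may only appear once, at the end")
  if (nchar(body) > 0L && grepl("[^ACGNT]", body)) {
    bad <- regmatches(body, regexpr("[^ACGNT]", body))
    stop(sprintf("illegal symbol '%s' (alphabet is A/C/G/T/N)", bad))
  }
  invisible(x)
}

#' Append the terminal sentinel to a sequence
#' @param x residues without a sentinel.
#' @return `x` with `$` appended.
#' @export
add_sentinel <- function(x) {
  check_sequence(x, sentinel = "forbid")
  paste0(x, SENTINEL)
}

#' Reverse complement
#'
#' Wraps [Biostrings::reverseComplement()]; `N` maps to `N`.
#'
#' @param x character scalar over A/C/G/T/N.
#' @return the reverse complement, as a character scalar.
#' @export
revcomp <- function(x) {
  check_sequence(x, sentinel = "forbid", allow_empty = TRUE)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# uniform random DNA, used by examples and the simulator
random_dna <- function(n, base_prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = base_prob),
        collapse = "")
}

# run a block under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
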