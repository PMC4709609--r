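# Affine-gap local alignment.  Z holds the similarity scores with its first
# row and column fixed at 0 and every cell floored at 0; I and J are the two
# gap matrices (I consumes the second sequence only, J the first) held at an
# impossible value on the boundary.  Two fill orders are provided: the
# classic serial row-major order and the wavefront order that computes all
# cells of one anti-diagonal together, each anti-diagonal split into `lanes`
# contiguous blocks.  Both produce bit-identical matrices.

check_sw_seq <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(sprintf("%s must be a single character string", what))
  x <- toupper(x)
  if (grepl("[^A-Z]", x))
    stop(sprintf("%s contains symbols outside 'A'..'Z'", what))
  x
}

sw_matrices <- function(fill, q0, q1, scheme) {
  structure(list(Z = fill$Z, I = fill$I, J = fill$J,
                 best_score = fill$best_score, best_cell = fill$best_cell,
                 q0 = q0, q1 = q1, scheme = scheme),
            class = "sw_matrices")
}

#' Serial Smith-Waterman matrix fill
#'
#' Fills the similarity matrix `Z` and the two affine gap matrices `I`, `J`
#' row by row.  `Z` has size `(nchar(q0) + 1) x (nchar(q1) + 1)`; its first
#' row and column are 0 and every cell is non-negative.  `best_cell` is the
#' position of the maximum of `Z` (as prefix lengths, i.e. 0-based matrix
#' coordinates), the smallest `(row, column)` among ties.
#'
#' @param q0,q1 sentinel-free sequences (character scalars).
#' @param scheme a [sw_scheme()].
#' @return An object of class `sw_matrices` with fields `Z`, `I`, `J`,
#'   `best_score`, `best_cell`.
#' @examples
#' m <- sw_fill_serial("AAAG", "AAAT", sw_scheme(1, -1, 2, 1))
#' m$best_score
#' @export
sw_fill_serial <- function(q0, q1, scheme = sw_scheme()) {
  stopifnot(inherits(scheme, "sw_scheme"))
  q0 <- check_sw_seq(q0, "q0")
  q1 <- check_sw_seq(q1, "q1")
  sw_matrices(sw_fill_cpp(q0, q1, scheme$match, scheme$mismatch,
                          scheme$gap_open, scheme$gap_extend,
                          scheme$special_n, wavefront = FALSE, lanes = 1L),
              q0, q1, scheme)
}

#' Wavefront (anti-diagonal) Smith-Waterman matrix fill
#'
#' Computes the same matrices as [sw_fill_serial()] by walking
#' anti-diagonals: every cell of one anti-diagonal depends only on the two
#' preceding anti-diagonals, so the cells of a diagonal are independent and
#' are dealt to `lanes` contiguous blocks, executed block by block in a
#' cache-friendly banded sweep.  The result is bit-identical to the serial
#' fill for every `lanes` value.
#'
#' @inheritParams sw_fill_serial
#' @param lanes positive integer number of blocks per anti-diagonal.
#' @return An object of class `sw_matrices`.
#' @export
sw_fill_wavefront <- function(q0, q1, scheme = sw_scheme(), lanes = 2L) {
  stopifnot(inherits(scheme, "sw_scheme"))
  lanes <- as.integer(lanes)
  if (is.na(lanes) || lanes < 1L) stop("lanes must be a positive integer")
  q0 <- check_sw_seq(q0, "q0")
  q1 <- check_sw_seq(q1, "q1")
  sw_matrices(sw_fill_cpp(q0, q1, scheme$match, scheme$mismatch,
                          scheme$gap_open, scheme$gap_extend,
                          scheme$special_n, wavefront = TRUE, lanes = lanes),
              q0, q1, scheme)
}

#' @export
print.sw_matrices <- function(x, ...) {
  cat(sprintf("<sw_matrices> %d x %d, best score %d at (%d, %d)\n",
              nrow(x$Z), ncol(x$Z), x$best_score, x$best_cell[1L],
              x$best_cell[2L]))
  invisible(x)
}

#' Backtrack an optimal local alignment
#'
#' Starts from the best cell of `Z` and walks back until a zero cell,
#' with deterministic tie-breaking (diagonal over vertical over
#' horizontal; gap closure over gap extension).
#'
#' @param m an `sw_matrices` from one of the fill functions.
#' @param q0,q1 the sequences the matrices were filled from.
#' @param scheme the scheme the matrices were filled with.
#' @return An object of class `sw_alignment`: `q0_interval` and
#'   `q1_interval` (0-based half-open), `ops` (run-length encoded
#'   `M`/`I`/`D`, `I` consuming `q0` only), and `score`.  A best score of 0
#'   yields an empty alignment.
#' @export
sw_backtrack <- function(m, q0 = m$q0, q1 = m$q1, scheme = m$scheme) {
  stopifnot(inherits(m, "sw_matrices"), inherits(scheme, "sw_scheme"))
  q0 <- check_sw_seq(q0, "q0")
  q1 <- check_sw_seq(q1, "q1")
  bt <- sw_backtrack_cpp(m$Z, m$I, m$J, q0, q1, scheme$match,
                         scheme$mismatch, scheme$gap_open, scheme$gap_extend,
                         scheme$special_n)
  structure(bt, class = "sw_alignment")
}

#' Local alignment in one call
#'
#' Facade over fill + backtrack.
#'
#' @inheritParams sw_fill_serial
#' @param mode `"serial"` or `"wavefront"`.
#' @param lanes lane count for the wavefront mode.
#' @return An `sw_alignment` (see [sw_backtrack()]).
#' @examples
#' sw_align("ACGTACGT", "ACGTTTTACGT", sw_scheme(2, -3, 2, 1))
#' @export
sw_align <- function(q0, q1, scheme = sw_scheme(),
                     mode = c("serial", "wavefront"), lanes = 2L) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "sw_scheme"))
  lanes <- as.integer(lanes)
  if (is.na(lanes) || lanes < 1L) stop("lanes must be a positive integer")
  q0 <- check_sw_seq(q0, "q0")
  q1 <- check_sw_seq(q1, "q1")
  bt <- sw_align_cpp(q0, q1, scheme$match, scheme$mismatch, scheme$gap_open,
                     scheme$gap_extend, scheme$special_n,
                     wavefront = mode == "wavefront", lanes = lanes)
  structure(bt, class = "sw_alignment")
}

#' @export
print.sw_alignment <- function(x, ...) {
  cat(sprintf("<sw_alignment> score %d, q0 [%d, %d), q1 [%d, %d), ops %s\n",
              x$score, x$q0_interval[1L], x$q0_interval[2L],
              x$q1_interval[1L], x$q1_interval[2L],
              if (nzchar(x$ops)) x$ops else "(empty)"))
  invisible(x)
}

#' Expand a run-length operation string
#'
#' `"3M1D2M"` becomes `c("M","M","M","D","M","M")`.
#' @param ops run-length encoded operation string over `M`, `I`, `D`
#'   (and `S` in SAM output).
#' @return character vector of single operations.
#' @export
expand_ops <- function(ops) {
  if (!nzchar(ops)) return(character(0))
  lens <- as.integer(regmatches(ops, gregexpr("[0-9]+", ops))[[1L]])
  kinds <- regmatches(ops, gregexpr("[A-Z]", ops))[[1L]]
  if (length(lens) != length(kinds)) stop("malformed ops string: ", ops)
  rep(kinds, lens)
}

#' Re-score an alignment under a scoring scheme
#'
#' Walks the edit operations over the aligned slices and recomputes the
#' score; used to verify that reported scores are consistent with their
#' operations.
#'
#' @param ops run-length operation string (`M`/`I`/`D`).
#' @param q0_sub,q1_sub the aligned slices of the two sequences.
#' @param scheme a [sw_scheme()].
#' @return integer score.
#' @export
rescore_ops <- function(ops, q0_sub, q1_sub, scheme = sw_scheme()) {
  v <- expand_ops(ops)
  i <- 0L; j <- 0L; score <- 0L
  prev <- "M"  # a gap run is a maximal run of the same op kind
  for (op in v) {
    if (op == "M") {
      i <- i + 1L; j <- j + 1L
      a <- substr(q0_sub, i, i); b <- substr(q1_sub, j, j)
      hit <- a == b && !(scheme$special_n && a == "N")
      score <- score + if (hit) scheme$match else scheme$mismatch
    } else if (op == "I") {
      i <- i + 1L
      score <- score - if (prev == "I") scheme$gap_extend else scheme$gap_open
    } else if (op == "D") {
      j <- j + 1L
      score <- score - if (prev == "D") scheme$gap_extend else scheme$gap_open
    } else stop("unknown op: ", op)
    prev <- op
  }
  if (i != nchar(q0_sub) || j != nchar(q1_sub))
    stop("ops do not consume the aligned slices exactly")
  score
}
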