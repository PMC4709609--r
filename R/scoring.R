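#' Scoring scheme for affine-gap alignment
#'
#' One scheme serves both the Smith-Waterman matrices and the seeding
#' dynamic programme: a positive match reward, a negative mismatch penalty
#' and two-level affine gap costs in which the first gapped column costs
#' `gap_open` and every further column of the same gap costs `gap_extend`
#' (a length-k gap therefore costs `gap_open + (k - 1) * gap_extend`).
#' By default `N` never matches positively; it is always scored as a
#' mismatch (see `special_n`).
#'
#' Defaults follow the usual long-read seed-and-extend settings:
#' match +1, mismatch -3, gap open 5, gap extend 2.
#'
#' @param match positive integer match score.
#' @param mismatch negative integer mismatch score.
#' @param gap_open positive integer cost of the first gapped column.
#' @param gap_extend positive integer cost of each further gapped column;
#'   must not exceed `gap_open`.
#' @param special_n score `N` as a mismatch even against another `N`
#'   (default `TRUE`, the DNA ambiguity semantics).  Set `FALSE` to treat
#'   `N` as an ordinary letter, e.g. for the classic non-DNA worked
#'   examples.
#' @return An object of class `sw_scheme`.
#' @examples
#' sw_scheme()
#' sw_scheme(match = 2, mismatch = -1, gap_open = 3, gap_extend = 1)
#' @export
sw_scheme <- function(match = 1L, mismatch = -3L, gap_open = 5L,
                      gap_extend = 2L, special_n = TRUE) {
  match <- as.integer(match)
  mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open)
  gap_extend <- as.integer(gap_extend)
  stopifnot(length(match) == 1L, length(mismatch) == 1L,
            length(gap_open) == 1L, length(gap_extend) == 1L)
  if (is.na(match) || match <= 0L) stop("match score must be > 0")
  if (is.na(mismatch) || mismatch >= 0L) stop("mismatch score must be < 0")
  if (is.na(gap_extend) || gap_extend <= 0L)
    stop("gap_extend must be > 0")
  if (is.na(gap_open) || gap_open < gap_extend)
    stop("gap_open must be >= gap_extend")
  if (!is.logical(special_n) || length(special_n) != 1L || is.na(special_n))
    stop("special_n must be TRUE or FALSE")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, special_n = special_n),
            class = "sw_scheme")
}

#' @export
print.sw_scheme <- function(x, ...) {
  cat(sprintf(
    "<sw_scheme> match %+d, mismatch %+d, gap open %d, gap extend %d\n",
    x$match, x$mismatch, x$gap_open, x$gap_extend))
  invisible(x)
}

#' Seeding and reporting thresholds
#'
#' Controls which states of the seeding dynamic programme become seed
#' interval pairs and how seeds are extended into reported alignments.
#'
#' @param max_interval_width a seed interval pair is only formed when the
#'   suffix-array interval of the reference-side node is at most this wide
#'   (i.e. the matched reference substring occurs at most this many times).
#'   Use `Inf` to disable the width heuristic.
#' @param min_seed_score minimum seeding score `E` for a seed interval
#'   pair.  The default (20 with the default match score) demands an
#'   anchor worth at least twenty matched bases; spurious anchors of that
#'   strength are essentially absent from desk-scale references, while
#'   real loci produce many.
#' @param extension_window flanking length, in bases, of the local
#'   Smith-Waterman window placed around a seed on both sequences.
#' @param min_report_score minimum Smith-Waterman score of a reported
#'   alignment record.
#' @param seed_x_drop X-drop pruning of the seeding dynamic programme: a
#'   state whose score falls more than this far below a perfect match of
#'   its own query depth is dropped.  `Inf` disables the heuristic (the
#'   seeding scores are then exact).
#' @return An object of class `seed_params`.
#' @examples
#' seed_params()
#' seed_params(max_interval_width = Inf, min_seed_score = 1e-9,
#'             seed_x_drop = Inf)
#' @export
seed_params <- function(max_interval_width = 3, min_seed_score = 20,
                        extension_window = 100L, min_report_score = 30L,
                        seed_x_drop = 16) {
  if (!is.numeric(max_interval_width) || max_interval_width <= 0)
    stop("max_interval_width must be positive")
  if (!is.numeric(min_seed_score) || min_seed_score <= 0)
    stop("min_seed_score must be positive")
  if (!is.numeric(seed_x_drop) || seed_x_drop <= 0)
    stop("seed_x_drop must be positive")
  extension_window <- as.integer(extension_window)
  min_report_score <- as.integer(min_report_score)
  if (extension_window <= 0L) stop("extension_window must be positive")
  if (min_report_score <= 0L) stop("min_report_score must be positive")
  structure(list(max_interval_width = max_interval_width,
                 min_seed_score = min_seed_score,
                 extension_window = extension_window,
                 min_report_score = min_report_score,
                 seed_x_drop = seed_x_drop),
            class = "seed_params")
}

#' @export
print.seed_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<seed_params> interval width <= %s, seed score >= %s,\n",
    "  extension window %d, report score >= %d\n"),
    format(x$max_interval_width), format(x$min_seed_score),
    x$extension_window, x$min_report_score))
  invisible(x)
}
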