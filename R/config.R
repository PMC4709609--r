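# One validated configuration document drives the pipeline and the CLI;
# every field is mirrored by a CLI flag and can come from a YAML or JSON
# file.

#' Pipeline run configuration
#'
#' @param scoring a [sw_scheme()].
#' @param seeding a [seed_params()].
#' @param chunking list: `chunk_len` (reference chunk length, default
#'   100000), `overlap` (default 10000), `q_chunk_len` (`NULL` = do not
#'   split queries), `q_overlap`.
#' @param workers list: `w` map/reduce workers, `p` cores per worker,
#'   `phase_overlap` (reduce may start at the first map completion).
#' @param output list: `both_strands`, `redundancy_fraction`.
#' @param seed RNG seed for any randomized scheduling (`NULL`: none used).
#' @param spill_dir optional directory for per-task JSON-lines spill files
#'   standing in for intermediate cloud storage (`NULL`: in memory).
#' @return object of class `run_config`.
#' @examples
#' cfg <- run_config(workers = list(w = 2))
#' cfg$workers$w
#' @export
run_config <- function(scoring = sw_scheme(), seeding = seed_params(),
                       chunking = list(), workers = list(), output = list(),
                       seed = NULL, spill_dir = NULL) {
  cfg <- list(
    scoring = scoring,
    seeding = seeding,
    chunking = utils::modifyList(
      list(chunk_len = 100000L, overlap = 10000L, q_chunk_len = NULL,
           q_overlap = 0L), chunking),
    workers = utils::modifyList(
      list(w = 1L, p = 1L, phase_overlap = TRUE), workers),
    output = utils::modifyList(
      list(both_strands = TRUE, redundancy_fraction = 0.5), output),
    seed = seed, spill_dir = spill_dir)
  class(cfg) <- "run_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!inherits(cfg, "run_config")) stop("config must be a run_config")
  stopifnot(inherits(cfg$scoring, "sw_scheme"),
            inherits(cfg$seeding, "seed_params"))
  ck <- cfg$chunking
  if (!is.numeric(ck$chunk_len) || ck$chunk_len <= 0)
    stop("chunking$chunk_len must be positive")
  if (!is.numeric(ck$overlap) || ck$overlap < 0 ||
      ck$overlap >= ck$chunk_len)
    stop("chunking$overlap must satisfy 0 <= overlap < chunk_len")
  if (!is.null(ck$q_chunk_len)) {
    if (!is.numeric(ck$q_chunk_len) || ck$q_chunk_len <= 0)
      stop("chunking$q_chunk_len must be positive (or NULL)")
    if (ck$q_overlap < 0 || ck$q_overlap >= ck$q_chunk_len)
      stop("chunking$q_overlap must satisfy 0 <= q_overlap < q_chunk_len")
  }
  wk <- cfg$workers
  if (!is.numeric(wk$w) || wk$w < 1) stop("workers$w must be >= 1")
  if (!is.numeric(wk$p) || wk$p < 1) stop("workers$p must be >= 1")
  if (!is.logical(wk$phase_overlap))
    stop("workers$phase_overlap must be logical")
  ou <- cfg$output
  if (!is.logical(ou$both_strands)) stop("output$both_strands must be logical")
  if (!is.numeric(ou$redundancy_fraction) || ou$redundancy_fraction < 0 ||
      ou$redundancy_fraction > 1)
    stop("output$redundancy_fraction must be in [0, 1]")
  cfg$chunking$chunk_len <- as.integer(cfg$chunking$chunk_len)
  cfg$chunking$overlap <- as.integer(cfg$chunking$overlap)
  cfg$workers$w <- as.integer(cfg$workers$w)
  cfg$workers$p <- as.integer(cfg$workers$p)
  cfg
}

#' Load a run configuration from YAML or JSON
#'
#' Field layout mirrors [run_config()]; unknown fields are rejected with a
#' field-precise message.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a validated `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else if (grepl("\\.json$", path)) jsonlite::read_json(
           path, simplifyVector = TRUE)
         else stop("config file must be .yaml, .yml or .json: ", path)
  known <- c("scoring", "seeding", "chunking", "workers", "output", "seed",
             "spill_dir")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config field(s): ", paste(extra, collapse = ", "))
  sc <- raw$scoring %||% list()
  se <- raw$seeding %||% list()
  check_fields <- function(x, ok, section) {
    bad <- setdiff(names(x), ok)
    if (length(bad))
      stop(sprintf("unknown field(s) in config section '%s': %s", section,
                   paste(bad, collapse = ", ")))
  }
  check_fields(sc, c("match", "mismatch", "gap_open", "gap_extend"),
               "scoring")
  check_fields(se, c("max_interval_width", "min_seed_score",
                     "extension_window", "min_report_score"), "seeding")
  check_fields(raw$chunking %||% list(),
               c("chunk_len", "overlap", "q_chunk_len", "q_overlap"),
               "chunking")
  check_fields(raw$workers %||% list(), c("w", "p", "phase_overlap"),
               "workers")
  check_fields(raw$output %||% list(),
               c("both_strands", "redundancy_fraction"), "output")
  run_config(
    scoring = do.call(sw_scheme, sc),
    seeding = do.call(seed_params, se),
    chunking = raw$chunking %||% list(),
    workers = raw$workers %||% list(),
    output = raw$output %||% list(),
    seed = raw$seed, spill_dir = raw$spill_dir)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  scoring: match %+d mismatch %+d open %d extend %d\n",
              x$scoring$match, x$scoring$mismatch, x$scoring$gap_open,
              x$scoring$gap_extend))
  cat(sprintf("  chunking: chunk %d overlap %d, query chunk %s\n",
              x$chunking$chunk_len, x$chunking$overlap,
              x$chunking$q_chunk_len %||% "off"))
  cat(sprintf("  workers: w=%d p=%d phase_overlap=%s\n", x$workers$w,
              x$workers$p, x$workers$phase_overlap))
  invisible(x)
}
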