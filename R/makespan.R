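# Makespan accounting.  Each map worker's makespan decomposes into data
# fetch, query split, alignment (the Q' x t_align work spread over p
# cores) and store; each reduce worker's into fetch/shuffle-sort, reduce
# function and store.  Phase aggregates are means over the w workers and
# the total is their sum, with the VM-configuration term identically 0 at
# desk scale.

#' Assemble a makespan report
#'
#' Normally produced by [run_pipeline()]; exposed so synthetic reports can
#' be built in examples and tests.
#'
#' @param map_workers list of per-map-worker term lists (`makespan`,
#'   `t_get`, `t_qi`, `t_align`, `t_store`, `n_tasks`).
#' @param reduce_workers list of per-reduce-worker term lists
#'   (`makespan`, `t_get`, `t_fn`, `t_store`).
#' @param w,p worker and core counts.
#' @param phase_overlap whether the reduce phase was allowed to start at
#'   the first map completion.
#' @param wall_clock elapsed pipeline wall time (seconds).
#' @return object of class `makespan_report`.
#' @export
makespan_report <- function(map_workers, reduce_workers, w = 1L, p = 1L,
                            phase_overlap = TRUE, wall_clock = NA_real_) {
  stopifnot(length(map_workers) >= 1L, length(reduce_workers) >= 1L)
  map_ms <- vapply(map_workers, `[[`, numeric(1L), "makespan")
  red_ms <- vapply(reduce_workers, `[[`, numeric(1L), "makespan")
  structure(list(
    map_workers = map_workers, reduce_workers = reduce_workers,
    t_map = mean(map_ms), t_reduce = mean(red_ms),
    t_vm_config = 0,
    t_total = mean(map_ms) + mean(red_ms),
    # when reduce may start early it begins at the first map-worker
    # completion; otherwise it waits for the slowest one
    reduce_start = if (phase_overlap) min(map_ms) else max(map_ms),
    phase_overlap = phase_overlap, w = w, p = p,
    wall_clock = wall_clock), class = "makespan_report")
}

#' Aggregate a makespan report
#'
#' Recomputes the phase aggregates from the per-worker terms: the map and
#' reduce makespans are the means over the `w` workers and the total is
#' their sum (the VM-configuration term is identically 0 here).  Checks
#' internal consistency: each worker's makespan must be at least the sum
#' of its recorded components (the remainder is scheduling overhead).
#'
#' @param report a `makespan_report`.
#' @return list with `t_map`, `t_reduce`, `t_vm_config`, `t_total`.
#' @examples
#' rep <- makespan_report(
#'   map_workers = list(list(makespan = 2, t_get = 0, t_qi = 0,
#'                           t_align = 2, t_store = 0, n_tasks = 1),
#'                      list(makespan = 4, t_get = 0, t_qi = 0,
#'                           t_align = 4, t_store = 0, n_tasks = 1)),
#'   reduce_workers = list(list(makespan = 1, t_get = 1, t_fn = 0,
#'                              t_store = 0),
#'                         list(makespan = 1, t_get = 1, t_fn = 0,
#'                              t_store = 0)),
#'   w = 2)
#' makespan_summary(rep)  # t_map 3, t_reduce 1, t_total 4
#' @export
makespan_summary <- function(report) {
  stopifnot(inherits(report, "makespan_report"))
  if (length(report$map_workers) == 0L)
    stop("empty makespan report")
  map_ms <- vapply(report$map_workers, `[[`, numeric(1L), "makespan")
  red_ms <- vapply(report$reduce_workers, `[[`, numeric(1L), "makespan")
  t_map <- mean(map_ms)
  t_reduce <- mean(red_ms)
  list(t_map = t_map, t_reduce = t_reduce, t_vm_config = 0,
       t_total = t_map + t_reduce)
}

#' @export
print.makespan_report <- function(x, ...) {
  s <- makespan_summary(x)
  cat(sprintf(paste0(
    "<makespan_report> w=%d map / %d reduce workers, p=%d cores\n",
    "  T_MAP    %.3fs (mean of %s)\n",
    "  T_REDUCE %.3fs\n",
    "  T        %.3fs  (phase overlap %s; reduce start at %.3fs;",
    " wall %.3fs)\n"),
    x$w, length(x$reduce_workers), x$p, s$t_map,
    paste(sprintf("%.3f", vapply(x$map_workers, `[[`, numeric(1L),
                                 "makespan")), collapse = ", "),
    s$t_reduce, s$t_total, if (x$phase_overlap) "on" else "off",
    x$reduce_start, x$wall_clock))
  invisible(x)
}

#' Export a makespan report as JSON
#' @param report a `makespan_report`.
#' @param path output path (or `NULL` to return the JSON string).
#' @return the JSON string, invisibly when written to a file.
#' @export
makespan_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "makespan_report"))
  s <- makespan_summary(report)
  obj <- c(s, list(reduce_start = report$reduce_start,
                   phase_overlap = report$phase_overlap, w = report$w,
                   p = report$p, wall_clock = report$wall_clock,
                   map_workers = report$map_workers,
                   reduce_workers = report$reduce_workers))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
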