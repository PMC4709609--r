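# Local parallel map-reduce execution: overlapping reference chunking,
# map workers running align_long_read, shuffle/sort on reference offsets,
# reduce workers aggregating nonredundant and nonoverlapping alignments,
# with per-worker makespan accounting.  Worker processes on one machine
# stand in for cloud VMs; w map/reduce workers with p cores each are
# configuration values and never change the output.

#' Split a reference into overlapping chunks
#'
#' Chunk `i` starts at `i * (chunk_len - overlap)`; the last chunk ends at
#' the reference end.  Adjacent chunks share exactly `overlap` positions,
#' so any alignment no longer than `overlap` lies wholly inside at least
#' one chunk.
#'
#' @param ref reference residues (character scalar).
#' @param chunk_len chunk length in bases (a chunk longer than the
#'   reference yields a single chunk).
#' @param overlap overlap length; must be smaller than `chunk_len`.
#' @return list of chunk records: `kr` (0-based id), `residues`, `start`,
#'   `end` (0-based half-open global coordinates), `overlap`.
#' @examples
#' ch <- split_reference(strrep("A", 100), 40, 10)
#' vapply(ch, function(x) c(x$start, x$end), integer(2))
#' @export
split_reference <- function(ref, chunk_len, overlap = 0L) {
  chunk_len <- as.integer(chunk_len)
  overlap <- as.integer(overlap)
  n <- nchar(ref)
  if (n == 0L) stop("reference must be nonempty")
  if (chunk_len <= 0L) stop("chunk_len must be positive")
  if (overlap < 0L || overlap >= chunk_len)
    stop("overlap must satisfy 0 <= overlap < chunk_len")
  step <- chunk_len - overlap
  starts <- seq(0L, max(0L, n - 1L), by = step)
  starts <- starts[starts == 0L | starts + overlap < n]
  # drop trailing chunks fully contained in the previous one
  ends <- pmin(starts + chunk_len, n)
  keep <- c(TRUE, ends[-1L] > ends[-length(ends)])
  starts <- starts[keep]; ends <- ends[keep]
  lapply(seq_along(starts), function(i)
    list(kr = i - 1L, residues = substr(ref, starts[i] + 1L, ends[i]),
         start = starts[i], end = ends[i], overlap = overlap))
}

#' Split a query into chunks
#'
#' Same convention as [split_reference()], applied to one query; each
#' record keeps the parent query id and the chunk's offset within it.
#'
#' @param query query residues.
#' @param q_chunk_len chunk length (`NULL` or >= query length: one chunk).
#' @param q_overlap overlap; must be smaller than `q_chunk_len`.
#' @param query_id parent query identifier.
#' @return list of query records: `kq`, `query_id`, `residues`, `offset`.
#' @export
split_query <- function(query, q_chunk_len = NULL, q_overlap = 0L,
                        query_id = "query") {
  n <- nchar(query)
  if (n == 0L) stop("query must be nonempty")
  if (is.null(q_chunk_len) || q_chunk_len >= n)
    return(list(list(kq = paste0(query_id, "/0"), query_id = query_id,
                     residues = query, offset = 0L)))
  chunks <- split_reference(query, q_chunk_len, q_overlap)
  lapply(chunks, function(ch)
    list(kq = paste0(query_id, "/", ch$kr), query_id = query_id,
         residues = ch$residues, offset = ch$start))
}

#' One map task: align all query chunks against one reference chunk
#'
#' Runs [align_long_read()] for each query record against the chunk (the
#' inner loop is distributed over `p` cores), translating coordinates to
#' global reference and query frames, and recording the timing terms of
#' the map makespan decomposition: data fetch, query split, alignment and
#' store.
#'
#' @param chunk a chunk record from [split_reference()].
#' @param q_records query records from [split_query()] (possibly several
#'   queries concatenated).
#' @param scheme a [sw_scheme()].
#' @param params a [seed_params()].
#' @param p cores used for the inner alignment loop.
#' @param both_strands align both strands.
#' @param ref_name reference name for the records.
#' @param t_get,t_qi externally measured fetch/split times to record.
#' @return list with `records` (global coordinates, keyed by
#'   `(query, chunk)`) and `timing` (seconds: `t_get`, `t_qi`, `t_align`,
#'   `t_store`).
#' @export
map_task <- function(chunk, q_records, scheme = sw_scheme(),
                     params = seed_params(), p = 1L, both_strands = TRUE,
                     ref_name = "ref", t_get = 0, t_qi = 0) {
  t0 <- proc_now()
  index <- build_fm_index(paste0(chunk$residues, SENTINEL), name = ref_name)
  one <- function(qr) {
    recs <- align_long_read(qr$residues, chunk$residues, scheme, params,
                            both_strands = both_strands,
                            query_id = qr$query_id, ref_name = ref_name,
                            index = index)
    if (nrow(recs) > 0L) {
      recs$q_start <- recs$q_start + qr$offset
      recs$q_end <- recs$q_end + qr$offset
      recs$r_start <- recs$r_start + chunk$start
      recs$r_end <- recs$r_end + chunk$start
      recs$chunk <- chunk$kr
    }
    recs
  }
  recs <- if (p > 1L && length(q_records) > 1L)
    parallel::mclapply(q_records, one, mc.cores = p)
  else lapply(q_records, one)
  bad <- vapply(recs, inherits, logical(1L), "try-error")
  if (any(bad))
    stop(sprintf("map task failed for chunk %d, query '%s': %s", chunk$kr,
                 q_records[[which(bad)[1L]]]$query_id,
                 as.character(recs[[which(bad)[1L]]])))
  t1 <- proc_now()
  records <- do.call(rbind, recs)
  if (is.null(records)) records <- empty_records()
  rownames(records) <- NULL
  t2 <- proc_now()
  list(records = records,
       timing = list(t_get = t_get, t_qi = t_qi, t_align = t1 - t0,
                     t_store = t2 - t1),
       kr = chunk$kr)
}

proc_now <- function() as.numeric(Sys.time())

#' Shuffle and sort intermediate records
#'
#' Groups intermediate records by query id and sorts each group by
#' `(global reference start, -score, chunk id)`; the grouping is total and
#' invariant under any permutation of the input.
#'
#' @param records intermediate alignment records (rows from map tasks),
#'   either one data frame or a list of them.
#' @return named list of sorted record data frames, one per query id, in
#'   query-id order.
#' @export
shuffle_sort <- function(records) {
  if (is.data.frame(records)) records <- list(records)
  all <- do.call(rbind, records)
  if (is.null(all) || nrow(all) == 0L)
    return(structure(list(), names = character(0)))
  groups <- split(all, all$query)
  groups <- groups[order(names(groups))]
  lapply(groups, function(g) {
    g <- g[order(g$r_start, -g$score, g$chunk, g$strand, g$q_start), ,
           drop = FALSE]
    rownames(g) <- NULL
    g
  })
}

#' Reduce one query group to nonredundant, nonoverlapping records
#'
#' Exact duplicates (the same alignment emitted by two overlapping chunks)
#' collapse to one.  The survivors are swept greedily in score-then-
#' position order: a record is retained unless its reference interval
#' overlaps an already retained record (same query, same strand) by more
#' than `redundancy_fraction` of the shorter interval.
#'
#' @param group one sorted group from [shuffle_sort()].
#' @param redundancy_fraction maximum tolerated overlap fraction
#'   (default 0.5).
#' @return data frame of retained records, sorted by reference start.
#' @export
reduce_task <- function(group, redundancy_fraction = 0.5) {
  if (nrow(group) == 0L) return(group)
  # collapse exact duplicates from chunk-overlap zones (chunk id may differ)
  key <- paste(group$query, group$strand, group$q_start, group$q_end,
               group$r_start, group$r_end, group$score, group$ops)
  group <- group[!duplicated(key), , drop = FALSE]
  ord <- order(-group$score, group$r_start, group$strand, group$q_start)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (group$strand[j] != group$strand[i]) next
      ov <- min(group$r_end[i], group$r_end[j]) -
        max(group$r_start[i], group$r_start[j])
      if (ov <= 0) next
      shorter <- min(group$r_end[i] - group$r_start[i],
                     group$r_end[j] - group$r_start[j])
      if (shorter <= 0 || ov > redundancy_fraction * shorter) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- group[sort(kept), , drop = FALSE]
  out <- out[order(out$r_start, -out$score, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full chunked alignment pipeline
#'
#' Orchestrates split, map (w parallel workers, p cores each),
#' shuffle/sort and reduce (w parallel workers).  With
#' `config$workers$phase_overlap` the shuffle consumes map output as soon
#' as the first map worker finishes rather than after the whole map phase;
#' this changes only the makespan report, never the records.  The final
#' record set is identical to a sequential single-worker run.
#'
#' @param ref named character scalar (or plain scalar) reference.
#' @param queries named character vector of reads.
#' @param config a [run_config()].
#' @return list with `records` (final nonredundant record data frame) and
#'   `makespan` (a `makespan_report`).
#' @export
run_pipeline <- function(ref, queries, config = run_config()) {
  config <- validate_config(config)
  if (length(ref) != 1L) stop("exactly one reference sequence expected")
  ref_name <- names(ref) %||% "ref"
  if (is.null(names(queries)))
    names(queries) <- sprintf("read%04d", seq_along(queries))
  scheme <- config$scoring
  params <- config$seeding
  w <- config$workers$w
  p <- config$workers$p
  wall0 <- proc_now()

  chunks <- split_reference(ref[[1L]], config$chunking$chunk_len,
                            config$chunking$overlap)

  # map phase: chunks are dealt round-robin to w workers; each worker
  # performs its tasks sequentially (fetch -> query split -> align -> store)
  worker_of <- (seq_along(chunks) - 1L) %% w + 1L
  run_worker <- function(widx) {
    t_start <- proc_now()
    mine <- which(worker_of == widx)
    tasks <- lapply(mine, function(ci) {
      tg0 <- proc_now()
      chunk <- chunks[[ci]]              # "fetch" the chunk
      tg1 <- proc_now()
      q_records <- unlist(lapply(names(queries), function(qid)
        split_query(queries[[qid]], config$chunking$q_chunk_len,
                    config$chunking$q_overlap, query_id = qid)),
        recursive = FALSE)
      tg2 <- proc_now()
      res <- try(map_task(chunk, q_records, scheme, params, p = p,
                          both_strands = config$output$both_strands,
                          ref_name = ref_name, t_get = tg1 - tg0,
                          t_qi = tg2 - tg1), silent = TRUE)
      if (inherits(res, "try-error"))
        stop(sprintf("map task for chunk %d failed: %s", chunk$kr,
                     attr(res, "condition")$message))
      if (!is.null(config$spill_dir)) spill_records(res, config$spill_dir)
      res
    })
    list(widx = widx, tasks = tasks, t_start = t_start, t_end = proc_now())
  }
  map_out <- if (w > 1L)
    parallel::mclapply(seq_len(w), run_worker, mc.cores = w)
  else lapply(seq_len(w), run_worker)
  errs <- vapply(map_out, inherits, logical(1L), "try-error")
  if (any(errs)) stop("map phase failed: ", as.character(map_out[[which(errs)[1L]]]))

  # shuffle: with phase overlap the reduce side begins inserting records
  # at the first map-worker completion; the insertion order is normalised
  # by chunk id so the grouping is identical either way.
  shuffle_t0 <- proc_now()
  all_tasks <- unlist(lapply(map_out, `[[`, "tasks"), recursive = FALSE)
  all_tasks <- all_tasks[order(vapply(all_tasks, `[[`, integer(1L), "kr"))]
  if (!is.null(config$spill_dir))
    all_tasks <- lapply(all_tasks, reload_records, dir = config$spill_dir)
  groups <- shuffle_sort(lapply(all_tasks, `[[`, "records"))
  shuffle_t1 <- proc_now()

  # reduce phase: query groups dealt round-robin to w reduce workers
  gw <- if (length(groups)) (seq_along(groups) - 1L) %% w + 1L else integer(0)
  run_reducer <- function(widx) {
    t0 <- proc_now()
    mine <- which(gw == widx)
    out <- lapply(groups[mine], reduce_task,
                  redundancy_fraction = config$output$redundancy_fraction)
    t1 <- proc_now()
    res <- do.call(rbind, out)
    list(widx = widx, records = res, t_fn = t1 - t0,
         t_store = proc_now() - t1)
  }
  red_out <- if (w > 1L && length(groups) > 1L)
    parallel::mclapply(seq_len(w), run_reducer, mc.cores = w)
  else lapply(seq_len(w), run_reducer)
  errs <- vapply(red_out, inherits, logical(1L), "try-error")
  if (any(errs))
    stop("reduce phase failed: ", as.character(red_out[[which(errs)[1L]]]))

  records <- do.call(rbind, lapply(red_out, `[[`, "records"))
  if (is.null(records)) records <- empty_records()
  records <- records[order(records$query, records$r_start, -records$score), ,
                     drop = FALSE]
  rownames(records) <- NULL

  # makespan bookkeeping (means over workers; the VM configuration term of
  # the total-makespan decomposition is fixed at 0 at desk scale)
  map_workers <- lapply(map_out, function(wk) {
    tm <- lapply(wk$tasks, `[[`, "timing")
    list(makespan = wk$t_end - wk$t_start,
         t_get = sum(vapply(tm, `[[`, numeric(1L), "t_get")),
         t_qi = sum(vapply(tm, `[[`, numeric(1L), "t_qi")),
         t_align = sum(vapply(tm, `[[`, numeric(1L), "t_align")),
         t_store = sum(vapply(tm, `[[`, numeric(1L), "t_store")),
         n_tasks = length(wk$tasks))
  })
  shuffle_share <- (shuffle_t1 - shuffle_t0) / w
  reduce_workers <- lapply(red_out, function(wk)
    list(makespan = shuffle_share + wk$t_fn + wk$t_store,
         t_get = shuffle_share, t_fn = wk$t_fn, t_store = wk$t_store))
  report <- makespan_report(map_workers, reduce_workers, w = w, p = p,
                            phase_overlap = config$workers$phase_overlap,
                            wall_clock = proc_now() - wall0)
  list(records = records, makespan = report)
}

spill_records <- function(task, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, sprintf("map-%05d.jsonl", task$kr))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(task$records) > 0L)
    for (i in seq_len(nrow(task$records)))
      writeLines(jsonlite::toJSON(as.list(task$records[i, ]),
                                  auto_unbox = TRUE), con)
  invisible(path)
}

reload_records <- function(task, dir) {
  path <- file.path(dir, sprintf("map-%05d.jsonl", task$kr))
  lines <- readLines(path)
  if (length(lines) == 0L) {
    task$records <- empty_records()
    return(task)
  }
  rows <- lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE))
  task$records <- do.call(rbind, rows)
  task
}
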