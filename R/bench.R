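# Informational benchmarks: serial vs wavefront matrix fill and
# sequential vs overlapped map/reduce phases.  Timings are
# hardware-dependent and reported as information only.

#' Time serial versus wavefront Smith-Waterman fills
#'
#' Aligns one random pair of sequences of length `n` (matrix fill plus
#' traceback, the in-memory fast path) with the serial order and with the
#' wavefront order at each lane count, and reports elapsed seconds and
#' speed-up ratios.
#'
#' @param n sequence length for both sequences.
#' @param lanes lane counts to try.
#' @param scheme a [sw_scheme()].
#' @param seed RNG seed for the random pair.
#' @param reps repetitions per timing; the minimum elapsed time is
#'   reported, which suppresses scheduler noise.
#' @return data frame: `mode`, `lanes`, `seconds`, `speedup` (serial time
#'   over this mode's time).
#' @export
bench_wavefront <- function(n = 2000L, lanes = c(1L, 2L, 4L),
                            scheme = sw_scheme(), seed = 1L, reps = 1L) {
  q0 <- with_seed(seed, random_dna(n))
  q1 <- with_seed(seed + 1L, random_dna(n))
  one <- function(wavefront, ln) {
    t0 <- proc_now()
    res <- sw_align_cpp(q0, q1, scheme$match, scheme$mismatch,
                        scheme$gap_open, scheme$gap_extend,
                        scheme$special_n, wavefront, ln)
    proc_now() - t0
  }
  # interleave the modes within each repetition so they face the same
  # machine conditions, and keep the per-mode minimum
  lanes <- as.integer(lanes)
  t_serial <- Inf
  t_wave <- rep(Inf, length(lanes))
  for (r in seq_len(reps)) {
    t_serial <- min(t_serial, one(FALSE, 1L))
    for (i in seq_along(lanes))
      t_wave[i] <- min(t_wave[i], one(TRUE, lanes[i]))
  }
  out <- rbind(data.frame(mode = "serial", lanes = 1L, seconds = t_serial,
                          speedup = 1),
               data.frame(mode = "wavefront", lanes = lanes,
                          seconds = t_wave, speedup = t_serial / t_wave))
  rownames(out) <- NULL
  out
}

#' Compare sequential and overlapped map/reduce phase execution
#'
#' Runs the same pipeline with the reduce phase gated on the full map
#' phase and with phase overlap enabled, confirming identical outputs and
#' reporting the makespans side by side.
#'
#' @param ref,queries pipeline inputs (see [run_pipeline()]).
#' @param config base [run_config()]; the phase-overlap flag is overridden.
#' @return data frame with one row per mode: `phase_overlap`,
#'   `t_map`, `t_reduce`, `t_total`, `reduce_start`, `wall_clock`,
#'   `identical_output`.
#' @export
bench_phases <- function(ref, queries, config = run_config()) {
  runs <- lapply(c(FALSE, TRUE), function(ov) {
    config$workers$phase_overlap <- ov
    run_pipeline(ref, queries, config)
  })
  same <- identical(runs[[1L]]$records, runs[[2L]]$records)
  do.call(rbind, lapply(seq_along(runs), function(i) {
    s <- makespan_summary(runs[[i]]$makespan)
    data.frame(phase_overlap = c(FALSE, TRUE)[i], t_map = s$t_map,
               t_reduce = s$t_reduce, t_total = s$t_total,
               reduce_start = runs[[i]]$makespan$reduce_start,
               wall_clock = runs[[i]]$makespan$wall_clock,
               identical_output = same)
  }))
}
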