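# Deterministic synthetic references and reads with exact ground truth, so
# the whole aligner is testable without any download.  The mutation model
# is deliberately minimal: independent per-base substitutions and
# per-position insertions/deletions with geometric lengths (mean 2).

#' Generate a random reference sequence
#'
#' Bases are drawn independently with `P(G) = P(C) = gc_fraction / 2` and
#' `P(A) = P(T) = (1 - gc_fraction) / 2`; deterministic for a fixed seed.
#'
#' @param length sequence length (> 0).
#' @param gc_fraction target GC content in `[0, 1]`.
#' @param seed integer RNG seed (`NULL` to use the current RNG state).
#' @param name sequence name.
#' @return named character vector of length 1.
#' @examples
#' generate_reference(50, seed = 1)
#' @export
generate_reference <- function(length, gc_fraction = 0.5, seed = NULL,
                               name = "ref") {
  length <- as.integer(length)
  if (is.na(length) || length <= 0L) stop("length must be positive")
  if (!is.numeric(gc_fraction) || gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must be in [0, 1]")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seq <- with_seed(seed, random_dna(length, base_prob = p))
  stats::setNames(seq, name)
}

#' Sample reads from a reference with known truth
#'
#' Read start positions are uniform over the valid range; each read is a
#' copy of the reference slice with independent per-base substitutions
#' (rate `sub_rate`, always to a different base), insertions and deletions
#' (rates `ins_rate`, `del_rate` per position, geometric lengths with mean
#' 2).  A fraction `strand_mix` of reads is reverse-complemented.  The
#' truth table records the exact reference interval, strand, edit counts
#' and the full edit script, from which the read is exactly re-derivable
#' (see [apply_edits()]).
#'
#' @param ref reference residues (character scalar or the output of
#'   [generate_reference()]).
#' @param n_reads number of reads.
#' @param read_len read length in bases (must not exceed the reference).
#' @param sub_rate,ins_rate,del_rate edit rates in `[0, 1)`.
#' @param strand_mix probability of the reverse strand.
#' @param seed integer RNG seed.
#' @return list with `reads` (named character vector) and `truth` (data
#'   frame: `read`, `start`, `end` 0-based half-open on the reference,
#'   `strand`, `n_sub`, `n_ins`, `n_del`, `ins_bases`, `del_bases`,
#'   `edits`).
#' @examples
#' ref <- generate_reference(500, seed = 7)
#' rs <- sample_reads(ref, 3, 100, sub_rate = 0.02, seed = 7)
#' rs$truth[, c("read", "start", "end", "strand", "n_sub")]
#' @export
sample_reads <- function(ref, n_reads, read_len, sub_rate = 0.02,
                         ins_rate = 0.0025, del_rate = 0.0025,
                         strand_mix = 0.5, seed = NULL) {
  ref <- ref[[1L]]
  n <- nchar(ref)
  read_len <- as.integer(read_len)
  if (read_len > n) stop("read_len exceeds the reference length")
  if (!is.numeric(sub_rate) || sub_rate < 0 || sub_rate > 1)
    stop("sub_rate must be in [0, 1]")
  for (r in c(ins_rate, del_rate))
    if (!is.numeric(r) || r < 0 || r >= 1) stop("indel rates must be in [0, 1)")
  with_seed(seed, {
    reads <- character(n_reads)
    truth <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      # margin so that deletions cannot run off the reference end
      margin <- min(n - read_len, max(20L, ceiling(read_len * 0.2)))
      start <- sample.int(n - read_len - margin + 1L, 1L) - 1L
      gen <- mutate_slice(ref, start, read_len, sub_rate, ins_rate, del_rate)
      strand <- if (runif(1L) < strand_mix) "-" else "+"
      read <- if (strand == "+") gen$read else revcomp(gen$read)
      id <- sprintf("read%04d", i)
      reads[i] <- read
      truth[[i]] <- data.frame(
        read = id, start = start, end = gen$ref_end, strand = strand,
        n_sub = gen$n_sub, n_ins = gen$n_ins, n_del = gen$n_del,
        ins_bases = gen$ins_bases, del_bases = gen$del_bases,
        edits = gen$edits, stringsAsFactors = FALSE)
    }
    names(reads) <- sprintf("read%04d", seq_len(n_reads))
    list(reads = reads, truth = do.call(rbind, truth))
  })
}

# walk the reference from `start` emitting read bases until read_len is
# reached; returns the read, the consumed reference end and the edit script
mutate_slice <- function(ref, start, read_len, sub_rate, ins_rate,
                         del_rate) {
  bases <- c("A", "C", "G", "T")
  out <- character(read_len)
  oi <- 0L
  ri <- start            # next reference position to consume (0-based)
  edits <- character(0)
  n_sub <- 0L; n_ins <- 0L; n_del <- 0L; ins_b <- 0L; del_b <- 0L
  n <- nchar(ref)
  while (oi < read_len) {
    u <- runif(1L)
    if (u < ins_rate) {
      len <- min(rgeom(1L, 0.5) + 1L, read_len - oi)
      ins <- paste(sample(bases, len, replace = TRUE), collapse = "")
      out[(oi + 1L):(oi + len)] <- strsplit(ins, "")[[1L]]
      oi <- oi + len
      n_ins <- n_ins + 1L; ins_b <- ins_b + len
      edits <- c(edits, paste0("I:", ins))
    } else if (u < ins_rate + del_rate && ri < n) {
      len <- min(rgeom(1L, 0.5) + 1L, n - ri)
      ri <- ri + len
      n_del <- n_del + 1L; del_b <- del_b + len
      edits <- c(edits, paste0("D:", len))
    } else {
      if (ri >= n) stop("ran off the reference while mutating a read")
      base <- substr(ref, ri + 1L, ri + 1L)
      ri <- ri + 1L
      if (runif(1L) < sub_rate) {
        nb <- sample(setdiff(bases, base), 1L)
        out[oi + 1L] <- nb
        n_sub <- n_sub + 1L
        edits <- c(edits, paste0("S:", nb))
      } else {
        out[oi + 1L] <- base
        edits <- c(edits, "M")
      }
      oi <- oi + 1L
    }
  }
  list(read = paste(out, collapse = ""), ref_end = ri, n_sub = n_sub,
       n_ins = n_ins, n_del = n_del, ins_bases = ins_b, del_bases = del_b,
       edits = paste(compress_edits(edits), collapse = ";"))
}

compress_edits <- function(edits) {
  # collapse runs of "M" into "M<k>"
  out <- character(0)
  i <- 1L
  while (i <= length(edits)) {
    if (edits[i] == "M") {
      j <- i
      while (j < length(edits) && edits[j + 1L] == "M") j <- j + 1L
      out <- c(out, paste0("M", j - i + 1L))
      i <- j + 1L
    } else {
      out <- c(out, edits[i])
      i <- i + 1L
    }
  }
  out
}

#' Re-derive a read from the reference and its recorded edits
#'
#' Applies one truth row's edit script to the reference; the result equals
#' the stored read exactly (for `-` strand reads, after reverse
#' complementing).  This is the round-trip invariant of the simulator.
#'
#' @param ref the reference residues.
#' @param truth_row one row of the truth table from [sample_reads()].
#' @return the reconstructed read (original read frame).
#' @export
apply_edits <- function(ref, truth_row) {
  ref <- ref[[1L]]
  ri <- truth_row$start
  out <- character(0)
  for (tok in strsplit(truth_row$edits, ";", fixed = TRUE)[[1L]]) {
    if (grepl("^M[0-9]+$", tok)) {
      k <- as.integer(substring(tok, 2L))
      out <- c(out, substr(ref, ri + 1L, ri + k))
      ri <- ri + k
    } else if (startsWith(tok, "S:")) {
      out <- c(out, substring(tok, 3L))
      ri <- ri + 1L
    } else if (startsWith(tok, "I:")) {
      out <- c(out, substring(tok, 3L))
    } else if (startsWith(tok, "D:")) {
      ri <- ri + as.integer(substring(tok, 3L))
    } else stop("malformed edit token: ", tok)
  }
  read <- paste(out, collapse = "")
  if (truth_row$strand == "-") read <- revcomp(read)
  read
}

#' Write a truth table as TSV
#' @param truth truth data frame from [sample_reads()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
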