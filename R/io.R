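# Readers and writers: FASTA input, TSV (canonical) and SAM
# (interoperability) alignment output, and a versioned JSON container for
# reference indexes.

#' One alignment record
#'
#' The unit record of the aligner: query and reference intervals are
#' 0-based half-open; `strand` is `+` or `-` (query coordinates are always
#' in the original read frame; `ops` always runs along the reference).
#'
#' @param query,ref identifiers.
#' @param q_start,q_end,q_len query interval and full query length.
#' @param r_start,r_end reference interval.
#' @param strand `"+"` or `"-"`.
#' @param score alignment score.
#' @param ops run-length `M`/`I`/`D` operation string.
#' @param chunk source reference-chunk id.
#' @return a one-row data frame.
#' @export
alignment_record <- function(query, q_start, q_end, q_len, ref, r_start,
                             r_end, strand, score, ops, chunk = 0L) {
  stopifnot(strand %in% c("+", "-"), q_start <= q_end, r_start <= r_end)
  data.frame(query = as.character(query), q_start = as.integer(q_start),
             q_end = as.integer(q_end), q_len = as.integer(q_len),
             ref = as.character(ref), r_start = as.integer(r_start),
             r_end = as.integer(r_end), strand = strand,
             score = as.integer(score), ops = as.character(ops),
             chunk = as.integer(chunk), stringsAsFactors = FALSE)
}

empty_records <- function() {
  data.frame(query = character(0), q_start = integer(0), q_end = integer(0),
             q_len = integer(0), ref = character(0), r_start = integer(0),
             r_end = integer(0), strand = character(0), score = integer(0),
             ops = character(0), chunk = integer(0),
             stringsAsFactors = FALSE)
}

#' Read a FASTA file
#'
#' Multi-record, wrapped lines, case folded to uppercase.  Residues are
#' restricted to A/C/G/T/N; anything else (including `-` and `*`) is
#' rejected with an error naming the record.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences (possibly length 0).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[[i]]) == 0L)
      stop(sprintf("record '%s': empty sequence", names(seqs)[i]))
    if (grepl("[^ACGNT]", seqs[[i]])) {
      bad <- regmatches(seqs[[i]], regexpr("[^ACGNT]", seqs[[i]]))
      stop(sprintf(
        "record '%s': illegal symbol '%s' (alphabet is A/C/G/T/N)",
        names(seqs)[i], bad))
    }
  }
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

TSV_COLUMNS <- c("query", "q_start", "q_end", "q_len", "ref", "r_start",
                 "r_end", "strand", "score", "ops", "chunk")

#' Write alignment records
#'
#' TSV is the canonical lossless format: one header line, then one row per
#' record with the columns `query`, `q_start`, `q_end`, `q_len` (0-based
#' half-open query interval and read length), `ref`, `r_start`, `r_end`
#' (0-based half-open reference interval), `strand`, `score`, `ops`
#' (run-length `M`/`I`/`D` along the reference) and `chunk`.  SAM output
#' converts to 1-based `POS`, sets `FLAG` 16 for reverse-strand records,
#' and renders `ops` as a CIGAR with soft clips for the unaligned ends of
#' the read.
#'
#' @param records alignment record data frame.
#' @param path output path ("" for standard output).
#' @param format `"tsv"` or `"sam"`.
#' @param ref_lengths named integer vector of reference lengths (required
#'   for SAM headers).
#' @return `path`, invisibly.
#' @export
write_alignments <- function(records, path, format = c("tsv", "sam"),
                             ref_lengths = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(records[, TSV_COLUMNS, drop = FALSE], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (is.null(ref_lengths))
    stop("SAM output requires ref_lengths (named vector)")
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                     as.integer(ref_lengths)))
  if (nrow(records) > 0L) {
    body <- vapply(seq_len(nrow(records)), function(i) {
      r <- records[i, ]
      # CIGAR is written in SAM (reference) orientation; for '-' records
      # SEQ would be the reverse complement, so the leading clip is the
      # unaligned tail of the original read.
      left <- if (r$strand == "+") r$q_start else r$q_len - r$q_end
      right <- if (r$strand == "+") r$q_len - r$q_end else r$q_start
      cigar <- paste0(if (left > 0L) paste0(left, "S") else "", r$ops,
                      if (right > 0L) paste0(right, "S") else "")
      paste(r$query, if (r$strand == "+") 0L else 16L, r$ref, r$r_start + 1L,
            255L, cigar, "*", 0L, 0L, "*", "*", paste0("AS:i:", r$score),
            sep = "\t")
    }, character(1L))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back a TSV alignment file
#' @param path a file written by [write_alignments()] with `format="tsv"`.
#' @return alignment record data frame.
#' @export
read_alignments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(query = "character", ref = "character",
                                  strand = "character", ops = "character"))
  if (!identical(names(df), TSV_COLUMNS))
    stop("not a seedwave alignment TSV: ", path)
  df
}

#' Serialize a reference index
#'
#' Versioned JSON container holding the suffix array and BWT; the text and
#' occurrence table are reconstructed on load (LF walk), so the container
#' stays compact and the on-disk format is plain text.
#'
#' @param index an `fm_index`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "fm_index"))
  obj <- list(format = "seedwave-index", version = 1L,
              name = index$name %||% NA_character_,
              n = index$n, sa = index$sa, bwt = index$bwt)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "seedwave-index") || obj$version != 1L)
    stop("not a seedwave index file (or unsupported version): ", path)
  text <- lf_reconstruct_cpp(obj$bwt, {
    # counts are derivable from the bwt
    tab <- table(factor(strsplit(obj$bwt, "")[[1L]],
                        levels = c("$", LETTERS)))
    cumsum(c(0L, as.integer(tab)))[seq_len(27L)]
  })
  idx <- build_fm_index(text, name = if (is.na(obj$name)) NULL else obj$name)
  if (!identical(idx$sa, as.integer(obj$sa)))
    stop("index file is corrupt (suffix array mismatch): ", path)
  idx
}

#' Re-score an alignment record against its sequences
#'
#' @param record one-row alignment record.
#' @param query_seq the full read (original frame).
#' @param ref_seq the full reference the record's coordinates refer to.
#' @param scheme a [sw_scheme()].
#' @return integer score recomputed from the record's `ops`.
#' @export
rescore_record <- function(record, query_seq, ref_seq,
                           scheme = sw_scheme()) {
  qs <- if (record$strand == "+") query_seq else revcomp(query_seq)
  qi <- if (record$strand == "+") c(record$q_start, record$q_end)
        else c(record$q_len - record$q_end, record$q_len - record$q_start)
  rescore_ops(record$ops,
              substr(qs, qi[1L] + 1L, qi[2L]),
              substr(ref_seq, record$r_start + 1L, record$r_end),
              scheme)
}
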