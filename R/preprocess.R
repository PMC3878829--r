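# Pre-processing: error-tolerant 3' adapter cleavage, length and quality
# filtering, read collapsing and read-length distribution reporting.

#' Specify 3' adapters and matching tolerances
#'
#' One or more 3' adapter sequences are searched jointly in every read. A
#' candidate match of matched-adapter length L with E unit-cost edit errors
#' (substitutions and indels) is admissible iff `L >= min_overlap` and
#' `E <= floor(max_error_rate * L)`. Among admissible candidates the winner
#' has the fewest errors, then the 5'-most start, then the earliest adapter
#' in the list. Everything from the match start to the read 3' end is
#' removed.
#'
#' @param adapters Character vector of adapter sequences over \{A,C,G,T\}.
#' @param max_error_rate Allowed errors per matched adapter base, in
#'   `[0, 1)`. Default 0.1.
#' @param min_overlap Minimum matched adapter length. Default 3.
#' @return An object of class `adapter_spec`.
#' @export
adapter_spec <- function(adapters, max_error_rate = 0.1, min_overlap = 3L) {
  adapters <- normalize_seq(as.character(adapters))
  if (!length(adapters) || any(!nchar(adapters))) {
    stop("at least one non-empty adapter is required", call. = FALSE)
  }
  if (any(grepl("[^ACGT]", adapters))) {
    stop("adapters must be over {A,C,G,T}", call. = FALSE)
  }
  if (max_error_rate < 0 || max_error_rate >= 1) {
    stop("max_error_rate must be in [0, 1)", call. = FALSE)
  }
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1L) stop("min_overlap must be >= 1", call. = FALSE)
  structure(list(adapters = adapters, max_error_rate = max_error_rate,
                 min_overlap = min_overlap),
            class = "adapter_spec")
}

#' Trim 3' sequencing adapters from reads
#'
#' Removes the best admissible adapter occurrence (see [adapter_spec()] for
#' the matching contract) from each read; the quality string is truncated
#' in lockstep. Reads without an admissible match are returned unchanged.
#'
#' @param reads A read data frame (columns `read_id`, `seq`, `qual`) or a
#'   character vector of sequences.
#' @param spec An [adapter_spec()].
#' @return A list with elements `reads` (the trimmed read data frame, or
#'   character vector if that was the input), `adapter_found` (logical),
#'   `trimmed_bases`, `errors_in_match` and `adapter` (1-based index into
#'   `spec$adapters`, `NA` when no match).
#' @examples
#' spec <- adapter_spec("TGGAATTCTCGG", max_error_rate = 0)
#' trim_adapter(c(r1 = "ACGTACGTTGGAATTCTCGG"), spec)
#' @export
trim_adapter <- function(reads, spec) {
  stopifnot(inherits(spec, "adapter_spec"))
  seq_only <- is.character(reads)
  seqs <- if (seq_only) normalize_seq(reads) else reads$seq
  res <- cpp_trim_adapters(seqs, spec$adapters, spec$max_error_rate,
                           spec$min_overlap)
  found <- res$adapter > 0L
  trimmed <- substr(seqs, 1L, res$keep)
  out <- if (seq_only) {
    stats::setNames(trimmed, names(reads))
  } else {
    data.frame(read_id = reads$read_id, seq = trimmed,
               qual = substr(reads$qual, 1L, res$keep),
               stringsAsFactors = FALSE)
  }
  list(reads = out,
       adapter_found = found,
       trimmed_bases = nchar(seqs) - res$keep,
       errors_in_match = ifelse(found, res$errors, 0L),
       adapter = ifelse(found, res$adapter, NA_integer_))
}

#' Keep reads whose mean base quality reaches a threshold
#'
#' @param reads Read data frame.
#' @param min_mean_q Minimum mean quality (inclusive). Default 20.
#' @return Logical keep vector. Empty reads are discarded.
#' @export
quality_filter <- function(reads, min_mean_q = 20) {
  mq <- mean_quality(reads$qual)
  !is.na(mq) & mq >= min_mean_q
}

#' Keep reads at least `min_len` bases long
#'
#' Reads shorter than 15 nt (the default) carry too little sequence to be
#' mapped unambiguously and are discarded.
#'
#' @param reads Read data frame or character vector of sequences.
#' @param min_len Minimum length (inclusive). Default 15.
#' @return Logical keep vector.
#' @export
length_filter <- function(reads, min_len = 15L) {
  seqs <- if (is.character(reads)) reads else reads$seq
  nchar(seqs) >= min_len
}

#' Collapse reads to unique sequences with multiplicities
#'
#' @param reads Read data frame or character vector of sequences.
#' @return Data frame with columns `seq` and `multiplicity`, in order of
#'   first occurrence. Multiplicities sum to the number of input reads.
#' @export
collapse_reads <- function(reads) {
  seqs <- if (is.character(reads)) reads else reads$seq
  if (!length(seqs)) {
    return(data.frame(seq = character(), multiplicity = integer(),
                      stringsAsFactors = FALSE))
  }
  u <- unique(seqs)
  counts <- table(factor(seqs, levels = u))
  data.frame(seq = u, multiplicity = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Read-length distribution
#'
#' @param reads Read data frame or character vector of sequences.
#' @return Data frame with columns `length` and `count`, sorted by length.
#' @export
length_distribution <- function(reads) {
  seqs <- if (is.character(reads)) reads else reads$seq
  if (!length(seqs)) {
    return(data.frame(length = integer(), count = integer()))
  }
  tb <- table(nchar(seqs))
  data.frame(length = as.integer(names(tb)), count = as.integer(tb))
}

#' Plot a read-length histogram
#'
#' @param dist A data frame from [length_distribution()].
#' @param ... Passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot_length_distribution <- function(dist, ...) {
  invisible(graphics::barplot(stats::setNames(dist$count, dist$length),
                              xlab = "read length (nt)", ylab = "reads", ...))
}

#' Run the full pre-processing stage on one sample
#'
#' Applies, in order: adapter trimming, minimum-length filtering, then
#' mean-quality filtering. Reads failing both filters are counted as
#' length discards. The report partitions the input exactly:
#' `n_input == n_kept + n_discarded_short + n_discarded_quality`.
#'
#' @param reads Read data frame.
#' @param spec An [adapter_spec()].
#' @param min_length Minimum post-trimming read length (default 15).
#' @param min_quality Minimum mean base quality (default 20).
#' @return A list with `reads` (kept, trimmed reads), `report` (class
#'   `preprocess_report`: the count partition plus the post-trimming
#'   length histogram of kept reads) and `trimming` (per-read trimming
#'   details for the input reads).
#' @export
preprocess_reads <- function(reads, spec, min_length = 15L,
                             min_quality = 20) {
  tr <- trim_adapter(reads, spec)
  trimmed <- tr$reads
  keep_len <- length_filter(trimmed, min_length)
  keep_q <- quality_filter(trimmed, min_quality)
  kept <- trimmed[keep_len & keep_q, , drop = FALSE]
  rownames(kept) <- NULL
  report <- structure(list(
    n_input = nrow(reads),
    n_kept = nrow(kept),
    n_discarded_short = sum(!keep_len),
    n_discarded_quality = sum(keep_len & !keep_q),
    length_histogram = length_distribution(kept)
  ), class = "preprocess_report")
  list(reads = kept, report = report,
       trimming = data.frame(adapter_found = tr$adapter_found,
                             trimmed_bases = tr$trimmed_bases,
                             errors_in_match = tr$errors_in_match))
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf(
    "<preprocess_report> input %d | kept %d | short %d | low-quality %d\n",
    x$n_input, x$n_kept, x$n_discarded_short, x$n_discarded_quality))
  invisible(x)
}
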