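# Readers/writers for the standard formats the pipeline touches, plus the
# shared tabular data models (reads, reference libraries, count tables).

#' Read single-end reads from a FASTQ file
#'
#' Parses 4-line FASTQ records with Sanger (offset-33) quality encoding.
#' Sequences are uppercased and U is normalized to T so that downstream
#' matching uses a single DNA alphabet. Gzipped files are read
#' transparently.
#'
#' @param path Path to a FASTQ file.
#' @return A data frame with columns `read_id`, `seq` and `qual` (the raw
#'   offset-33 quality string, same length as `seq`). Decode scores with
#'   [phred_scores()].
#' @seealso [write_fastq()], [phred_scores()]
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGU", "+", "IIII"), fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(read_id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  if (n %% 4L != 0L) {
    stop(sprintf("malformed FASTQ '%s': truncated record starting at line %d",
                 path, (n %/% 4L) * 4L + 1L), call. = FALSE)
  }
  hdr <- lines[seq.int(1L, n, by = 4L)]
  sq <- lines[seq.int(2L, n, by = 4L)]
  plus <- lines[seq.int(3L, n, by = 4L)]
  qual <- lines[seq.int(4L, n, by = 4L)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ '%s': missing '@' at line %d",
                 path, (bad[1] - 1L) * 4L + 1L), call. = FALSE)
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ '%s': missing '+' at line %d",
                 path, (bad[1] - 1L) * 4L + 3L), call. = FALSE)
  }
  sq <- normalize_seq(sq)
  bad <- which(nchar(sq) != nchar(qual))
  if (length(bad)) {
    stop(sprintf(
      "malformed FASTQ '%s': sequence/quality length mismatch at line %d",
      path, (bad[1] - 1L) * 4L + 2L), call. = FALSE)
  }
  check_alphabet(sq, "read")
  ids <- sub("^@", "", hdr)
  ids <- sub("[ \t].*$", "", ids)
  data.frame(read_id = ids, seq = sq, qual = qual, stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads A read data frame as returned by [read_fastq()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("sequence/quality length mismatch", call. = FALSE)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(reads)) {
    out <- rbind(paste0("@", reads$read_id), reads$seq, "+", reads$qual)
    writeLines(as.vector(out), con, sep = "\n")
  }
  invisible(path)
}

#' Decode offset-33 quality strings to integer scores
#'
#' @param qual Character vector of quality strings.
#' @return A list of integer vectors, one per read.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

mean_quality <- function(qual) {
  vapply(qual, function(q) {
    v <- utf8ToInt(q)
    if (!length(v)) return(NA_real_)
    mean(v) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

#' Construct a reference library of one small RNA class
#'
#' A reference library is an ordered, named set of reference sequences all
#' belonging to one small non-coding RNA class. For miRNA libraries whose
#' entries carry genomic flanks around the mature sequence, the canonical
#' mature region can be marked with `canonical_start`/`canonical_end`
#' (1-based, inclusive); by default the whole entry is the canonical
#' sequence.
#'
#' @param name Library name.
#' @param rna_class One of `"miRNA"`, `"tRNA"`, `"rRNA"`, `"mRNA"`,
#'   `"piRNA"`, `"other"`.
#' @param ids Character vector of unique feature identifiers.
#' @param seqs Character vector of sequences (U is normalized to T).
#' @param canonical_start,canonical_end Optional integer vectors marking
#'   the canonical mature region within each entry.
#' @return An object of class `ref_library`.
#' @export
ref_library <- function(name, rna_class, ids, seqs,
                        canonical_start = NULL, canonical_end = NULL) {
  rna_class <- match.arg(rna_class, RNA_CLASSES)
  ids <- as.character(ids)
  seqs <- normalize_seq(as.character(seqs))
  if (length(ids) != length(seqs)) {
    stop("ids and seqs must have the same length", call. = FALSE)
  }
  if (!length(ids)) stop("reference library is empty", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate feature_id in library '", name, "': ",
         ids[duplicated(ids)][1], call. = FALSE)
  }
  if (any(!nchar(seqs))) stop("empty reference sequence", call. = FALSE)
  check_alphabet(seqs, "reference")
  canonical_start <- as.integer(canonical_start %||% rep(1L, length(seqs)))
  canonical_end <- as.integer(canonical_end %||% nchar(seqs))
  if (any(canonical_start < 1L) || any(canonical_end > nchar(seqs)) ||
      any(canonical_start > canonical_end)) {
    stop("canonical region outside reference entry", call. = FALSE)
  }
  structure(list(name = name, rna_class = rna_class, ids = ids, seqs = seqs,
                 canonical_start = canonical_start,
                 canonical_end = canonical_end),
            class = "ref_library")
}

#' @export
length.ref_library <- function(x) length(x$ids)

#' @export
print.ref_library <- function(x, ...) {
  cat(sprintf("<ref_library> %s (%s): %d entries, lengths %d-%d nt\n",
              x$name, x$rna_class, length(x$ids),
              min(nchar(x$seqs)), max(nchar(x$seqs))))
  invisible(x)
}

#' Read a reference library from a FASTA file
#'
#' The header token up to the first whitespace becomes the feature id;
#' multi-line sequences are concatenated; U is normalized to T. Duplicate
#' ids and empty files are errors.
#'
#' @param path FASTA file path.
#' @param rna_class Small RNA class of every entry in this file.
#' @param name Library name (defaults to the file name).
#' @inheritParams ref_library
#' @return A [ref_library()].
#' @export
read_fasta <- function(path, rna_class, name = basename(path),
                       canonical_start = NULL, canonical_end = NULL) {
  x <- Biostrings::readBStringSet(path)
  if (!length(x)) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("[ \t].*$", "", names(x))
  ref_library(name, rna_class, ids, as.character(x),
              canonical_start = canonical_start,
              canonical_end = canonical_end)
}

#' Write a reference library to a FASTA file
#'
#' @param library A [ref_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(library, path) {
  stopifnot(inherits(library, "ref_library"))
  x <- Biostrings::BStringSet(stats::setNames(library$seqs, library$ids))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Assemble a feature-by-sample count table
#'
#' The canonical tabular model of the pipeline: one row per feature with
#' its class label, one numeric column per sample.
#'
#' @param feature_id Character vector of unique feature ids.
#' @param rna_class Character vector of class labels, recycled if scalar.
#' @param counts Matrix or data frame of non-negative counts, one column
#'   per sample.
#' @return A data frame with columns `feature_id`, `rna_class`, then one
#'   column per sample.
#' @export
count_table <- function(feature_id, rna_class, counts) {
  counts <- as.data.frame(counts)
  if (length(rna_class) == 1L) rna_class <- rep(rna_class, length(feature_id))
  tab <- cbind(data.frame(feature_id = as.character(feature_id),
                          rna_class = as.character(rna_class),
                          stringsAsFactors = FALSE),
               counts)
  validate_count_table(tab)
}

#' Validate a count table
#'
#' @param tab A count table data frame.
#' @return `tab`, invisibly coerced to the canonical column layout.
#' @export
validate_count_table <- function(tab) {
  if (ncol(tab) < 2L || !identical(names(tab)[1:2], c("feature_id", "rna_class"))) {
    stop("count table must start with columns feature_id, rna_class",
         call. = FALSE)
  }
  if (anyDuplicated(tab$feature_id)) {
    stop("duplicate feature_id in count table", call. = FALSE)
  }
  if (anyDuplicated(names(tab))) {
    stop("duplicate column names in count table", call. = FALSE)
  }
  for (j in seq_along(tab)[-(1:2)]) {
    if (!is.numeric(tab[[j]])) {
      stop("non-numeric counts in sample column '", names(tab)[j], "'",
           call. = FALSE)
    }
    if (anyNA(tab[[j]]) || any(tab[[j]] < 0)) {
      stop("negative or missing counts in sample column '", names(tab)[j],
           "'", call. = FALSE)
    }
  }
  rownames(tab) <- NULL
  tab
}

sample_columns <- function(tab) {
  setdiff(names(tab), c("feature_id", "rna_class"))
}

count_matrix <- function(tab) {
  m <- as.matrix(tab[, sample_columns(tab), drop = FALSE])
  rownames(m) <- tab$feature_id
  m
}

#' Read and write count tables
#'
#' The file dialect is tab-separated with a header line: first column
#' `feature_id`, second `rna_class`, remaining columns one per sample.
#' Lines starting with `#` are ignored. `read_count_table(write_count_table(t))`
#' is the identity for valid tables.
#'
#' @param path File path.
#' @return For `read_count_table`, a validated count table data frame.
#' @export
read_count_table <- function(path) {
  tab <- read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
  tab$feature_id <- as.character(tab$feature_id)
  tab$rna_class <- as.character(tab$rna_class)
  if (!nrow(tab)) {
    # header-only file: sample columns have no inferable type
    tab[-(1:2)] <- lapply(tab[-(1:2)], as.numeric)
  }
  validate_count_table(tab)
}

#' @param tab A count table data frame.
#' @rdname read_count_table
#' @export
write_count_table <- function(tab, path) {
  tab <- validate_count_table(tab)
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}
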