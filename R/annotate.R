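# Hierarchical (first-match cascade) annotation of collapsed reads against
# ordered small RNA reference libraries, with isomiR classification.

default_mismatches <- function(rna_class) {
  ifelse(rna_class %in% c("miRNA", "piRNA"), 0L, 1L)
}

#' Configure the annotation cascade
#'
#' Libraries are tried in the order given; each unique read sequence is
#' assigned, with its full multiplicity, to the first library in which it
#' has at least one hit, and is never tested against later libraries. This
#' first-match semantics mitigates cross-mapping between classes (e.g. a
#' mature miRNA sequence that also occurs in a piRNA database is counted
#' as miRNA when the miRNA library comes first).
#'
#' @param libraries A list of [ref_library()] objects in priority order.
#'   The conventional order is miRNA, tRNA, rRNA, mRNA, piRNA, other.
#' @param max_mismatches Allowed substitutions per library: a single
#'   integer, or a vector named by library name (or class). Defaults to 0
#'   for miRNA/piRNA libraries and 1 for the longer-reference classes.
#' @return An object of class `cascade_config`.
#' @export
cascade_config <- function(libraries, max_mismatches = NULL) {
  if (inherits(libraries, "ref_library")) libraries <- list(libraries)
  if (!length(libraries)) stop("at least one library is required", call. = FALSE)
  ok <- vapply(libraries, inherits, logical(1), what = "ref_library")
  if (!all(ok)) stop("libraries must be ref_library objects", call. = FALSE)
  nm <- vapply(libraries, function(l) l$name, character(1))
  cls <- vapply(libraries, function(l) l$rna_class, character(1))
  if (anyDuplicated(nm)) stop("duplicate library names", call. = FALSE)
  names(libraries) <- nm
  if (is.null(max_mismatches)) {
    mm <- default_mismatches(cls)
  } else if (is.null(names(max_mismatches))) {
    if (length(max_mismatches) == 1L) {
      mm <- rep(as.integer(max_mismatches), length(libraries))
    } else if (length(max_mismatches) == length(libraries)) {
      mm <- as.integer(max_mismatches)
    } else {
      stop("max_mismatches length does not match libraries", call. = FALSE)
    }
  } else {
    mm <- default_mismatches(cls)
    hit <- match(nm, names(max_mismatches))
    hit2 <- match(cls, names(max_mismatches))
    use <- ifelse(!is.na(hit), hit, hit2)
    mm[!is.na(use)] <- as.integer(max_mismatches[use[!is.na(use)]])
  }
  if (any(mm < 0L)) stop("max_mismatches must be >= 0", call. = FALSE)
  structure(list(libraries = libraries, max_mismatches = mm),
            class = "cascade_config")
}

#' Find all occurrences of a read within one reference library
#'
#' Substitution-only (Hamming) matching of the read as a substring of any
#' reference entry, with at most `max_mismatches` mismatches. `N` bases
#' never match.
#'
#' @param seq A single read sequence.
#' @param library A [ref_library()].
#' @param max_mismatches Allowed substitutions.
#' @return Data frame of hits with columns `feature_id`, `start_offset`
#'   (0-based position of the read within the reference) and `mismatches`,
#'   sorted by (mismatches, library entry order, start offset). Zero rows
#'   when there is no hit.
#' @export
map_read <- function(seq, library, max_mismatches = 0L) {
  stopifnot(inherits(library, "ref_library"), length(seq) == 1L)
  seq <- normalize_seq(seq)
  hits <- cpp_map_all(seq, library$seqs, as.integer(max_mismatches))
  data.frame(feature_id = library$ids[hits[, "ref"]],
             start_offset = hits[, "start"],
             mismatches = hits[, "mismatches"],
             stringsAsFactors = FALSE)
}

#' Classify a mapped miRNA read as canonical or isomiR
#'
#' A read equal to the canonical mature sequence is `canonical`. Otherwise
#' the mapped end positions are compared with the canonical mature region
#' of the reference entry: if only the 5' end position differs the read is
#' a `5p_shift`, if only the 3' end position differs a `3p_shift`, and
#' `both_shift` otherwise. Reads assigned to non-miRNA libraries are
#' `not_applicable`.
#'
#' @param seq Read sequence(s).
#' @param feature_id Feature the read was assigned to.
#' @param start_offset 0-based position of the read within the reference
#'   entry.
#' @param library The miRNA [ref_library()] carrying the canonical region
#'   annotation.
#' @return Character vector of isomiR classes.
#' @export
classify_isomir <- function(seq, feature_id, start_offset, library) {
  stopifnot(inherits(library, "ref_library"))
  if (library$rna_class != "miRNA") {
    return(rep("not_applicable", length(seq)))
  }
  i <- match(feature_id, library$ids)
  if (anyNA(i)) stop("unknown feature_id for library", call. = FALSE)
  canon <- substr(library$seqs[i], library$canonical_start[i],
                  library$canonical_end[i])
  five_same <- start_offset == library$canonical_start[i] - 1L
  three_same <- start_offset + nchar(seq) == library$canonical_end[i]
  cls <- ifelse(seq == canon, "canonical",
         ifelse(five_same & !three_same, "3p_shift",
         ifelse(!five_same & three_same, "5p_shift", "both_shift")))
  cls
}

#' Annotate collapsed reads through the library cascade
#'
#' Each unique sequence is tested against the libraries in order and
#' assigned to the best hit (fewest mismatches, then library entry order,
#' then leftmost offset) of the first library with any hit; sequences with
#' no hit anywhere are reported as unassigned. Per-feature counts are sums
#' of the multiplicities of their assigned sequences, so class totals plus
#' the unassigned total always equal the number of input reads.
#'
#' @param reads A collapsed read data frame (`seq`, `multiplicity`) from
#'   [collapse_reads()], a read data frame, or a character vector of
#'   sequences (collapsed automatically).
#' @param config A [cascade_config()].
#' @return A list of class `annotation` with elements `assignments` (one
#'   row per unique sequence: class, feature, offset, mismatches, isomiR
#'   class or `unassigned`), `counts` (single-sample count table columns
#'   `feature_id`, `rna_class`, `count`) and `summary` (per-library read
#'   totals plus `unassigned`, in cascade order).
#' @export
cascade_annotate <- function(reads, config) {
  stopifnot(inherits(config, "cascade_config"))
  if (is.character(reads) || !("multiplicity" %in% names(reads))) {
    reads <- collapse_reads(reads)
  }
  n_seq <- nrow(reads)
  assigned <- data.frame(
    seq = reads$seq, multiplicity = reads$multiplicity,
    rna_class = rep(NA_character_, n_seq),
    feature_id = rep(NA_character_, n_seq),
    start_offset = rep(NA_integer_, n_seq),
    mismatches = rep(NA_integer_, n_seq),
    isomir_class = rep("not_applicable", n_seq),
    stringsAsFactors = FALSE)
  remaining <- seq_len(n_seq)
  lib_totals <- stats::setNames(numeric(length(config$libraries)),
                                names(config$libraries))
  for (li in seq_along(config$libraries)) {
    if (!length(remaining)) break
    lib <- config$libraries[[li]]
    best <- cpp_map_best(reads$seq[remaining], lib$seqs,
                         config$max_mismatches[li])
    hit <- best[, "ref"] > 0L
    if (any(hit)) {
      rows <- remaining[hit]
      assigned$rna_class[rows] <- lib$rna_class
      assigned$feature_id[rows] <- lib$ids[best[hit, "ref"]]
      assigned$start_offset[rows] <- best[hit, "start"]
      assigned$mismatches[rows] <- best[hit, "mismatches"]
      if (lib$rna_class == "miRNA") {
        assigned$isomir_class[rows] <- classify_isomir(
          assigned$seq[rows], assigned$feature_id[rows],
          assigned$start_offset[rows], lib)
      }
      lib_totals[li] <- sum(assigned$multiplicity[rows])
      remaining <- remaining[!hit]
    }
  }
  assigned$rna_class[is.na(assigned$rna_class)] <- "unassigned"
  hit_rows <- assigned$rna_class != "unassigned"
  counts <- if (any(hit_rows)) {
    agg <- stats::aggregate(multiplicity ~ feature_id + rna_class,
                            data = assigned[hit_rows, ], FUN = sum)
    # restore library/cascade order
    key <- unlist(lapply(config$libraries, function(l) l$ids), use.names = FALSE)
    agg <- agg[order(match(agg$feature_id, key)), ]
    data.frame(feature_id = agg$feature_id, rna_class = agg$rna_class,
               count = as.numeric(agg$multiplicity), stringsAsFactors = FALSE)
  } else {
    data.frame(feature_id = character(), rna_class = character(),
               count = numeric(), stringsAsFactors = FALSE)
  }
  rownames(counts) <- NULL
  summary <- data.frame(
    library = c(names(config$libraries), "unassigned"),
    rna_class = c(vapply(config$libraries, function(l) l$rna_class,
                         character(1)), "unassigned"),
    reads = c(as.numeric(lib_totals),
              sum(assigned$multiplicity[!hit_rows])),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(assignments = assigned, counts = counts, summary = summary),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat("<annotation>\n")
  print(x$summary)
  invisible(x)
}

#' Merge single-sample annotation counts into a count table
#'
#' Features absent from a sample receive count 0.
#'
#' @param counts_list Named list of single-sample count data frames
#'   (`feature_id`, `rna_class`, `count`), e.g. the `counts` element of
#'   [cascade_annotate()] results. Names become sample names.
#' @return A count table data frame (see [count_table()]).
#' @export
merge_sample_counts <- function(counts_list) {
  stopifnot(length(counts_list) >= 1L, !is.null(names(counts_list)))
  feats <- unique(do.call(rbind, lapply(counts_list, function(x) {
    x[, c("feature_id", "rna_class")]
  })))
  if (anyDuplicated(feats$feature_id)) {
    stop("a feature_id maps to more than one rna_class across samples",
         call. = FALSE)
  }
  out <- feats
  for (nm in names(counts_list)) {
    x <- counts_list[[nm]]
    out[[nm]] <- x$count[match(feats$feature_id, x$feature_id)]
    out[[nm]][is.na(out[[nm]])] <- 0
  }
  validate_count_table(out)
}
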