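# Count filtering and correction-factor fold-changes: removing noise and
# low-information features before differential expression, and damping
# fold-changes of low-count features with an additive median correction.

#' Filter features by a minimum read count
#'
#' A feature counts as expressed in a sample iff its count is at least `c`
#' (inclusive). A feature row is dropped from the table only when it is
#' below the cutoff in every sample.
#'
#' @param tab A count table data frame.
#' @param c Minimum read count (>= 0). `c = 0` is the identity.
#' @return The filtered count table.
#' @export
min_count_filter <- function(tab, c) {
  tab <- validate_count_table(tab)
  stopifnot(c >= 0)
  m <- count_matrix(tab)
  if (!nrow(m)) return(tab)
  keep <- apply(m >= c, 1L, any)
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentile cutoff of a sample's count distribution
#'
#' Nearest-rank percentile of the nonzero counts of one sample (zeros mean
#' "not detected" and are excluded by default). Filtering keeps counts
#' greater than or equal to the cutoff, so `q = 0` retains everything.
#'
#' @param counts Numeric vector of one sample's read counts.
#' @param q Percentile in `[0, 100]`.
#' @param include_zeros Include zero counts in the distribution.
#' @return The cutoff value.
#' @export
percentile_cutoff <- function(counts, q, include_zeros = FALSE) {
  stopifnot(q >= 0, q <= 100)
  x <- if (include_zeros) counts else counts[counts > 0]
  if (!length(x)) stop("empty or all-zero count vector", call. = FALSE)
  x <- sort(x)
  rank <- max(1L, as.integer(ceiling(q / 100 * length(x))))
  x[rank]
}

#' Filter features by a per-sample percentile cutoff
#'
#' Each sample's cutoff is the nearest-rank `q`-th percentile of its
#' nonzero counts ([percentile_cutoff()]); a feature is expressed in a
#' sample iff its count reaches that sample's cutoff, and a row is dropped
#' only when below cutoff in every sample.
#'
#' @inheritParams min_count_filter
#' @inheritParams percentile_cutoff
#' @return The filtered count table.
#' @export
percentile_filter <- function(tab, q, include_zeros = FALSE) {
  tab <- validate_count_table(tab)
  m <- count_matrix(tab)
  if (!nrow(m)) return(tab)
  cuts <- apply(m, 2L, percentile_cutoff, q = q,
                include_zeros = include_zeros)
  keep <- apply(sweep(m, 2L, cuts, ">="), 1L, any)
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correction factor for fold-change damping
#'
#' The median of all nonzero counts pooled over the samples being compared
#' (for an even pool size, the mean of the two middle values). Added to
#' both counts before forming a fold-change ratio, it pushes low-count
#' ratios toward 1 while leaving high-count ratios essentially unchanged.
#'
#' @param tab A count table data frame.
#' @param samples Optional character vector restricting the pool to these
#'   sample columns (default: all samples).
#' @param include_zeros Include zero counts in the pooled distribution.
#' @return A list of class `correction_factor` with elements `k` and
#'   `source` (`"auto_median"`).
#' @export
correction_factor <- function(tab, samples = NULL, include_zeros = FALSE) {
  tab <- validate_count_table(tab)
  m <- count_matrix(tab)
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(m))
    if (length(missing)) stop("unknown sample: ", missing[1], call. = FALSE)
    m <- m[, samples, drop = FALSE]
  }
  x <- as.numeric(m)
  if (!include_zeros) x <- x[x > 0]
  if (!length(x)) stop("no counts to compute a correction factor from",
                       call. = FALSE)
  structure(list(k = median(x), source = "auto_median"),
            class = "correction_factor")
}

#' @export
print.correction_factor <- function(x, ...) {
  cat(sprintf("<correction_factor> k = %g (%s)\n", x$k, x$source))
  invisible(x)
}

#' Signed fold-change with an additive correction factor
#'
#' Computes `r = (a + k) / (b + k)` and reports it as a signed fold-change:
#' `r` when `r >= 1` and `-1/r` otherwise, so that a threshold of 1.5 reads
#' as "<= -1.5 or >= 1.5". With counts 10 vs 5 and k = 30 the result is
#' 1.14 (reported at 2 decimals); with k = 0 it is 2.0.
#'
#' @param a Test count(s), >= 0.
#' @param b Control count(s), >= 0.
#' @param k Correction factor: a non-negative number or a
#'   [correction_factor()] object. Default 0 (no correction).
#' @return Signed fold-change(s) at full precision (round to 2 decimals for
#'   reporting). `b + k == 0` is an error.
#' @export
corrected_fold_change <- function(a, b, k = 0) {
  if (inherits(k, "correction_factor")) k <- k$k
  stopifnot(length(k) == 1L, k >= 0)
  if (any(a < 0) || any(b < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(b + k == 0)) {
    stop("fold-change undefined: control count + correction factor is 0",
         call. = FALSE)
  }
  r <- (a + k) / (b + k)
  ifelse(r >= 1, r, -1 / r)
}
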