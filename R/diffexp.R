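# No-replicate differential expression: quantile normalization, per-feature
# Fisher's exact test against library totals, Benjamini-Hochberg adjustment
# and threshold-based calling; plus sample clustering and PCA.

#' Differential expression parameters
#'
#' Defaults follow the conventional small RNA thresholds: absolute signed
#' fold-change at least 1.5 and p at most 0.05. Calling uses the raw
#' Fisher p by default; BH-adjusted p values are always computed and can be
#' used for calling with `use_adjusted_p = TRUE`.
#'
#' @param fc_threshold Fold-change threshold `t >= 1` (default 1.5).
#' @param p_threshold Significance threshold in `(0, 1]` (default 0.05).
#' @param use_adjusted_p Call on BH-adjusted instead of raw p.
#' @param correction Correction factor for fold-changes: `NULL`/"none"
#'   (k = 0), `"auto"` (median of pooled nonzero normalized counts), a
#'   number, or a [correction_factor()] object.
#' @param normalize Quantile-normalize the two columns before testing
#'   (default `TRUE`).
#' @return An object of class `de_params`.
#' @export
de_params <- function(fc_threshold = 1.5, p_threshold = 0.05,
                      use_adjusted_p = FALSE, correction = NULL,
                      normalize = TRUE) {
  stopifnot(fc_threshold >= 1, p_threshold > 0, p_threshold <= 1)
  structure(list(fc_threshold = fc_threshold, p_threshold = p_threshold,
                 use_adjusted_p = isTRUE(use_adjusted_p),
                 correction = correction, normalize = isTRUE(normalize)),
            class = "de_params")
}

qn_matrix <- function(m) {
  if (!nrow(m) || ncol(m) < 2L) return(m)
  srt <- apply(m, 2L, sort)
  mu <- rowMeans(srt)
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    pos <- integer(length(x))
    pos[order(x)] <- seq_along(x)
    # ties within a column get the mean of the rank means over their group
    out[, j] <- ave(mu[pos], x, FUN = mean)
  }
  out
}

#' Quantile-normalize a count table
#'
#' Standard rank-mean algorithm: sort each sample column, average across
#' samples at each rank, and give every value the mean for its rank; tied
#' values within a column receive the mean of the rank means over their
#' tied ranks. After normalization all columns share the same multiset of
#' values (up to tie averaging) and the grand mean is preserved.
#'
#' @param tab A count table data frame (or a bare numeric matrix).
#' @return The table with sample columns replaced by real-valued
#'   normalized counts.
#' @export
quantile_normalize <- function(tab) {
  if (is.matrix(tab)) {
    if (ncol(tab) < 2L) {
      warning("single sample: quantile normalization is the identity")
      return(tab)
    }
    return(qn_matrix(tab))
  }
  tab <- validate_count_table(tab)
  sc <- sample_columns(tab)
  if (length(sc) < 2L) {
    warning("single sample: quantile normalization is the identity")
    return(tab)
  }
  tab[, sc] <- qn_matrix(count_matrix(tab))
  tab
}

#' Two-sided Fisher's exact test for digital expression counts
#'
#' Tests the 2x2 table `[[a, N_test - a], [b, N_control - b]]` contrasting
#' one feature's counts against all other reads in each library. The
#' two-sided p is the sum of hypergeometric probabilities of all tables
#' with the same margins that are no more probable than the observed one
#' (minimum-likelihood summation). Vectorized over `a` and `b`.
#'
#' @param a Feature count(s) in the test sample.
#' @param b Feature count(s) in the control sample.
#' @param n_test,n_control Total read counts of the two samples.
#' @return Two-sided p value(s).
#' @export
fisher_test <- function(a, b, n_test, n_control) {
  k <- max(length(a), length(b))
  a <- rep_len(as.numeric(a), k)
  b <- rep_len(as.numeric(b), k)
  n_test <- rep_len(as.numeric(n_test), k)
  n_control <- rep_len(as.numeric(n_control), k)
  if (any(n_test <= 0) || any(n_control <= 0)) {
    stop("sample totals must be positive", call. = FALSE)
  }
  if (any(a < 0) || any(b < 0) || any(a > n_test) || any(b > n_control)) {
    stop("invalid margins: need 0 <= a <= n_test and 0 <= b <= n_control",
         call. = FALSE)
  }
  vapply(seq_len(k), function(i) {
    m1 <- a[i] + b[i]
    lo <- max(0, m1 - n_control[i])
    hi <- min(m1, n_test[i])
    xs <- lo:hi
    pr <- dhyper(xs, n_test[i], n_control[i], m1)
    obs <- dhyper(a[i], n_test[i], n_control[i], m1)
    # relative epsilon absorbs floating-point noise among near-tied tables
    min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p values
#'
#' @param p Numeric vector of raw p values.
#' @return Step-up adjusted p values (monotone, capped at 1).
#' @export
adjust_pvalues <- function(p) {
  p.adjust(p, method = "BH")
}

resolve_correction <- function(correction, tab_norm) {
  if (is.null(correction) || identical(correction, "none")) return(0)
  if (identical(correction, "auto")) return(correction_factor(tab_norm)$k)
  if (inherits(correction, "correction_factor")) return(correction$k)
  if (is.numeric(correction) && length(correction) == 1L && correction >= 0) {
    return(correction)
  }
  stop("invalid correction specification", call. = FALSE)
}

signed_fc_safe <- function(a, b, k) {
  zero <- (a + k) == 0 & (b + k) == 0
  r <- ifelse(zero, 1, (a + k) / pmax(b + k, .Machine$double.xmin))
  ifelse(r >= 1, r, -1 / r)
}

#' No-replicate differential expression between two samples
#'
#' Pipeline: quantile-normalize the two sample columns, round normalized
#' counts to the nearest integer (half away from zero), run a per-feature
#' two-sided [fisher_test()] against the column totals, BH-adjust, compute
#' signed fold-changes from the normalized counts with the configured
#' correction factor, and call `up`/`down`/`unchanged` by
#' `|FC| >= fc_threshold` and `p <= p_threshold`.
#'
#' @param tab A count table data frame (low-count filtering beforehand is
#'   recommended; see [min_count_filter()]).
#' @param test,control Sample column names.
#' @param params A [de_params()] object.
#' @return A data frame of class `de_result` with one row per feature
#'   (`feature_id`, `rna_class`, raw and normalized counts, `signed_fc`,
#'   `p_value`, `adj_p`, `call`) and a `summary` attribute with `n_up`,
#'   `n_down`, `n_unchanged`, `pct_unchanged` and the correction `k` used.
#' @export
differential_expression <- function(tab, test, control, params = de_params()) {
  tab <- validate_count_table(tab)
  stopifnot(inherits(params, "de_params"))
  sc <- sample_columns(tab)
  missing <- setdiff(c(test, control), sc)
  if (length(missing)) stop("unknown sample: ", missing[1], call. = FALSE)
  raw <- count_matrix(tab)[, c(test, control), drop = FALSE]
  norm <- if (params$normalize) qn_matrix(raw) else raw
  a <- round_half_up(norm[, 1L])
  b <- round_half_up(norm[, 2L])
  n_test <- sum(a)
  n_control <- sum(b)
  p <- fisher_test(a, b, n_test, n_control)
  adj <- adjust_pvalues(p)
  norm_tab <- count_table(tab$feature_id, tab$rna_class,
                          stats::setNames(data.frame(a, b), c(test, control)))
  k <- resolve_correction(params$correction, norm_tab)
  fc <- signed_fc_safe(a, b, k)
  p_call <- if (params$use_adjusted_p) adj else p
  call <- rep("unchanged", nrow(tab))
  call[fc >= params$fc_threshold & p_call <= params$p_threshold] <- "up"
  call[fc <= -params$fc_threshold & p_call <= params$p_threshold] <- "down"
  out <- data.frame(
    feature_id = tab$feature_id, rna_class = tab$rna_class,
    count_test = raw[, 1L], count_control = raw[, 2L],
    norm_test = a, norm_control = b,
    signed_fc = fc, p_value = p, adj_p = adj, call = call,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  n <- nrow(out)
  attr(out, "summary") <- list(
    n_up = sum(call == "up"), n_down = sum(call == "down"),
    n_unchanged = sum(call == "unchanged"),
    pct_unchanged = if (n) 100 * sum(call == "unchanged") / n else NA_real_,
    correction_k = k, test = test, control = control)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Summarize a differential expression result
#'
#' @param object A `de_result` from [differential_expression()].
#' @param ... Unused.
#' @return The summary list (`n_up`, `n_down`, `n_unchanged`,
#'   `pct_unchanged`, `correction_k`).
#' @method summary de_result
#' @export
summary.de_result <- function(object, ...) {
  attr(object, "summary")
}

#' Average-linkage clustering of samples by expression profile
#'
#' Distance is 1 minus the Pearson correlation between sample columns
#' (identical profiles merge at 0; perfectly anticorrelated profiles are at
#' distance 2); linkage is average by default. The merge order is
#' deterministic.
#'
#' @param tab A count table with at least two samples.
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return A list with `hclust` (the tree), `order` (leaf order, sample
#'   names), `newick` (Newick text of the dendrogram) and `matrix` (the
#'   feature-by-sample matrix with columns in leaf order).
#' @export
hierarchical_cluster <- function(tab, linkage = "average") {
  tab <- validate_count_table(tab)
  m <- count_matrix(tab)
  if (ncol(m) < 2L) stop("clustering needs at least two samples", call. = FALSE)
  cc <- cor(m)
  if (anyNA(cc)) stop("constant sample column: correlation undefined",
                      call. = FALSE)
  hc <- hclust(as.dist(1 - cc), method = linkage)
  newick <- ape::write.tree(ape::as.phylo(hc))
  ord <- hc$labels[hc$order]
  list(hclust = hc, order = ord, newick = newick,
       matrix = m[, ord, drop = FALSE])
}

#' Principal component analysis of samples
#'
#' PCA of the sample-by-feature matrix after centering features.
#'
#' @param tab A count table with at least two samples.
#' @return A list with `coordinates` (samples x components data frame) and
#'   `variance_fraction` (per component; sums to at most 1, all zero for a
#'   constant matrix).
#' @export
pca_samples <- function(tab) {
  tab <- validate_count_table(tab)
  m <- count_matrix(tab)
  if (ncol(m) < 2L) stop("PCA needs at least two samples", call. = FALSE)
  x <- t(m)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  vf <- if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev))
  coords <- as.data.frame(pc$x)
  coords <- cbind(data.frame(sample = rownames(pc$x),
                             stringsAsFactors = FALSE), coords)
  rownames(coords) <- NULL
  list(coordinates = coords, variance_fraction = vf)
}
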