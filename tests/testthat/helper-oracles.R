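# Independent brute-force oracles used to validate the fast implementations.
# These deliberately use different machinery (utils::adist, lchoose,
# character-vector scans) than the package code paths they check.

# Enumerates every (start, matched-length, segment) candidate of the 3'
# adapter matching contract and returns the winner under the (errors,
# 5'-most start, adapter order) tie-break. `keep` is the number of 5'
# bases retained (0-based trim start).
trim_oracle <- function(seq, adapters, e, o) {
  n <- nchar(seq)
  s2 <- chartr("N", "n", seq) # N must mismatch everything (adapters are ACGT)
  best <- NULL
  better <- function(E, st, k) {
    is.null(best) || E < best$E ||
      (E == best$E && (st < best$st || (st == best$st && k < best$k)))
  }
  for (k in seq_along(adapters)) {
    A <- adapters[k]
    m <- nchar(A)
    if (n == 0) next
    prefixes <- substring(A, 1, seq_len(m))
    suffixes <- substring(s2, seq_len(n), n)
    db <- utils::adist(prefixes, suffixes) # m x n edit distances
    for (st in seq_len(n)) {
      for (L in seq_len(m)) {
        if (L < o) next
        E <- db[L, st]
        if (E <= floor(e * L + 1e-9) && better(E, st - 1L, k)) {
          best <- list(E = E, st = st - 1L, k = k)
        }
      }
      if (m >= o) {
        segs <- substring(s2, st, (st - 1):n) # every prefix of the suffix
        E <- min(utils::adist(A, segs))
        if (E <= floor(e * m + 1e-9) && better(E, st - 1L, k)) {
          best <- list(E = E, st = st - 1L, k = k)
        }
      }
    }
  }
  if (is.null(best)) {
    list(found = FALSE, keep = n, errors = 0L, adapter = NA_integer_)
  } else {
    list(found = TRUE, keep = best$st, errors = as.integer(best$E),
         adapter = best$k)
  }
}

# Two-sided Fisher p by direct enumeration of all 2x2 tables with the
# observed margins, probabilities from log-binomial coefficients.
fisher_oracle <- function(a, b, n_test, n_control) {
  m1 <- a + b
  xs <- max(0, m1 - n_control):min(m1, n_test)
  logp <- lchoose(n_test, xs) + lchoose(n_control, m1 - xs) -
    lchoose(n_test + n_control, m1)
  pr <- exp(logp)
  obs <- pr[xs == a]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# All substring occurrences of `query` within `refs` with <= max_mm
# substitutions, as a naive character-vector scan.
naive_hamming_scan <- function(query, refs, max_mm) {
  qv <- strsplit(query, "")[[1]]
  q <- length(qv)
  out <- list()
  for (r in seq_along(refs)) {
    rv <- strsplit(refs[r], "")[[1]]
    L <- length(rv)
    if (q > L) next
    for (st in 0:(L - q)) {
      w <- rv[(st + 1):(st + q)]
      d <- sum(qv != w | qv == "N" | w == "N")
      if (d <= max_mm) {
        out[[length(out) + 1L]] <- c(ref = r, start = st, mm = d)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(ref = integer(), start = integer(), mm = integer()))
  }
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$mm), , drop = FALSE] # stable radix sort keeps (ref, start) order
}

# Naive position-by-position scan for the three canonical seed-site types,
# with motif construction via a lookup-table reverse complement and the
# 8mer > 7mer-m8 > 7mer-A1 precedence applied per locus.
naive_seed_scan <- function(utr, mirna_seq,
                            types = c("8mer", "7mer-m8", "7mer-A1")) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc1 <- function(s) paste(rev(unname(comp[strsplit(s, "")[[1]]])),
                           collapse = "")
  m8 <- rc1(substr(mirna_seq, 2, 8))
  e8 <- paste0(m8, "A")
  a1 <- paste0(rc1(substr(mirna_seq, 2, 7)), "A")
  n <- nchar(utr)
  starts_of <- function(mot) {
    w <- nchar(mot)
    if (n < w) return(integer())
    p <- seq_len(n - w + 1L)
    p[substring(utr, p, p + w - 1L) == mot]
  }
  s8 <- if ("8mer" %in% types) starts_of(e8) else integer()
  s7m8 <- if ("7mer-m8" %in% types) setdiff(starts_of(m8), s8) else integer()
  s7a1 <- if ("7mer-A1" %in% types) {
    h <- starts_of(a1)
    h[!(h - 1L) %in% s8]
  } else integer()
  df <- rbind(
    data.frame(site_type = rep("8mer", length(s8)),
               start = as.integer(s8) - 1L),
    data.frame(site_type = rep("7mer-m8", length(s7m8)),
               start = as.integer(s7m8) - 1L),
    data.frame(site_type = rep("7mer-A1", length(s7a1)),
               start = as.integer(s7a1) - 1L))
  ord <- c("8mer" = 1L, "7mer-m8" = 2L, "7mer-A1" = 3L)
  df <- df[order(df$start, ord[df$site_type]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

random_dna <- function(n, len) {
  vapply(rep_len(len, n), function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}
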