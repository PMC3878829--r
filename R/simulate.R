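# Seeded synthetic-data generator: reference libraries, read libraries with
# known class composition, adapter contamination and sequencing errors, and
# the matching ground truth, so every pipeline stage is testable offline.

#' Simulation profile
#'
#' Defines the conditions of a simulated small RNA sequencing library. The
#' defaults emulate a proliferating human cell line library: a
#' miRNA-dominated class composition (about 57% miRNA, small tRNA/rRNA/
#' mRNA-fragment and piRNA fractions, the remainder unassignable
#' background), strongly skewed within-class abundances (log-normal,
#' sdlog 1.5), a standard TruSeq small RNA 3' adapter, 36 nt reads and a
#' 0.5% per-base substitution error rate.
#'
#' @param rng_seed Integer seed governing all randomness.
#' @param n_reads Number of reads per library.
#' @param read_length Fixed sequencing read length (nt).
#' @param class_fractions Named fractions per RNA class (sum <= 1; the
#'   remainder becomes unassignable random background reads).
#' @param n_features Named feature counts per class.
#' @param adapter 3' adapter sequence appended to every fragment.
#' @param read_error_rate Per-base substitution probability in `[0, 0.2]`.
#' @param abundance_sdlog Log-normal sdlog of within-class feature
#'   abundances.
#' @param isomir_3p_fraction Fraction of miRNA reads carrying a 1-2 nt 3'
#'   trimming (3' isomiRs).
#' @param base_quality Constant Phred quality assigned to every base.
#' @param mature_length_probs Mature miRNA length distribution (names are
#'   lengths 20-24).
#' @param fragment_length_range Length range of fragments sampled from
#'   long references (tRNA/rRNA/mRNA/other).
#' @return An object of class `sim_profile`.
#' @export
sim_profile <- function(rng_seed = 1L,
                        n_reads = 50000L,
                        read_length = 36L,
                        class_fractions = c(miRNA = 0.570, tRNA = 0.004,
                                            rRNA = 0.022, mRNA = 0.096,
                                            piRNA = 0.004),
                        n_features = c(miRNA = 60L, tRNA = 20L, rRNA = 4L,
                                       mRNA = 40L, piRNA = 20L),
                        adapter = "TGGAATTCTCGGGTGCCAAGG",
                        read_error_rate = 0.005,
                        abundance_sdlog = 1.5,
                        isomir_3p_fraction = 0.1,
                        base_quality = 40L,
                        mature_length_probs = c("20" = 0.05, "21" = 0.20,
                                                "22" = 0.50, "23" = 0.20,
                                                "24" = 0.05),
                        fragment_length_range = c(18L, 30L)) {
  stopifnot(all(names(class_fractions) %in% RNA_CLASSES),
            all(class_fractions >= 0), sum(class_fractions) <= 1,
            all(names(n_features) %in% RNA_CLASSES),
            read_error_rate >= 0, read_error_rate <= 0.2,
            read_length >= 15L)
  n_features <- n_features[n_features > 0]
  class_fractions <- class_fractions[names(class_fractions) %in%
                                       names(n_features)]
  structure(list(rng_seed = as.integer(rng_seed),
                 n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 class_fractions = class_fractions,
                 n_features = n_features,
                 adapter = normalize_seq(adapter),
                 read_error_rate = read_error_rate,
                 abundance_sdlog = abundance_sdlog,
                 isomir_3p_fraction = isomir_3p_fraction,
                 base_quality = as.integer(base_quality),
                 mature_length_probs = mature_length_probs,
                 fragment_length_range = as.integer(fragment_length_range)),
            class = "sim_profile")
}

# Minimum Hamming distance over all alignments of the shorter sequence as a
# window within the longer one.
min_window_hamming <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av)
  offs <- 0:(length(bv) - la)
  min(vapply(offs, function(o) sum(av != bv[(o + 1):(o + la)]), numeric(1)))
}

class_lengths <- function(class, n, profile) {
  switch(class,
    miRNA = sample(as.integer(names(profile$mature_length_probs)), n,
                   replace = TRUE, prob = profile$mature_length_probs),
    piRNA = sample(26:31, n, replace = TRUE),
    tRNA = sample(70:80, n, replace = TRUE),
    rRNA = sample(120:160, n, replace = TRUE),
    mRNA = sample(250:350, n, replace = TRUE),
    other = sample(60:100, n, replace = TRUE))
}

#' Simulate reference libraries and within-class abundance profiles
#'
#' Generates one random reference library per class with class-typical
#' lengths (mature miRNA 20-24 nt, piRNA 26-31 nt, tRNA about 75 nt,
#' rRNA/mRNA longer). Generated miRNAs are rejection-sampled so that every
#' pair is at least 3 mismatches apart under sliding Hamming comparison,
#' keeping cascade assignment unambiguous at up to 1 allowed mismatch.
#' Fully deterministic under the profile seed.
#'
#' @param profile A [sim_profile()].
#' @return An object of class `sim_references`: a list with `libraries`
#'   (named list of [ref_library()] in cascade order) and `abundances`
#'   (named list of per-feature expected within-class fractions, each
#'   summing to 1).
#' @export
simulate_references <- function(profile) {
  stopifnot(inherits(profile, "sim_profile"))
  with_seed(profile$rng_seed, {
    classes <- intersect(RNA_CLASSES, names(profile$n_features))
    libraries <- list()
    abundances <- list()
    for (cl in classes) {
      n <- profile$n_features[[cl]]
      lens <- class_lengths(cl, n, profile)
      seqs <- character(n)
      for (i in seq_len(n)) {
        for (try in seq_len(1000L)) {
          cand <- random_seq(lens[i])
          if (cl != "miRNA" || i == 1L ||
              min(vapply(seqs[seq_len(i - 1L)], min_window_hamming,
                         numeric(1), b = cand)) >= 3) {
            seqs[i] <- cand
            break
          }
        }
        if (!nchar(seqs[i])) {
          stop("could not generate sufficiently distinct miRNA sequences",
               call. = FALSE)
        }
      }
      ids <- sprintf("sim-%s-%03d", tolower(cl), seq_len(n))
      libraries[[cl]] <- ref_library(paste0("sim_", cl), cl, ids, seqs)
      w <- rlnorm(n, meanlog = 0, sdlog = profile$abundance_sdlog)
      abundances[[cl]] <- stats::setNames(w / sum(w), ids)
    }
    structure(list(libraries = libraries, abundances = abundances),
              class = "sim_references")
  })
}

inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  idx <- which(nerr > 0L)
  for (i in idx) {
    v <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(lens[i], nerr[i])
    for (p in pos) v[p] <- sample(setdiff(BASES, v[p]), 1L)
    seqs[i] <- paste(v, collapse = "")
  }
  seqs
}

fragment_for_feature <- function(class, refseq, n, profile) {
  if (class == "miRNA") {
    frag <- rep(refseq, n)
    iso <- runif(n) < profile$isomir_3p_fraction
    trim_n <- integer(n)
    trim_n[iso] <- sample(1:2, sum(iso), replace = TRUE)
    substr(frag, 1L, nchar(refseq) - trim_n)
  } else if (class == "piRNA") {
    rep(refseq, n)
  } else {
    lo <- profile$fragment_length_range[1]
    hi <- min(profile$fragment_length_range[2], nchar(refseq))
    fl <- sample(seq.int(lo, hi), n, replace = TRUE)
    st <- vapply(fl, function(l) sample.int(nchar(refseq) - l + 1L, 1L),
                 integer(1))
    substr(rep(refseq, n), st, st + fl - 1L)
  }
}

#' Simulate a FASTQ read library with ground truth
#'
#' Each read is a feature (sub)sequence followed by the 3' adapter,
#' truncated to the read length, with per-base substitution errors applied
#' at the profile's error rate. Features are drawn from a multinomial over
#' class fractions times within-class abundances, optionally scaled by
#' per-feature condition multipliers; the unallocated class fraction
#' produces uniform random background reads that exercise the unassigned
#' path of the cascade.
#'
#' @param profile A [sim_profile()].
#' @param refs A [simulate_references()] result.
#' @param condition_effects Optional named numeric vector of per-feature
#'   abundance multipliers (fold-change effects).
#' @param sample_name Sample name used in read ids.
#' @param seed RNG seed for read sampling (default: the profile seed).
#' @return A list with `reads` (read data frame), `truth_reads` (per-read
#'   true class and feature; background reads have class `"background"`)
#'   and `truth_counts` (per-feature true read counts, including zeros).
#' @export
simulate_reads <- function(profile, refs, condition_effects = NULL,
                           sample_name = "sample",
                           seed = profile$rng_seed) {
  stopifnot(inherits(profile, "sim_profile"),
            inherits(refs, "sim_references"))
  with_seed(seed, {
    classes <- names(refs$libraries)
    feat <- do.call(rbind, lapply(classes, function(cl) {
      lib <- refs$libraries[[cl]]
      cf <- if (cl %in% names(profile$class_fractions)) {
        profile$class_fractions[[cl]]
      } else 0
      data.frame(feature_id = lib$ids, rna_class = cl, seq = lib$seqs,
                 weight = cf * refs$abundances[[cl]][lib$ids],
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(condition_effects)) {
      hit <- match(names(condition_effects), feat$feature_id)
      if (anyNA(hit)) {
        stop("condition effect names unknown: ",
             names(condition_effects)[is.na(hit)][1], call. = FALSE)
      }
      feat$weight[hit] <- feat$weight[hit] * condition_effects
    }
    bg_weight <- max(0, 1 - sum(profile$class_fractions))
    w <- c(feat$weight, bg_weight)
    counts <- as.integer(rmultinom(1L, profile$n_reads, w))
    nf <- nrow(feat)
    frag_list <- vector("list", nf + 1L)
    for (i in seq_len(nf)) {
      if (counts[i] > 0L) {
        frag_list[[i]] <- fragment_for_feature(feat$rna_class[i],
                                               feat$seq[i], counts[i],
                                               profile)
      }
    }
    n_bg <- counts[nf + 1L]
    if (n_bg > 0L) {
      lo <- profile$fragment_length_range[1]
      hi <- max(profile$fragment_length_range)
      frag_list[[nf + 1L]] <- random_seq(sample(seq.int(lo, hi), n_bg,
                                                replace = TRUE))
    }
    frags <- unlist(frag_list, use.names = FALSE) %||% character()
    truth_class <- rep(c(feat$rna_class, "background"), counts)
    truth_feature <- rep(c(feat$feature_id, NA_character_), counts)
    # fragment + adapter (repeated if needed), truncated to read length
    pad <- strrep(profile$adapter,
                  ceiling(profile$read_length / nchar(profile$adapter)) + 1L)
    seqs <- substr(paste0(frags, pad), 1L, profile$read_length)
    seqs <- inject_errors(seqs, profile$read_error_rate)
    n <- length(seqs)
    ord <- sample.int(n)
    seqs <- seqs[ord]
    truth_class <- truth_class[ord]
    truth_feature <- truth_feature[ord]
    ids <- sprintf("%s_r%06d", sample_name, seq_len(n))
    qual <- strrep(intToUtf8(profile$base_quality + 33L),
                   profile$read_length)
    reads <- data.frame(read_id = ids, seq = seqs,
                        qual = rep(qual, n), stringsAsFactors = FALSE)
    truth_reads <- data.frame(read_id = ids, rna_class = truth_class,
                              feature_id = truth_feature,
                              stringsAsFactors = FALSE)
    truth_counts <- data.frame(feature_id = feat$feature_id,
                               rna_class = feat$rna_class,
                               true_count = counts[seq_len(nf)],
                               stringsAsFactors = FALSE)
    list(reads = reads, truth_reads = truth_reads,
         truth_counts = truth_counts)
  })
}

#' Simulate a two-condition experiment with known fold-changes
#'
#' Draws a test and a control library from the same reference set; the
#' test library applies the given per-feature abundance multipliers. The
#' two libraries use distinct sub-seeds derived from the profile seed.
#'
#' @param profile A [sim_profile()].
#' @param condition_effects Named numeric vector of per-feature fold
#'   multipliers applied to the test condition.
#' @param refs Optional pre-built [simulate_references()] result.
#' @return A list with `references`, `test`, `control` (each a
#'   [simulate_reads()] result) and `truth` (per-feature true counts in
#'   both conditions and the true fold multiplier).
#' @export
simulate_experiment <- function(profile, condition_effects = NULL,
                                refs = NULL) {
  stopifnot(inherits(profile, "sim_profile"))
  refs <- refs %||% simulate_references(profile)
  test <- simulate_reads(profile, refs, condition_effects,
                         sample_name = "test", seed = profile$rng_seed + 1L)
  control <- simulate_reads(profile, refs, NULL, sample_name = "control",
                            seed = profile$rng_seed + 2L)
  truth <- test$truth_counts
  names(truth)[names(truth) == "true_count"] <- "true_count_test"
  truth$true_count_control <-
    control$truth_counts$true_count[match(truth$feature_id,
                                          control$truth_counts$feature_id)]
  truth$true_multiplier <- 1
  if (!is.null(condition_effects)) {
    hit <- match(names(condition_effects), truth$feature_id)
    truth$true_multiplier[hit] <- condition_effects
  }
  list(references = refs, test = test, control = control, truth = truth)
}
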