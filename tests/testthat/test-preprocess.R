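test_that("exact adapter occurrences are removed from the 3' end", {
  spec <- adapter_spec("TGGAATTCTCGG", max_error_rate = 0)
  res <- trim_adapter(make_reads("ACGTACGTTGGAATTCTCGG"), spec)
  expect_true(res$adapter_found)
  expect_equal(res$reads$seq, "ACGTACGT")
  expect_equal(res$reads$qual, "IIIIIIII")
  expect_equal(res$trimmed_bases, 12L)
  expect_equal(res$errors_in_match, 0L)

  none <- trim_adapter(make_reads("ACGTACGTACGTACGT"), spec)
  expect_false(none$adapter_found)
  expect_equal(none$reads$seq, "ACGTACGTACGTACGT")
  expect_equal(none$trimmed_bases, 0L)
})

test_that("error-tolerant matching admits floor(e*L) errors", {
  # one substitution inside a full 12-base adapter occurrence
  spec <- adapter_spec("TGGAATTCTCGG", max_error_rate = 0.1, min_overlap = 3)
  res <- trim_adapter("AAAACCCCTGGAATTCTGGG", spec)
  expect_true(res$adapter_found)
  expect_equal(res$errors_in_match, 1L)
  expect_equal(res$reads, c("AAAACCCC"))
  # the same read is untouched at e = 0
  strict <- trim_adapter("AAAACCCCTGGAATTCTGGG",
                         adapter_spec("TGGAATTCTCGG", max_error_rate = 0))
  expect_false(strict$adapter_found)
})

test_that("trimming agrees with the brute-force enumeration oracle", {
  set.seed(42)
  adapters <- c("TGGAATTCTCGG", "AGATCGGAAGAG")
  for (e in c(0, 0.1, 0.2)) {
    spec <- adapter_spec(adapters, max_error_rate = e, min_overlap = 3)
    for (i in 1:60) {
      n <- sample(8:40, 1)
      seq <- random_dna(1, n)
      # implant an adapter prefix with occasional errors in half the reads
      if (i %% 2 == 0) {
        ad <- sample(adapters, 1)
        pos <- sample(seq_len(max(1, n - 6)), 1)
        piece <- substr(ad, 1, min(nchar(ad), n - pos + 1))
        seq <- paste0(substr(seq, 1, pos - 1), piece)
        seq <- substr(paste0(seq, random_dna(1, n)), 1, n)
      }
      if (i %% 7 == 0) { # sprinkle an N
        p <- sample(nchar(seq), 1)
        substr(seq, p, p) <- "N"
      }
      got <- trim_adapter(seq, spec)
      want <- trim_oracle(seq, adapters, e, 3)
      expect_equal(unname(got$adapter_found), want$found, info = seq)
      expect_equal(nchar(got$reads), want$keep, info = seq)
      if (want$found) {
        expect_equal(unname(got$errors_in_match), want$errors, info = seq)
        expect_equal(unname(got$adapter), want$adapter, info = seq)
      }
    }
  }
})

test_that("trimming never lengthens a read and is deterministic", {
  set.seed(7)
  spec <- adapter_spec("TGGAATTCTCGG", max_error_rate = 0.1)
  seqs <- random_dna(50, sample(15:40, 50, replace = TRUE))
  r1 <- trim_adapter(seqs, spec)
  r2 <- trim_adapter(seqs, spec)
  expect_identical(r1, r2)
  expect_true(all(nchar(r1$reads) <= nchar(seqs)))
  expect_true(all(nchar(r1$reads) + r1$trimmed_bases == nchar(seqs)))
})

test_that("quality filter keeps reads at or above the mean threshold", {
  reads <- make_reads(c("ACGT", "ACGT", "ACGT"))
  reads$qual <- c("IIII", "####", strrep(intToUtf8(20 + 33), 4)) # Q40, Q2, Q20
  expect_equal(quality_filter(reads, 20), c(TRUE, FALSE, TRUE))
})

test_that("length filter uses an inclusive 15 nt default cutoff", {
  reads <- make_reads(c(strrep("A", 14), strrep("C", 15), ""))
  expect_equal(length_filter(reads), c(FALSE, TRUE, FALSE))
})

test_that("collapsing preserves total read count and first-seen order", {
  col <- collapse_reads(c("ACG", "ACG", "CGT"))
  expect_equal(col$seq, c("ACG", "CGT"))
  expect_equal(col$multiplicity, c(2L, 1L))
  expect_equal(nrow(collapse_reads(character())), 0L)
  distinct <- collapse_reads(random_dna(20, 25))
  expect_true(all(distinct$multiplicity == 1L))
  expect_equal(sum(distinct$multiplicity), 20L)
})

test_that("length distribution counts sum to the number of reads", {
  d <- length_distribution(c("AAAA", "CCCC", "GG"))
  expect_equal(sum(d$count), 3L)
  expect_equal(d$count[d$length == 4], 2L)
  same <- length_distribution(rep(strrep("A", 22), 3))
  expect_equal(same, data.frame(length = 22L, count = 3L))
})

test_that("preprocess report partitions the input exactly", {
  spec <- adapter_spec("TGGAATTCTCGG", max_error_rate = 0.1)
  reads <- make_reads(c(
    paste0(strrep("ACGT", 5), "TGGAATTCTCGG"), # kept, trimmed to 20 nt
    paste0("ACGTACG", "TGGAATTCTCGG"),         # 7 nt after trim -> short
    strrep("ACGT", 5)))                        # kept, untrimmed
  reads$qual[3] <- strrep("#", 20)             # Q2 -> low quality
  pp <- preprocess_reads(reads, spec)
  rep <- pp$report
  expect_equal(rep$n_input, 3L)
  expect_equal(rep$n_kept, 1L)
  expect_equal(rep$n_discarded_short, 1L)
  expect_equal(rep$n_discarded_quality, 1L)
  expect_equal(rep$n_input,
               rep$n_kept + rep$n_discarded_short + rep$n_discarded_quality)
  expect_equal(sum(rep$length_histogram$count), rep$n_kept)
})
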