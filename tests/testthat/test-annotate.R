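test_that("map_read reports hits sorted by mismatches, entry order, offset", {
  lib <- ref_library("l", "miRNA", c("a", "b"),
                     c("TGAGGTAGTAGGTTGTATAGTT", "TGAGGTAGTAGGTTG"))
  hit <- map_read("TGAGGTAGTAGG", lib, 0)
  expect_equal(hit$feature_id, c("a", "b"))
  expect_equal(hit$start_offset, c(0L, 0L))
  expect_equal(hit$mismatches, c(0L, 0L))
  expect_equal(nrow(map_read("CCCCCCCCCCCC", lib, 0)), 0L)
  # read longer than every reference
  expect_equal(nrow(map_read(strrep("A", 30), lib, 2)), 0L)
})

test_that("map_read equals the naive Hamming scan on random instances", {
  set.seed(11)
  refs <- random_dna(50, sample(40:60, 50, replace = TRUE))
  lib <- ref_library("rand", "mRNA", sprintf("f%02d", 1:50), refs)
  for (i in 1:40) {
    if (i %% 2 == 0) {
      # plant the query inside a reference so hits actually occur
      r <- sample(50, 1)
      st <- sample(nchar(refs[r]) - 19, 1)
      query <- substr(refs[r], st, st + 19)
      if (i %% 4 == 0) {
        p <- sample(20, 1)
        substr(query, p, p) <- "T"
      }
    } else {
      query <- random_dna(1, 20)
    }
    got <- map_read(query, lib, 1)
    want <- naive_hamming_scan(query, refs, 1)
    expect_equal(got$feature_id, lib$ids[want$ref])
    expect_equal(got$start_offset, want$start)
    expect_equal(got$mismatches, want$mm)
  }
})

test_that("cascade assigns each sequence to the first library with a hit", {
  mir <- ref_library("mir", "miRNA", "mir-1", "TGAGGTAGTAGGTTGTATAGTT")
  # the same mature sequence also occurs inside a piRNA reference
  pir <- ref_library("pir", "piRNA", "pir-1",
                     paste0("TGAGGTAGTAGGTTGTATAGTT", "ACCGGTA"))
  cfg <- cascade_config(list(mir, pir))
  ann <- cascade_annotate(c("TGAGGTAGTAGGTTGTATAGTT", "GGGGGGGGGGGGGGGGGGGG"),
                          cfg)
  expect_equal(ann$assignments$rna_class, c("miRNA", "unassigned"))
  expect_equal(ann$assignments$feature_id[1], "mir-1")
  expect_equal(ann$summary$reads, c(1, 0, 1))
  expect_equal(sum(ann$summary$reads), 2)
})

test_that("cascade totals partition the input reads exactly", {
  profile <- sim_profile(rng_seed = 5, n_reads = 4000)
  refs <- simulate_references(profile)
  sim <- simulate_reads(profile, refs, sample_name = "s", seed = 6)
  pp <- preprocess_reads(sim$reads, adapter_spec(profile$adapter))
  col <- collapse_reads(pp$reads)
  ann <- cascade_annotate(col, cascade_config(refs$libraries))
  expect_equal(sum(ann$summary$reads), sum(col$multiplicity))
  expect_equal(sum(ann$counts$count) +
                 ann$summary$reads[ann$summary$library == "unassigned"],
               sum(col$multiplicity))
  # single assignment: no sequence in two classes
  expect_false(anyDuplicated(ann$assignments$seq) > 0)
})

test_that("raising the mismatch budget never shrinks class totals", {
  profile <- sim_profile(rng_seed = 9, n_reads = 3000, read_error_rate = 0.02)
  refs <- simulate_references(profile)
  sim <- simulate_reads(profile, refs, sample_name = "s", seed = 10)
  pp <- preprocess_reads(sim$reads, adapter_spec(profile$adapter))
  col <- collapse_reads(pp$reads)
  a0 <- cascade_annotate(col, cascade_config(refs$libraries, 0))
  a1 <- cascade_annotate(col, cascade_config(refs$libraries, 1))
  cls <- setdiff(a0$summary$library, "unassigned")
  t0 <- a0$summary$reads[match(cls, a0$summary$library)]
  t1 <- a1$summary$reads[match(cls, a1$summary$library)]
  expect_true(all(t1 >= t0))
  expect_lte(a1$summary$reads[a1$summary$library == "unassigned"],
             a0$summary$reads[a0$summary$library == "unassigned"])
})

test_that("isomiR classes follow the end-shift definitions", {
  mature <- "TGAGGTAGTAGGTTGTATAGTT"
  lib <- ref_library("mir", "miRNA", "mir-1", mature)
  expect_equal(classify_isomir(mature, "mir-1", 0L, lib), "canonical")
  # canonical minus last base: same 5' start, shorter 3' end
  expect_equal(classify_isomir(substr(mature, 1, 21), "mir-1", 0L, lib),
               "3p_shift")
  # trimmed at the 5' end only
  expect_equal(classify_isomir(substr(mature, 2, 22), "mir-1", 1L, lib),
               "5p_shift")
  # shifted at both ends
  expect_equal(classify_isomir(substr(mature, 2, 21), "mir-1", 1L, lib),
               "both_shift")
})

test_that("isomiR windows with flanks detect 5' shifted reads", {
  mature <- "TGAGGTAGTAGGTTGTATAGTT"
  entry <- paste0("ACGTA", mature, "GGCCA") # +/- 5 nt genomic flanks
  lib <- ref_library("mir", "miRNA", "mir-1", entry,
                     canonical_start = 6L, canonical_end = 5L + nchar(mature))
  ann <- cascade_annotate(c(mature, paste0("A", mature)),
                          cascade_config(list(lib)))
  expect_equal(ann$assignments$isomir_class, c("canonical", "5p_shift"))
})

test_that("non-miRNA assignments are not isomiR-classified", {
  lib <- ref_library("t", "tRNA", "trna-1", strrep("ACGT", 20))
  ann <- cascade_annotate("ACGTACGTACGTACGT", cascade_config(list(lib)))
  expect_equal(ann$assignments$isomir_class, "not_applicable")
})

test_that("sample count merging fills absent features with zero", {
  a <- data.frame(feature_id = c("f1", "f2"), rna_class = "miRNA",
                  count = c(3, 1))
  b <- data.frame(feature_id = c("f2", "f3"), rna_class = "miRNA",
                  count = c(5, 2))
  tab <- merge_sample_counts(list(s1 = a, s2 = b))
  expect_equal(tab$feature_id, c("f1", "f2", "f3"))
  expect_equal(tab$s1, c(3, 1, 0))
  expect_equal(tab$s2, c(0, 5, 2))
})
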