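# Small in-code fixtures shared across test files.

make_reads <- function(seqs, qual_char = "I") {
  data.frame(read_id = sprintf("r%d", seq_along(seqs)), seq = seqs,
             qual = strrep(qual_char, nchar(seqs)), stringsAsFactors = FALSE)
}

write_fastq_lines <- function(lines) {
  path <- tempfile(fileext = ".fastq")
  writeLines(lines, path)
  path
}

write_fasta_lines <- function(lines) {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path)
  path
}

tiny_mirna_library <- function() {
  ref_library("mir", "miRNA",
              ids = c("mir-1", "mir-2"),
              seqs = c("TGAGGTAGTAGGTTGTATAGTT", "ACCCGTAGATCCGAACTTGTGA"))
}
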