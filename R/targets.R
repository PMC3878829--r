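# Seed-based miRNA target prediction: scanning 3'UTR sense strands for
# canonical 8mer, 7mer-m8 and 7mer-A1 seed-match sites.

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1")

#' Seed-match scanning parameters
#'
#' @param site_types Subset of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`.
#' @param min_sites_per_utr Minimum total sites for a (miRNA, UTR) pair to
#'   be reported by [predict_targets()] (default 1).
#' @return An object of class `seed_match_params`.
#' @export
seed_match_params <- function(site_types = SITE_TYPES,
                              min_sites_per_utr = 1L) {
  site_types <- match.arg(site_types, SITE_TYPES, several.ok = TRUE)
  min_sites_per_utr <- as.integer(min_sites_per_utr)
  stopifnot(min_sites_per_utr >= 1L)
  structure(list(site_types = site_types,
                 min_sites_per_utr = min_sites_per_utr),
            class = "seed_match_params")
}

#' Extract the miRNA seed sequence
#'
#' The seed is nucleotides 2-8 (1-based) from the 5' end of the mature
#' sequence; target recognition is driven by hybridization of this 7-mer
#' to the mRNA 3'UTR.
#'
#' @param mirna_seq Mature miRNA sequence(s), at least 8 nt.
#' @return 7-nt seed sequence(s).
#' @export
mirna_seed <- function(mirna_seq) {
  mirna_seq <- normalize_seq(mirna_seq)
  if (any(nchar(mirna_seq) < 8L)) {
    stop("miRNA shorter than 8 nt has no defined seed", call. = FALSE)
  }
  substr(mirna_seq, 2L, 8L)
}

#' Canonical seed-match site motifs on the mRNA sense strand
#'
#' For a mature miRNA: the 7mer-m8 motif is the reverse complement of
#' nucleotides 2-8; the 7mer-A1 motif is the reverse complement of
#' nucleotides 2-7 followed by an A; the 8mer motif is the reverse
#' complement of nucleotides 2-8 followed by an A (so its first 7 bases
#' equal the 7mer-m8 motif).
#'
#' @param mirna_seq A single mature miRNA sequence, at least 8 nt.
#' @return Named character vector with elements `8mer`, `7mer-m8`,
#'   `7mer-A1`.
#' @export
site_motifs <- function(mirna_seq) {
  stopifnot(length(mirna_seq) == 1L)
  mirna_seq <- normalize_seq(mirna_seq)
  seed7 <- mirna_seed(mirna_seq)
  seed6 <- substr(mirna_seq, 2L, 7L)
  m8 <- reverse_complement(seed7)
  c("8mer" = paste0(m8, "A"),
    "7mer-m8" = m8,
    "7mer-A1" = paste0(reverse_complement(seed6), "A"))
}

# All (possibly overlapping) 1-based start positions of `motif` in `subject`.
# fixed = TRUE keeps IUPAC codes literal, so N in the UTR never matches.
motif_starts <- function(motif, subject) {
  if (nchar(subject) < nchar(motif)) return(integer())
  Biostrings::start(Biostrings::matchPattern(motif, Biostrings::DNAString(subject),
                                             fixed = TRUE))
}

#' Find seed-match sites of one miRNA in one 3'UTR
#'
#' Scans the UTR sense strand at every position for the requested site
#' motifs. Each locus is reported once with the strongest applicable type
#' (8mer > 7mer-m8 > 7mer-A1): a 7mer-m8 start coinciding with an 8mer
#' start, or a 7mer-A1 site lying inside an 8mer site, is absorbed by the
#' 8mer. Overlapping sites at distinct loci are all reported. Coordinates
#' are 0-based on the sense strand.
#'
#' @param utr_seq 3'UTR sequence (sense strand, over \{A,C,G,T,N\}).
#' @param mirna_seq Mature miRNA sequence.
#' @param params A [seed_match_params()].
#' @param utr_id,mirna_id Identifiers copied into the result.
#' @return Data frame with columns `utr_id`, `mirna_id`, `site_type`,
#'   `start` (0-based position of the site's 5'-most base) and `site_seq`.
#' @export
find_seed_sites <- function(utr_seq, mirna_seq,
                            params = seed_match_params(),
                            utr_id = "UTR", mirna_id = "miRNA") {
  stopifnot(inherits(params, "seed_match_params"), length(utr_seq) == 1L)
  utr_seq <- normalize_seq(utr_seq)
  empty <- data.frame(utr_id = character(), mirna_id = character(),
                      site_type = character(), start = integer(),
                      site_seq = character(), stringsAsFactors = FALSE)
  if (!nchar(utr_seq)) return(empty)
  mot <- site_motifs(mirna_seq)
  types <- params$site_types
  s8 <- if ("8mer" %in% types) motif_starts(mot[["8mer"]], utr_seq) else integer()
  s7m8 <- if ("7mer-m8" %in% types) {
    setdiff(motif_starts(mot[["7mer-m8"]], utr_seq), s8)
  } else integer()
  s7a1 <- if ("7mer-A1" %in% types) {
    hits <- motif_starts(mot[["7mer-A1"]], utr_seq)
    hits[!(hits - 1L) %in% s8]
  } else integer()
  out <- rbind(
    data.frame(site_type = rep("8mer", length(s8)), start = as.integer(s8),
               len = rep(8L, length(s8)), stringsAsFactors = FALSE),
    data.frame(site_type = rep("7mer-m8", length(s7m8)),
               start = as.integer(s7m8), len = rep(7L, length(s7m8)),
               stringsAsFactors = FALSE),
    data.frame(site_type = rep("7mer-A1", length(s7a1)),
               start = as.integer(s7a1), len = rep(7L, length(s7a1)),
               stringsAsFactors = FALSE))
  if (!nrow(out)) return(empty)
  out <- out[order(out$start, match(out$site_type, SITE_TYPES)), ]
  data.frame(utr_id = utr_id, mirna_id = mirna_id,
             site_type = out$site_type,
             start = out$start - 1L,
             site_seq = substr(rep(utr_seq, nrow(out)), out$start,
                               out$start + out$len - 1L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Predict mRNA targets of a set of miRNAs by seed matching
#'
#' Scans every (miRNA, UTR) pair with [find_seed_sites()] and reports the
#' pairs with at least `min_sites_per_utr` sites.
#'
#' @param mirnas A miRNA [ref_library()] (mature sequences).
#' @param utrs A 3'UTR [ref_library()] (`rna_class` `"mRNA"`).
#' @param params A [seed_match_params()].
#' @return A data frame with one row per reported pair: `mirna_id`,
#'   `utr_id`, `n_8mer`, `n_7mer_m8`, `n_7mer_a1`, `total` and `sites`
#'   (semicolon-joined `type:start` coordinates), sorted by miRNA library
#'   order then descending total sites.
#' @export
predict_targets <- function(mirnas, utrs, params = seed_match_params()) {
  stopifnot(inherits(mirnas, "ref_library"), inherits(utrs, "ref_library"))
  rows <- list()
  for (i in seq_along(mirnas$ids)) {
    for (j in seq_along(utrs$ids)) {
      sites <- find_seed_sites(utrs$seqs[j], mirnas$seqs[i], params,
                               utr_id = utrs$ids[j],
                               mirna_id = mirnas$ids[i])
      if (nrow(sites) < params$min_sites_per_utr) next
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = mirnas$ids[i], utr_id = utrs$ids[j],
        n_8mer = sum(sites$site_type == "8mer"),
        n_7mer_m8 = sum(sites$site_type == "7mer-m8"),
        n_7mer_a1 = sum(sites$site_type == "7mer-A1"),
        total = nrow(sites),
        sites = paste(paste0(sites$site_type, ":", sites$start),
                      collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_id = character(), utr_id = character(),
                      n_8mer = integer(), n_7mer_m8 = integer(),
                      n_7mer_a1 = integer(), total = integer(),
                      sites = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$mirna_id, mirnas$ids), -out$total), ]
  rownames(out) <- NULL
  out
}
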