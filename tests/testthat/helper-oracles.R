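# Independent oracles used to cross-check the implementation.

# Smith-Waterman local alignment score by explicit Gotoh dynamic programming
# (match/mismatch, affine gaps costing open + len * ext). Independent of
# Biostrings; only for short strings.
sw_score <- function(q, s, match = 1, mismatch = -2, open = 5, ext = 2) {
  qb <- strsplit(q, "")[[1]]
  sb <- strsplit(s, "")[[1]]
  m <- length(qb); n <- length(sb)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, E[i + 1, j] - ext)
      F[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, F[i, j + 1] - ext)
      sub <- H[i, j] + if (qb[i] == sb[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, sub, E[i + 1, j + 1], F[i + 1, j + 1])
      if (H[i + 1, j + 1] > best) best <- H[i + 1, j + 1]
    }
  }
  best
}

# Naive per-pattern substring scan over reads: the reference semantics that
# scan_reads() must reproduce exactly.
naive_scan <- function(reads, index) {
  ids <- rtchimera:::normalize_read_ids(names(reads))
  seqs <- toupper(as.character(reads))
  rows <- lapply(unique(index$kmer), function(k) {
    hit <- grepl(k, seqs, fixed = TRUE)
    if (!any(hit)) return(NULL)
    tibble::tibble(read_id = ids[hit], kmer = k)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(read_id = character(0), junction_id = character(0),
                          orientation = character(0)))
  }
  out |>
    dplyr::inner_join(index, by = "kmer", relationship = "many-to-many") |>
    dplyr::distinct(read_id, junction_id, orientation) |>
    dplyr::arrange(read_id, junction_id, orientation)
}

# exact-containment oracle for the exon filter at thresholds 1.0/1.0
substring_hit_oracle <- function(junction_seqs, exon_seqs) {
  vapply(junction_seqs, function(j) {
    any(vapply(exon_seqs, function(e) grepl(j, e, fixed = TRUE), logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

random_dna_str <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
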