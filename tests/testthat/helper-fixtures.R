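# Hand-buildable annotation rows and tiny worlds used across test files.

exon_row <- function(gene, tx, chrom, start, end, strand, name = gene) {
  tibble::tibble(gene_id = gene, gene_name = name, transcript_id = tx,
                 exon_id = paste0(chrom, ":", start, "-", end, "(", strand, ")"),
                 chrom = chrom, start = as.integer(start), end = as.integer(end),
                 strand = strand, rank = NA_integer_,
                 width = as.integer(end - start + 1L))
}

# assign transcription-order ranks the way load_annotation() does
rank_exons <- function(exons) {
  exons |>
    dplyr::group_by(transcript_id) |>
    dplyr::arrange(ifelse(strand == "+", start, -start), .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

dna_set <- function(...) {
  x <- c(...)
  Biostrings::DNAStringSet(setNames(unlist(x), names(x)))
}

# deterministic 400-bp toy chromosome used by the hand-computed junction
# examples; fixed (not random) so expected slices can be written down
toy_chrom <- function(len = 400) {
  set.seed(20240101)
  s <- random_dna_str(len)
  set.seed(NULL)
  s
}

# Figure-style two-gene world: a 5-exon gene and a 4-exon gene on one
# strand, everything within the distance cap
figure_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_world(file.path(tempdir(), "figure_world"), seed = 101,
                               n_pairs = 1)
    }
    cache
  }
})

# shared decoy world: one regular pair plus one decoy per pre-filter stage
decoy_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_world(
        file.path(tempdir(), "decoy_world"), seed = 202, n_pairs = 1,
        decoys = c("paralog", "short_exon", "same_isoform", "exon_copy",
                   "similar_exons"))
    }
    cache
  }
})
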