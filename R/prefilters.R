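#' Best local alignment summary between two nucleotide strings
#'
#' Smith-Waterman local alignment under a blastn-like scheme (match +1,
#' mismatch -2, gap open 5, gap extend 2). Identity is computed over aligned
#' columns (gap columns count as non-identical); query coverage is the
#' fraction of query bases inside the aligned region.
#'
#' @param query Character vector of query sequences.
#' @param subject Single subject sequence.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return Tibble with one row per query: `identity`, `query_coverage`,
#'   `aligned_length`.
#' @export
local_align <- function(query, subject, match = 1, mismatch = -2,
                        gap_open = 5, gap_extend = 2) {
  n <- length(query)
  out <- tibble(identity = numeric(n), query_coverage = numeric(n),
                aligned_length = integer(n))
  if (n == 0L) return(out)
  qlen <- nchar(query)
  ok <- qlen > 0L & !is.na(query)
  if (!nzchar(subject %||% "") || !any(ok)) return(out)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(query[ok]), subject, type = "local",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend)
  cols <- Biostrings::nchar(aln)
  qspan <- IRanges::end(Biostrings::pattern(aln)) -
    IRanges::start(Biostrings::pattern(aln)) + 1L
  # a best local alignment with score <= 0 collapses to zero columns
  identity <- ifelse(cols > 0L, Biostrings::nmatch(aln) / cols, 0)
  coverage <- ifelse(cols > 0L, qspan / qlen[ok], 0)
  out$identity[ok] <- identity
  out$query_coverage[ok] <- coverage
  out$aligned_length[ok] <- as.integer(cols)
  out
}

# TRUE where some subject sequence aligns to the query at >= id_min identity
# and >= cov_min query coverage. queries with NA sequence return FALSE.
align_hits_any <- function(queries, subjects, id_min, cov_min, config = NULL) {
  hit <- logical(length(queries))
  todo <- which(!is.na(queries) & nzchar(queries))
  if (length(todo) == 0L || length(subjects) == 0L) return(hit)
  cfg <- config %||% list()
  for (s in subjects) {
    if (length(todo) == 0L) break
    summ <- local_align(queries[todo], s,
                        match = cfg$match %||% 1, mismatch = cfg$mismatch %||% -2,
                        gap_open = cfg$gap_open %||% 5,
                        gap_extend = cfg$gap_extend %||% 2)
    new_hit <- summ$identity >= id_min & summ$query_coverage >= cov_min
    hit[todo[new_hit]] <- TRUE
    todo <- todo[!new_hit]
  }
  hit
}

#' Paralog filter (pre-filter 1)
#'
#' Removes combinations whose 5' and 3' genes are paralogs of each other:
#' paralogous pairs share sequence by descent, so reads from one gene can
#' fabricate junction matches in the other. An empty relation is a no-op.
#'
#' @param junctions Combination or junction table.
#' @param paralogs Relation from [load_paralogs()].
#' @return Filtered table.
#' @export
paralog_filter <- function(junctions, paralogs) {
  if (nrow(paralogs) == 0L || nrow(junctions) == 0L) return(junctions)
  junctions |>
    filter(!is_paralog_pair(paralogs, .data$gene5_id, .data$gene3_id))
}

#' Flank-length filter (pre-filter 2)
#'
#' Removes combinations where the donor or acceptor exon is shorter than
#' the flank: a full-length junction sequence cannot be constructed from
#' such an exon.
#'
#' @param junctions Combination or junction table (needs `donor_len`,
#'   `acceptor_len`).
#' @param flank Flank length in bp (default 20).
#' @return Filtered table.
#' @export
flank_length_filter <- function(junctions, flank = 20) {
  junctions |>
    filter(.data$donor_len >= flank, .data$acceptor_len >= flank)
}

# transcript adjacency table: one row per consecutive exon pair of each
# transcript, keyed by the exact genomic coordinates of both exons.
transcript_adjacency <- function(exons) {
  exons |>
    group_by(.data$transcript_id) |>
    arrange(.data$rank, .by_group = TRUE) |>
    mutate(next_start = dplyr::lead(.data$start),
           next_end = dplyr::lead(.data$end)) |>
    ungroup() |>
    filter(!is.na(.data$next_start)) |>
    transmute(gene_id = .data$gene_id, chrom = .data$chrom,
              strand = .data$strand,
              up_start = .data$start, up_end = .data$end,
              down_start = .data$next_start, down_end = .data$next_end) |>
    distinct()
}

#' Same-isoform filter (pre-filter 3)
#'
#' Removes same-isoform artifacts from overlapping genes: a read covering
#' two consecutive exons of one transcript can masquerade as a read-through
#' between two genes that share those exons. A combination is discarded
#' when an exon with the acceptor's exact coordinates exists in a transcript
#' of the 5' gene as the immediate successor of the donor exon, or an exon
#' with the donor's exact coordinates exists in a transcript of the 3' gene
#' as the immediate predecessor of the acceptor exon.
#'
#' @param junctions Combination or junction table.
#' @param exons Exon table from [load_annotation()].
#' @return Filtered table.
#' @export
same_isoform_filter <- function(junctions, exons) {
  if (nrow(junctions) == 0L) return(junctions)
  adj <- transcript_adjacency(exons)
  if (nrow(adj) == 0L) return(junctions)
  offender <- adj |>
    select("gene_id", "chrom", "strand",
           donor_start = "up_start", donor_end = "up_end",
           acceptor_start = "down_start", acceptor_end = "down_end")
  hit5 <- junctions |>
    mutate(.row = row_number()) |>
    semi_join(offender |> rename(gene5_id = "gene_id"),
              by = c("gene5_id", "chrom", "strand", "donor_start", "donor_end",
                     "acceptor_start", "acceptor_end")) |>
    pull(".row")
  hit3 <- junctions |>
    mutate(.row = row_number()) |>
    semi_join(offender |> rename(gene3_id = "gene_id"),
              by = c("gene3_id", "chrom", "strand", "donor_start", "donor_end",
                     "acceptor_start", "acceptor_end")) |>
    pull(".row")
  drop <- union(hit5, hit3)
  if (length(drop) == 0L) return(junctions)
  junctions[-drop, , drop = FALSE]
}

#' Exon filter (pre-filter 4)
#'
#' Removes junctions whose 40-mer matches some exon of the annotation at
#' `id_min` identity covering `cov_min` of the junction sequence: such a
#' junction would collect reads that actually originate from a single
#' contiguous exon. Junctions with no constructible sequence pass through
#' (the flank-length filter owns them).
#'
#' @param junctions Junction table with `sequence`.
#' @param exons Exon table (all genes of the annotation).
#' @param genome Genome from [load_genome()].
#' @param id_min,cov_min Identity / junction-coverage thresholds
#'   (defaults 0.90 / 0.90).
#' @param align_config Optional list overriding alignment scores
#'   (`match`, `mismatch`, `gap_open`, `gap_extend`).
#' @return Filtered table.
#' @export
exon_filter <- function(junctions, exons, genome, id_min = 0.90,
                        cov_min = 0.90, align_config = NULL) {
  if (nrow(junctions) == 0L) return(junctions)
  subj <- exons |>
    distinct(.data$chrom, .data$start, .data$end, .data$strand)
  subjects <- unique(exon_sequence(subj, genome))
  hit <- align_hits_any(junctions$sequence, subjects, id_min, cov_min,
                        align_config)
  junctions[!hit, , drop = FALSE]
}

#' Cross-similarity filter (pre-filter 5)
#'
#' Removes combinations where the donor exon is similar to any exon of the
#' participating 3' gene, or the acceptor exon to any exon of the 5' gene
#' (identity and query-exon coverage both at least the thresholds). Such
#' pairs are typically alternatively spliced isoforms or local duplications
#' rather than read-throughs. When probing the partner gene, an exon with
#' coordinates identical to the probed exon (degenerate overlap) is skipped.
#'
#' @param junctions Combination or junction table.
#' @param exons Exon table.
#' @param genome Genome.
#' @param id_min,cov_min Thresholds (defaults 0.70 / 0.70).
#' @param align_config Optional alignment-score overrides.
#' @return Filtered table.
#' @export
similarity_filter <- function(junctions, exons, genome, id_min = 0.70,
                              cov_min = 0.70, align_config = NULL) {
  if (nrow(junctions) == 0L) return(junctions)
  uex <- exons |>
    distinct(.data$gene_id, .data$chrom, .data$start, .data$end, .data$strand)
  uex$seq <- exon_sequence(uex, genome)
  by_gene <- split(uex, uex$gene_id)
  pair_key <- paste(junctions$gene5_id, junctions$gene3_id, sep = "\r")
  drop <- logical(nrow(junctions))
  for (key in unique(pair_key)) {
    rows <- which(pair_key == key)
    g5 <- junctions$gene5_id[rows[1]]
    g3 <- junctions$gene3_id[rows[1]]
    ex5 <- by_gene[[g5]]
    ex3 <- by_gene[[g3]]
    # probe each unique participating exon once, then map back to rows
    probe_side <- function(starts, ends, partner) {
      ukey <- paste(starts, ends)
      u <- !duplicated(ukey)
      useq <- slice_genome(genome, junctions$chrom[rows][u], starts[u], ends[u])
      minus <- junctions$strand[rows][u] == "-"
      useq[minus] <- revcomp(useq[minus])
      uhit <- vapply(seq_along(useq), function(k) {
        # skip the coordinate-identical exon of the partner gene
        subj <- partner$seq[!(partner$start == starts[u][k] &
                                partner$end == ends[u][k])]
        align_hits_any(useq[k], subj, id_min, cov_min, align_config)
      }, logical(1))
      uhit[match(ukey, ukey[u])]
    }
    hit_d <- probe_side(junctions$donor_start[rows],
                        junctions$donor_end[rows], ex3)
    hit_a <- probe_side(junctions$acceptor_start[rows],
                        junctions$acceptor_end[rows], ex5)
    drop[rows] <- hit_d | hit_a
  }
  junctions[!drop, , drop = FALSE]
}

#' Run the five-stage pre-filter cascade
#'
#' Applies, in order: paralog filter, flank-length filter, same-isoform
#' filter, exon filter, cross-similarity filter. Junction sequences are
#' constructed once after the flank-length stage guarantees they exist.
#' Every stage is a pure per-record predicate, so the surviving set is
#' independent of stage order; the per-stage tallies are not.
#'
#' @param combos Combination table from [enumerate_exon_combinations()].
#' @param exons Exon table.
#' @param genome Genome.
#' @param paralogs Relation from [load_paralogs()].
#' @param flank Flank length (default 20).
#' @param exon_id_min,exon_cov_min Exon-filter thresholds (0.90 / 0.90).
#' @param sim_id_min,sim_cov_min Similarity-filter thresholds (0.70 / 0.70).
#' @param align_config Optional alignment-score overrides.
#' @param order Character vector permuting the stage order (default the
#'   canonical order above); must be a permutation of the five stage names.
#' @return List with `junctions` (surviving junction table, sequences
#'   attached) and `tally` (tibble: `stage`, `discarded`, `retained`).
#' @export
run_prefilter_cascade <- function(combos, exons, genome, paralogs,
                                  flank = 20,
                                  exon_id_min = 0.90, exon_cov_min = 0.90,
                                  sim_id_min = 0.70, sim_cov_min = 0.70,
                                  align_config = NULL,
                                  order = c("paralog", "flank_length",
                                            "same_isoform", "exon",
                                            "similarity")) {
  stages <- c("paralog", "flank_length", "same_isoform", "exon", "similarity")
  if (!setequal(order, stages) || length(order) != 5L) {
    stop("`order` must be a permutation of: ", paste(stages, collapse = ", "),
         call. = FALSE)
  }
  current <- make_junctions(combos, genome, flank = flank, on_short = "na")
  tally <- tibble(stage = c("input", order),
                  discarded = c(0L, integer(5)),
                  retained = c(nrow(current), integer(5)))
  for (k in seq_along(order)) {
    before <- nrow(current)
    current <- switch(
      order[k],
      paralog = paralog_filter(current, paralogs),
      flank_length = flank_length_filter(current, flank),
      same_isoform = same_isoform_filter(current, exons),
      exon = exon_filter(current, exons, genome, exon_id_min, exon_cov_min,
                         align_config),
      similarity = similarity_filter(current, exons, genome, sim_id_min,
                                     sim_cov_min, align_config)
    )
    tally$discarded[k + 1L] <- before - nrow(current)
    tally$retained[k + 1L] <- nrow(current)
  }
  list(junctions = current, tally = tally)
}
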