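#' Enumerate donor/acceptor exon combinations of eligible gene pairs
#'
#' Scans the annotation for all same-chromosome, same-strand gene pairs and
#' emits every (donor exon, acceptor exon) combination where the acceptor
#' breakpoint lies strictly downstream (in transcription direction) of the
#' donor breakpoint and the genomic distance between the two breakpoints is
#' at most `max_distance`. The donor breakpoint is the last transcribed base
#' of the 5' exon (genomic `end` on `+`, `start` on `-`); the acceptor
#' breakpoint is the first transcribed base of the 3' exon. Intervening genes
#' do not disqualify a pair; adjacency is not required.
#'
#' Combinations are deduplicated by (gene pair, donor breakpoint, acceptor
#' breakpoint): exon variants that share a breakpoint (alternative
#' non-junction ends across isoforms) collapse to one row whose representative
#' exon interval is the longest contributing exon, with all contributing exon
#' ids retained.
#'
#' @param exons Exon table from [load_annotation()].
#' @param max_distance Maximum breakpoint distance in bp (default 70000).
#' @return Tibble with one row per unique combination: `gene5_id`,
#'   `gene5_name`, `gene3_id`, `gene3_name`, `chrom`, `strand`,
#'   `donor_start`, `donor_end`, `donor_len`, `donor_bp`, `acceptor_start`,
#'   `acceptor_end`, `acceptor_len`, `acceptor_bp`, `distance`,
#'   `donor_exon_ids`, `acceptor_exon_ids`.
#' @export
enumerate_exon_combinations <- function(exons, max_distance = 70000) {
  empty <- tibble(
    gene5_id = character(0), gene5_name = character(0),
    gene3_id = character(0), gene3_name = character(0),
    chrom = character(0), strand = character(0),
    donor_start = integer(0), donor_end = integer(0), donor_len = integer(0),
    donor_bp = integer(0),
    acceptor_start = integer(0), acceptor_end = integer(0),
    acceptor_len = integer(0), acceptor_bp = integer(0),
    distance = integer(0),
    donor_exon_ids = character(0), acceptor_exon_ids = character(0)
  )
  if (nrow(exons) == 0L || max_distance < 1) return(empty)

  uex <- exons |>
    distinct(.data$gene_id, .data$gene_name, .data$chrom, .data$strand,
             .data$start, .data$end, .data$exon_id)
  donors <- uex |>
    mutate(donor_bp = ifelse(.data$strand == "+", .data$end, .data$start))
  acceptors <- uex |>
    mutate(acceptor_bp = ifelse(.data$strand == "+", .data$start, .data$end))

  combos <- inner_join(
    donors, acceptors,
    by = c("chrom", "strand"),
    suffix = c("_5", "_3"),
    relationship = "many-to-many"
  ) |>
    filter(.data$gene_id_5 != .data$gene_id_3) |>
    mutate(sdist = ifelse(.data$strand == "+",
                          .data$acceptor_bp - .data$donor_bp,
                          .data$donor_bp - .data$acceptor_bp)) |>
    filter(.data$sdist >= 1L, .data$sdist <= max_distance)
  if (nrow(combos) == 0L) return(empty)

  combos |>
    mutate(dlen = .data$end_5 - .data$start_5 + 1L,
           alen = .data$end_3 - .data$start_3 + 1L) |>
    group_by(.data$gene_id_5, .data$gene_id_3, .data$chrom, .data$strand,
             .data$donor_bp, .data$acceptor_bp) |>
    summarise(
      gene5_name = first(.data$gene_name_5),
      gene3_name = first(.data$gene_name_3),
      donor_start = .data$start_5[which.max(.data$dlen)],
      donor_end = .data$end_5[which.max(.data$dlen)],
      donor_len = max(.data$dlen),
      acceptor_start = .data$start_3[which.max(.data$alen)],
      acceptor_end = .data$end_3[which.max(.data$alen)],
      acceptor_len = max(.data$alen),
      distance = first(.data$sdist),
      donor_exon_ids = paste(sort(unique(.data$exon_id_5)), collapse = ";"),
      acceptor_exon_ids = paste(sort(unique(.data$exon_id_3)), collapse = ";"),
      .groups = "drop"
    ) |>
    rename(gene5_id = "gene_id_5", gene3_id = "gene_id_3") |>
    rtc_arrange(.data$chrom, .data$gene5_id, .data$gene3_id,
                .data$donor_bp, .data$acceptor_bp) |>
    select("gene5_id", "gene5_name", "gene3_id", "gene3_name", "chrom",
           "strand", "donor_start", "donor_end", "donor_len", "donor_bp",
           "acceptor_start", "acceptor_end", "acceptor_len", "acceptor_bp",
           "distance", "donor_exon_ids", "acceptor_exon_ids")
}

#' Enumerate candidate read-through gene pairs
#'
#' A gene pair is a candidate when the genes share chromosome and strand,
#' the 3' gene lies downstream of the 5' gene in transcription direction,
#' and at least one donor/acceptor exon combination has a breakpoint
#' distance within `max_distance` (see [enumerate_exon_combinations()]).
#'
#' @inheritParams enumerate_exon_combinations
#' @return Tibble with `gene5_id`, `gene5_name`, `gene3_id`, `gene3_name`,
#'   `chrom`, `strand`, `min_distance` (smallest eligible breakpoint
#'   distance of the pair).
#' @export
enumerate_candidate_pairs <- function(exons, max_distance = 70000) {
  combos <- enumerate_exon_combinations(exons, max_distance)
  if (nrow(combos) == 0L) {
    return(tibble(gene5_id = character(0), gene5_name = character(0),
                  gene3_id = character(0), gene3_name = character(0),
                  chrom = character(0), strand = character(0),
                  min_distance = integer(0)))
  }
  combos |>
    group_by(.data$gene5_id, .data$gene5_name, .data$gene3_id,
             .data$gene3_name, .data$chrom, .data$strand) |>
    summarise(min_distance = min(.data$distance), .groups = "drop") |>
    rtc_arrange(.data$chrom, .data$gene5_id, .data$gene3_id)
}

# Genomic windows (1-based inclusive) whose transcribed concatenation is the
# junction sequence. Pure breakpoint arithmetic; no genome access.
junction_window_coords <- function(df, flank) {
  plus <- df$strand == "+"
  tibble(
    donor_win_start = as.integer(ifelse(plus, df$donor_bp - flank + 1L, df$donor_bp)),
    donor_win_end = as.integer(ifelse(plus, df$donor_bp, df$donor_bp + flank - 1L)),
    acceptor_win_start = as.integer(ifelse(plus, df$acceptor_bp, df$acceptor_bp - flank + 1L)),
    acceptor_win_end = as.integer(ifelse(plus, df$acceptor_bp + flank - 1L, df$acceptor_bp))
  )
}

#' Construct junction sequences for exon combinations
#'
#' For every combination the junction sequence is the last `flank`
#' transcribed bases of the donor exon followed by the first `flank`
#' transcribed bases of the acceptor exon (on `-` both windows are the
#' reverse complement of the corresponding genomic slice), giving a
#' `2 * flank`-nt string (40 nt by default). Breakpoints stay 1-based
#' genomic coordinates.
#'
#' A combination whose donor or acceptor exon is shorter than `flank`
#' cannot yield a junction: with `on_short = "error"` (the default) this is
#' an error; with `on_short = "na"` the row is kept with `sequence = NA`
#' (used inside the filter cascade, where the flank-length filter removes
#' such rows explicitly).
#'
#' @param combos Combination table from [enumerate_exon_combinations()].
#' @param genome Genome from [load_genome()].
#' @param flank Bases taken from each side of the breakpoints (default 20).
#' @param on_short `"error"` or `"na"` (see Details).
#' @return `combos` with added columns `junction_id`, `flank`, `sequence`,
#'   `has_n`, `variant_of` (`NA` for database parents), `snp_ids`.
#' @export
make_junctions <- function(combos, genome, flank = 20,
                           on_short = c("error", "na")) {
  on_short <- match.arg(on_short)
  stopifnot(flank >= 1)
  short <- combos$donor_len < flank | combos$acceptor_len < flank
  if (any(short) && on_short == "error") {
    i <- which(short)[1]
    stop(sprintf(
      "FlankTooShort: %s/%s exon of %s-%s is shorter than flank %d (donor %d bp, acceptor %d bp)",
      if (combos$donor_len[i] < flank) "5'" else "",
      if (combos$acceptor_len[i] < flank) "3'" else "",
      combos$gene5_id[i], combos$gene3_id[i], flank,
      combos$donor_len[i], combos$acceptor_len[i]), call. = FALSE)
  }
  out <- combos
  out$junction_id <- paste(out$gene5_id, out$donor_bp,
                           out$gene3_id, out$acceptor_bp, sep = "|")
  out$flank <- as.integer(flank)
  out$sequence <- NA_character_
  ok <- !short
  if (any(ok)) {
    w <- junction_window_coords(out[ok, , drop = FALSE], flank)
    dseq <- slice_genome(genome, out$chrom[ok], w$donor_win_start, w$donor_win_end)
    aseq <- slice_genome(genome, out$chrom[ok], w$acceptor_win_start, w$acceptor_win_end)
    minus <- out$strand[ok] == "-"
    if (any(minus)) {
      dseq[minus] <- revcomp(dseq[minus])
      aseq[minus] <- revcomp(aseq[minus])
    }
    out$sequence[ok] <- paste0(dseq, aseq)
  }
  out$has_n <- !is.na(out$sequence) & grepl("N", out$sequence, fixed = TRUE)
  out$variant_of <- NA_character_
  out$snp_ids <- NA_character_
  out
}

#' Build the searchable junction-sequence index
#'
#' Maps every junction 40-mer and its reverse complement to the junction(s)
#' carrying it. Distinct junctions sharing an identical 40-mer map to the
#' same key (the read-based post-filter resolves the ambiguity later); a
#' palindromic 40-mer yields a single key carrying both orientations.
#' Junctions whose sequence contains N are excluded (exact matching against
#' N is meaningless); the number excluded is reported with a message.
#'
#' @param junctions Junction table from [make_junctions()] (or after
#'   filtering / SNP expansion).
#' @return Tibble with columns `kmer`, `junction_id`, `orientation`
#'   (`"forward"` or `"revcomp"`).
#' @export
build_index <- function(junctions) {
  usable <- junctions |> filter(!is.na(.data$sequence))
  n_with_n <- sum(usable$has_n)
  if (n_with_n > 0L) {
    message(n_with_n, " junction sequence(s) containing N excluded from the index")
    usable <- usable |> filter(!.data$has_n)
  }
  if (nrow(usable) == 0L) {
    return(tibble(kmer = character(0), junction_id = character(0),
                  orientation = character(0)))
  }
  bind_rows(
    tibble(kmer = usable$sequence, junction_id = usable$junction_id,
           orientation = "forward"),
    tibble(kmer = revcomp(usable$sequence), junction_id = usable$junction_id,
           orientation = "revcomp")
  ) |>
    distinct() |>
    rtc_arrange(.data$kmer, .data$junction_id, .data$orientation)
}
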