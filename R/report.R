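#' Assemble the final candidate report table
#'
#' Joins candidates back to their junction records and the genome to
#' produce one row per candidate with everything needed for primer design:
#' gene ids/names, strand, 1-based donor and acceptor breakpoints,
#' breakpoint distance, support counts and read ids, the junction
#' sequence(s) actually matched (including SNP variants), and the full
#' donor/acceptor exon sequences in transcribed orientation. Rows are
#' sorted by (chrom, donor breakpoint, acceptor breakpoint) so output is
#' byte-stable across reruns.
#'
#' @param candidates Candidate tibble from [read_based_filter()] /
#'   [min_support_filter()].
#' @param junctions Junction table the index was built from.
#' @param genome Genome from [load_genome()].
#' @param max_reads_listed Cap on read ids listed per row (default 20);
#'   the count in `n_support` is never capped.
#' @return Report tibble.
#' @export
report_table <- function(candidates, junctions, genome, max_reads_listed = 20) {
  parents <- junctions |> filter(is.na(.data$variant_of))
  base <- parents |>
    select("junction_id", "gene5_id", "gene5_name", "gene3_id", "gene3_name",
           "chrom", "strand", "donor_start", "donor_end", "donor_bp",
           "acceptor_start", "acceptor_end", "acceptor_bp", "distance",
           "flank", "sequence")
  out <- candidates |>
    inner_join(base, by = c(event_key = "junction_id")) |>
    mutate(
      matched_sequences = vapply(
        strsplit(.data$matched_junction_ids, ";", fixed = TRUE),
        function(ids) paste(unique(
          junctions$sequence[match(ids, junctions$junction_id)]), collapse = ";"),
        character(1)),
      supporting_reads = vapply(
        strsplit(.data$supporting_reads, ";", fixed = TRUE),
        function(r) paste(utils::head(r, max_reads_listed), collapse = ";"),
        character(1))
    )
  donor_seq <- exon_sequence(
    tibble(chrom = out$chrom, start = out$donor_start, end = out$donor_end,
           strand = out$strand), genome)
  acceptor_seq <- exon_sequence(
    tibble(chrom = out$chrom, start = out$acceptor_start, end = out$acceptor_end,
           strand = out$strand), genome)
  out |>
    mutate(donor_exon_seq = donor_seq, acceptor_exon_seq = acceptor_seq) |>
    rtc_arrange(.data$chrom, .data$donor_bp, .data$acceptor_bp) |>
    select("gene5_id", "gene5_name", "gene3_id", "gene3_name", "chrom",
           "strand", "donor_bp", "acceptor_bp", "distance", "n_support",
           "supporting_reads", "junction_seq" = "sequence",
           "matched_sequences", "donor_start", "donor_end",
           "acceptor_start", "acceptor_end", "flank",
           "donor_exon_seq", "acceptor_exon_seq")
}

#' Write the candidate report
#'
#' Writes the [report_table()] as a TSV with a header (header-only when
#' there are no candidates) plus a sidecar `<path>.reads.tsv` with the full
#' uncapped read lists. Output is deterministic: no timestamps, fixed sort.
#'
#' @inheritParams report_table
#' @param path Output TSV path.
#' @return The report tibble, invisibly.
#' @export
write_report <- function(candidates, junctions, genome, path,
                         max_reads_listed = 20) {
  tbl <- report_table(candidates, junctions, genome, max_reads_listed)
  readr::write_tsv(tbl, path)
  full <- candidates |> select("event_key", "n_support", "supporting_reads")
  readr::write_tsv(full, paste0(path, ".reads.tsv"))
  invisible(tbl)
}

#' Export candidate breakpoints as BEDPE
#'
#' Two single-base anchors per event (donor and acceptor breakpoints) in
#' BEDPE's 0-based half-open convention, for genome-browser visualization.
#'
#' @param report Report tibble from [report_table()].
#' @param path Output path.
#' @return The BEDPE tibble, invisibly.
#' @export
write_bedpe <- function(report, path) {
  bedpe <- tibble(
    chrom1 = report$chrom, start1 = report$donor_bp - 1L, end1 = report$donor_bp,
    chrom2 = report$chrom, start2 = report$acceptor_bp - 1L, end2 = report$acceptor_bp,
    name = paste0(report$gene5_name, "-", report$gene3_name),
    score = report$n_support,
    strand1 = report$strand, strand2 = report$strand
  )
  readr::write_tsv(bedpe, path, col_names = FALSE)
  invisible(bedpe)
}
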