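#' Load a genome FASTA
#'
#' Reads a (possibly gzip-compressed) FASTA into a [Biostrings::DNAStringSet].
#' Record names are truncated at the first whitespace so that
#' chromosome-level accessors use the header token (`>chr1 description`
#' becomes `chr1`). Lowercase bases are normalised to uppercase by the
#' DNAString alphabet.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A named `DNAStringSet`, one entry per chromosome.
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("genome FASTA not found: ", fasta_path, call. = FALSE)
  }
  genome <- tryCatch(
    Biostrings::readDNAStringSet(fasta_path),
    error = function(e) stop("malformed FASTA '", fasta_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(genome) == 0L) stop("FASTA contains no records: ", fasta_path, call. = FALSE)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome))) {
    stop("duplicate chromosome names in FASTA: ",
         paste(unique(names(genome)[duplicated(names(genome))]), collapse = ", "),
         call. = FALSE)
  }
  genome
}

#' Load gene annotation from an Ensembl-dialect GTF
#'
#' Imports exon features and normalises them into a tidy exon table, the
#' package's central annotation structure: one row per exon per transcript.
#' GTF coordinates (1-based inclusive) are kept in that convention
#' throughout. Exon `rank` is recomputed in transcription order (ascending
#' genomic coordinate on `+`, descending on `-`), so an `exon_number`
#' attribute is not required.
#'
#' Exon features missing `gene_id` or `transcript_id` are skipped with a
#' warning; a gene whose exons lie on both strands is an error.
#'
#' @param gtf_path Path to a GTF file with exon features.
#' @return A tibble with columns `gene_id`, `gene_name`, `transcript_id`,
#'   `exon_id`, `chrom`, `start`, `end`, `strand`, `rank`, `width`.
#' @export
load_annotation <- function(gtf_path) {
  if (!file.exists(gtf_path)) stop("GTF not found: ", gtf_path, call. = FALSE)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[as.character(gr$type) == "exon"]
  if (length(gr) == 0L) stop("GTF contains no exon features: ", gtf_path, call. = FALSE)
  df <- as_tibble(as.data.frame(gr, stringsAsFactors = FALSE))
  df$gene_id <- as.character(df$gene_id %||% NA_character_)
  df$transcript_id <- as.character(df$transcript_id %||% NA_character_)
  missing_ids <- is.na(df$gene_id) | is.na(df$transcript_id) |
    df$gene_id == "" | df$transcript_id == ""
  if (any(missing_ids)) {
    warning(sum(missing_ids), " exon feature(s) lacking gene_id/transcript_id skipped",
            call. = FALSE)
    df <- df[!missing_ids, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no usable exon features in ", gtf_path, call. = FALSE)
  if (is.null(df[["gene_name"]])) df$gene_name <- df$gene_id
  df$gene_name <- dplyr::coalesce(as.character(df$gene_name), df$gene_id)

  exons <- df |>
    transmute(
      gene_id = .data$gene_id,
      gene_name = .data$gene_name,
      transcript_id = .data$transcript_id,
      chrom = as.character(.data$seqnames),
      start = as.integer(.data$start),
      end = as.integer(.data$end),
      strand = as.character(.data$strand)
    )
  if (!all(exons$strand %in% c("+", "-"))) {
    stop("exon features must be stranded (+/-)", call. = FALSE)
  }
  mixed <- exons |>
    group_by(.data$gene_id) |>
    summarise(n_strand = dplyr::n_distinct(.data$strand),
              n_chrom = dplyr::n_distinct(.data$chrom), .groups = "drop") |>
    filter(.data$n_strand > 1L | .data$n_chrom > 1L)
  if (nrow(mixed) > 0L) {
    stop("gene(s) with exons on mixed strands or chromosomes: ",
         paste(mixed$gene_id, collapse = ", "), call. = FALSE)
  }

  exons |>
    mutate(exon_id = paste0(.data$chrom, ":", .data$start, "-", .data$end,
                            "(", .data$strand, ")")) |>
    group_by(.data$transcript_id) |>
    arrange(ifelse(.data$strand == "+", .data$start, -.data$start),
            .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    mutate(width = .data$end - .data$start + 1L) |>
    rtc_arrange(.data$gene_id, .data$transcript_id, .data$rank) |>
    select("gene_id", "gene_name", "transcript_id", "exon_id",
           "chrom", "start", "end", "strand", "rank", "width")
}

#' Summarise an exon table to one row per gene
#'
#' @param exons Exon table from [load_annotation()].
#' @return Tibble with `gene_id`, `gene_name`, `chrom`, `strand`,
#'   `start`, `end` (gene span over all exons).
#' @export
gene_table <- function(exons) {
  exons |>
    group_by(.data$gene_id) |>
    summarise(
      gene_name = first(.data$gene_name),
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      start = min(.data$start),
      end = max(.data$end),
      .groups = "drop"
    )
}

#' Load a paralog-pair table
#'
#' Two whitespace- or tab-separated gene-ID columns, optional header.
#' The relation is symmetric and self-pairs are dropped; membership is
#' tested with [is_paralog_pair()]. Unknown gene IDs are retained (the
#' relation is only ever used for membership tests).
#'
#' @param tsv_path Path to the two-column table. `NULL` or a missing file
#'   with `allow_missing = TRUE` yields an empty relation.
#' @param allow_missing Return an empty relation when `tsv_path` is `NULL`.
#' @return A tibble of normalised pairs with columns `a`, `b` (`a <= b`).
#' @export
load_paralogs <- function(tsv_path = NULL, allow_missing = TRUE) {
  empty <- tibble(a = character(0), b = character(0))
  if (is.null(tsv_path)) {
    if (allow_missing) return(empty)
    stop("paralog table required", call. = FALSE)
  }
  if (!file.exists(tsv_path)) stop("paralog table not found: ", tsv_path, call. = FALSE)
  lines <- readr::read_lines(tsv_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(trimws(lines), "[\t ]+")
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    stop("paralog table line ", which(nf != 2L)[1],
         ": expected 2 columns, found ", nf[nf != 2L][1], call. = FALSE)
  }
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  # drop a header line if present
  if (length(a) > 0L && grepl("gene", a[1], ignore.case = TRUE) &&
      grepl("gene|paralog", b[1], ignore.case = TRUE)) {
    a <- a[-1]; b <- b[-1]
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  tibble(a = lo, b = hi) |>
    filter(.data$a != .data$b) |>
    distinct()
}

#' Test paralog-relation membership (order-independent)
#'
#' @param paralogs Relation from [load_paralogs()].
#' @param gene_a,gene_b Gene-ID vectors (recycled to a common length).
#' @return Logical vector.
#' @export
is_paralog_pair <- function(paralogs, gene_a, gene_b) {
  key <- paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b), sep = "\r")
  key %in% paste(paralogs$a, paralogs$b, sep = "\r")
}

#' Extract exon sequences in transcribed orientation
#'
#' For minus-strand exons the reverse complement of the genomic slice is
#' returned, i.e. the sequence as it appears in the transcript.
#'
#' @param exons Exon table (rows; needs `chrom`, `start`, `end`, `strand`).
#' @param genome Genome from [load_genome()].
#' @return Character vector of sequences, one per row of `exons`.
#' @export
exon_sequence <- function(exons, genome) {
  seqs <- slice_genome(genome, exons$chrom, exons$start, exons$end)
  minus <- exons$strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  seqs
}
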