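#' Build the read-through junction database
#'
#' End-to-end database construction: load genome, annotation and paralog
#' relation; enumerate all eligible donor/acceptor exon combinations within
#' `max_distance`; construct junction sequences; run the five-stage
#' pre-filter cascade; and expand survivors with common-SNP variants. When
#' `out_dir` is given the junction table is serialized as TSV next to a
#' JSON manifest holding parameters and filter tallies.
#'
#' Defaults follow the method's standard configuration: 70 kb breakpoint
#' distance, 20 bp flanks (40 bp junctions), CAF >= 0.10, exon filter at
#' 90% identity / 90% junction coverage, similarity filter at 70% / 70%.
#'
#' @param genome Path to the genome FASTA (or a loaded `DNAStringSet`).
#' @param gtf Path to the GTF (or a loaded exon table).
#' @param paralogs Path to the paralog TSV, a loaded relation, or `NULL`.
#' @param snps Path to a VCF/TSV SNP file, a loaded SNP table, or `NULL`
#'   to skip SNP expansion.
#' @param out_dir Output directory for `junctions.tsv` + `manifest.json`
#'   (optional).
#' @param max_distance Maximum breakpoint distance, bp (default 70000).
#' @param flank Flank length, bp (default 20).
#' @param min_caf Minimum alternate-allele frequency (default 0.10).
#' @param exon_id_min,exon_cov_min Exon-filter thresholds (0.90 / 0.90).
#' @param sim_id_min,sim_cov_min Similarity-filter thresholds (0.70 / 0.70).
#' @param align_config Optional alignment-score overrides (list with
#'   `match`, `mismatch`, `gap_open`, `gap_extend`).
#' @param expand_snp_pairs Also enumerate double-SNP variants
#'   (default `FALSE`).
#' @return An `rtc_db` object: `junctions`, `tally`, `params`, `exons`,
#'   `genome`, `n_combinations`, plus output `paths` when written.
#' @export
rtc_build_db <- function(genome, gtf, paralogs = NULL, snps = NULL,
                         out_dir = NULL, max_distance = 70000, flank = 20,
                         min_caf = 0.10,
                         exon_id_min = 0.90, exon_cov_min = 0.90,
                         sim_id_min = 0.70, sim_cov_min = 0.70,
                         align_config = NULL, expand_snp_pairs = FALSE) {
  genome_path <- if (is.character(genome)) genome else NA_character_
  if (is.character(genome)) genome <- load_genome(genome)
  gtf_path <- if (is.character(gtf)) gtf else NA_character_
  exons <- if (is.character(gtf)) load_annotation(gtf) else gtf
  par_rel <- if (is.character(paralogs)) load_paralogs(paralogs) else {
    paralogs %||% load_paralogs(NULL)
  }
  snp_tbl <- if (is.character(snps)) load_common_snps(snps, min_caf) else snps
  if (!is.null(snp_tbl) && nrow(snp_tbl) > 0L) {
    snp_tbl <- snp_tbl |> filter(.data$caf >= min_caf)
  }

  combos <- enumerate_exon_combinations(exons, max_distance)
  cascade <- run_prefilter_cascade(
    combos, exons, genome, par_rel, flank = flank,
    exon_id_min = exon_id_min, exon_cov_min = exon_cov_min,
    sim_id_min = sim_id_min, sim_cov_min = sim_cov_min,
    align_config = align_config)
  junctions <- cascade$junctions
  n_parents <- nrow(junctions)
  if (!is.null(snp_tbl) && nrow(snp_tbl) > 0L) {
    junctions <- expand_with_snps(junctions, snp_tbl,
                                  pairwise = expand_snp_pairs)
  }
  junctions <- junctions |>
    rtc_arrange(.data$chrom, .data$donor_bp, .data$acceptor_bp,
                .data$junction_id)

  params <- list(
    max_distance = max_distance, flank = flank, min_caf = min_caf,
    exon_id_min = exon_id_min, exon_cov_min = exon_cov_min,
    sim_id_min = sim_id_min, sim_cov_min = sim_cov_min,
    align = list(match = align_config$match %||% 1,
                 mismatch = align_config$mismatch %||% -2,
                 gap_open = align_config$gap_open %||% 5,
                 gap_extend = align_config$gap_extend %||% 2),
    expand_snp_pairs = expand_snp_pairs
  )
  db <- structure(list(
    junctions = junctions,
    tally = cascade$tally,
    params = params,
    exons = exons,
    genome = genome,
    n_combinations = nrow(combos),
    n_parents = n_parents,
    n_variants = nrow(junctions) - n_parents,
    genome_path = genome_path,
    gtf_path = gtf_path
  ), class = "rtc_db")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    db_path <- file.path(out_dir, "junctions.tsv")
    readr::write_tsv(junctions, db_path)
    manifest <- list(
      genome = genome_path, annotation = gtf_path,
      parameters = params,
      n_combinations = nrow(combos),
      n_junctions = n_parents,
      n_snp_variants = db$n_variants,
      filter_tally = as.list(setNames(cascade$tally$retained,
                                      cascade$tally$stage))
    )
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    db$paths <- list(junctions = db_path, manifest = manifest_path)
  }
  db
}

#' Run the detection pipeline against RNA-seq reads
#'
#' Builds the two-orientation sequence index from a junction database,
#' scans the reads for exact junction matches under a memory-bounded chunk
#' plan, collapses hits to breakpoint-pair events, applies the read-based
#' ambiguity filter and the optional minimum-support filter, and assembles
#' the breakpoint-annotated report. When `out_dir` is given,
#' `report.tsv`, its read-list sidecar and a BEDPE export are written.
#'
#' @param db An `rtc_db` from [rtc_build_db()].
#' @param reads Character vector of FASTQ(.gz) / FASTA read files.
#' @param out_dir Optional output directory.
#' @param min_support Minimum supporting reads per candidate (default 1).
#' @param memory_budget_gb Memory budget for the pattern scan (default 4).
#' @param threads Worker processes (default 1); results are independent of
#'   the thread count.
#' @param n_chunks Optional explicit chunk count (testing / tuning).
#' @param max_reads_listed Read ids listed per report row (default 20).
#' @return An `rtc_result`: `report`, `candidates`, `stage_counts`,
#'   `params`, plus `paths` when written.
#' @export
rtc_run <- function(db, reads, out_dir = NULL, min_support = 1,
                    memory_budget_gb = 4, threads = 1, n_chunks = NULL,
                    max_reads_listed = 20) {
  stopifnot(inherits(db, "rtc_db"))
  index <- build_index(db$junctions)
  hits <- scan_reads(reads, index, n_chunks = n_chunks,
                     memory_budget_gb = memory_budget_gb, threads = threads)
  events <- collapse_to_events(hits, db$junctions)
  candidates_all <- read_based_filter(events)
  candidates <- min_support_filter(candidates_all, min_support)
  report <- report_table(candidates, db$junctions, db$genome, max_reads_listed)

  stage_counts <- tibble(
    stage = c("indexed_junctions", "hitting_reads", "events_with_hits",
              "after_read_based_filter", "after_min_support"),
    n = c(dplyr::n_distinct(index$junction_id),
          dplyr::n_distinct(hits$read_id),
          dplyr::n_distinct(events$event_key),
          nrow(candidates_all),
          nrow(candidates))
  )
  res <- structure(list(
    report = report, candidates = candidates, hits = hits,
    stage_counts = stage_counts,
    params = c(db$params, list(min_support = min_support, threads = threads))
  ), class = "rtc_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    report_path <- file.path(out_dir, "report.tsv")
    write_report(candidates, db$junctions, db$genome, report_path,
                 max_reads_listed)
    bedpe_path <- file.path(out_dir, "report.bedpe")
    write_bedpe(report, bedpe_path)
    res$paths <- list(report = report_path, bedpe = bedpe_path)
  }
  res
}

#' Read a serialized junction database back from disk
#'
#' @param dir Directory written by [rtc_build_db()].
#' @param genome Genome FASTA path or `DNAStringSet`; defaults to the path
#'   recorded in the manifest.
#' @param gtf Annotation GTF path or exon table; defaults to the manifest
#'   entry.
#' @return An `rtc_db`.
#' @export
read_junction_db <- function(dir, genome = NULL, gtf = NULL) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  junctions <- readr::read_tsv(
    file.path(dir, "junctions.tsv"),
    col_types = readr::cols(
      chrom = "c", strand = "c", sequence = "c", variant_of = "c",
      snp_ids = "c", junction_id = "c", gene5_id = "c", gene5_name = "c",
      gene3_id = "c", gene3_name = "c", donor_exon_ids = "c",
      acceptor_exon_ids = "c", has_n = "l", .default = "i"))
  params <- manifest$parameters
  num <- c("max_distance", "flank", "min_caf", "exon_id_min", "exon_cov_min",
           "sim_id_min", "sim_cov_min")
  params[num] <- lapply(params[num], as.numeric)
  params$align <- lapply(params$align, as.numeric)
  genome <- genome %||% manifest$genome
  if (is.character(genome)) genome <- load_genome(genome)
  gtf <- gtf %||% manifest$annotation
  exons <- if (is.character(gtf)) load_annotation(gtf) else gtf
  structure(list(
    junctions = junctions,
    tally = tibble(stage = names(manifest$filter_tally),
                   retained = unlist(manifest$filter_tally, use.names = FALSE)),
    params = params,
    exons = exons, genome = genome,
    n_combinations = manifest$n_combinations,
    n_parents = manifest$n_junctions,
    n_variants = manifest$n_snp_variants,
    genome_path = manifest$genome, gtf_path = manifest$annotation
  ), class = "rtc_db")
}

#' @export
print.rtc_db <- function(x, ...) {
  cat("<rtc_db> read-through junction database\n")
  cat("  exon combinations enumerated:", x$n_combinations, "\n")
  cat("  junctions after pre-filters: ", x$n_parents, "\n")
  cat("  SNP variant records:         ", x$n_variants, "\n")
  cat("  parameters: max_distance =", x$params$max_distance,
      "| flank =", x$params$flank, "| min CAF =", x$params$min_caf, "\n")
  invisible(x)
}

#' @export
print.rtc_result <- function(x, ...) {
  cat("<rtc_result> read-through detection result\n")
  print(x$stage_counts, n = Inf)
  cat("candidates:", nrow(x$report), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the junction database into its junction table
#' @param x An `rtc_db`.
#' @param ... Unused.
#' @return The junction tibble.
#' @method tidy rtc_db
#' @export
tidy.rtc_db <- function(x, ...) x$junctions

#' One-row database summary
#' @param x An `rtc_db`.
#' @param ... Unused.
#' @method glance rtc_db
#' @export
glance.rtc_db <- function(x, ...) {
  tibble(n_combinations = x$n_combinations, n_junctions = x$n_parents,
         n_snp_variants = x$n_variants,
         max_distance = x$params$max_distance, flank = x$params$flank)
}

#' Tidy a detection result into its report table
#' @param x An `rtc_result`.
#' @param ... Unused.
#' @return The report tibble.
#' @method tidy rtc_result
#' @export
tidy.rtc_result <- function(x, ...) x$report

#' One-row detection summary
#' @param x An `rtc_result`.
#' @param ... Unused.
#' @method glance rtc_result
#' @export
glance.rtc_result <- function(x, ...) {
  sc <- setNames(x$stage_counts$n, x$stage_counts$stage)
  tibble(n_candidates = nrow(x$report),
         n_hitting_reads = sc[["hitting_reads"]],
         n_events_with_hits = sc[["events_with_hits"]],
         n_dropped_ambiguous = sc[["events_with_hits"]] -
           sc[["after_read_based_filter"]],
         min_support = x$params$min_support)
}

#' Plot the pre-filter retention cascade of a junction database
#' @param object An `rtc_db`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rtc_db
#' @export
autoplot.rtc_db <- function(object, ...) {
  df <- object$tally |>
    mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$retained)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$retained), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "junction sequences retained",
                  title = "Pre-filter cascade") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot supporting-read counts per reported candidate
#' @param object An `rtc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rtc_result
#' @export
autoplot.rtc_result <- function(object, ...) {
  df <- object$report |>
    mutate(label = paste0(.data$gene5_name, "-", .data$gene3_name, "@",
                          .data$donor_bp, ":", .data$acceptor_bp))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$label, .data$n_support), y = .data$n_support)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "supporting reads",
                  title = "Read-through candidates") +
    ggplot2::theme_minimal()
}
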