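#' Collapse read hits to biological events
#'
#' SNP variants, and the two orientations, of one junction are evidence for
#' the same biological event. Hits are therefore re-keyed from junction ids
#' to event keys: the (gene pair, donor breakpoint, acceptor breakpoint)
#' identity, with variants resolved to their parent junction. A read's set
#' of matched junctions becomes a set of events.
#'
#' @param hits Hit tibble from [scan_reads()].
#' @param junctions Junction table the index was built from.
#' @return Tibble with `read_id`, `event_key`, `junction_id` (the matched
#'   record, possibly a variant), one row per distinct (read, event,
#'   matched junction).
#' @export
collapse_to_events <- function(hits, junctions) {
  if (nrow(hits) == 0L) {
    return(tibble(read_id = character(0), event_key = character(0),
                  junction_id = character(0)))
  }
  dangling <- setdiff(hits$junction_id, junctions$junction_id)
  if (length(dangling) > 0L) {
    stop("hit(s) reference junction id(s) absent from the database: ",
         paste(utils::head(dangling, 3), collapse = ", "), call. = FALSE)
  }
  key_tbl <- junctions |>
    transmute(junction_id = .data$junction_id,
              event_key = ifelse(is.na(.data$variant_of),
                                 .data$junction_id, .data$variant_of))
  hits |>
    inner_join(key_tbl, by = "junction_id") |>
    distinct(.data$read_id, .data$event_key, .data$junction_id) |>
    rtc_arrange(.data$read_id, .data$event_key, .data$junction_id)
}

#' Read-based ambiguity filter (post-filter 6)
#'
#' A read that supports more than one event cannot be trusted as evidence
#' for any of them: it is discarded entirely and supporting-read counts are
#' recomputed. Events left with no supporting reads are dropped. The filter
#' is single-pass and idempotent (reads surviving one pass are unambiguous
#' by construction).
#'
#' @param event_hits Tibble from [collapse_to_events()].
#' @return Candidate tibble: `event_key`, `n_support`, `supporting_reads`
#'   (semicolon-joined read ids), `matched_junction_ids` (semicolon-joined
#'   parent/variant records observed among surviving reads).
#' @export
read_based_filter <- function(event_hits) {
  empty <- tibble(event_key = character(0), n_support = integer(0),
                  supporting_reads = character(0),
                  matched_junction_ids = character(0))
  if (nrow(event_hits) == 0L) return(empty)
  ambiguous <- event_hits |>
    distinct(.data$read_id, .data$event_key) |>
    dplyr::count(.data$read_id) |>
    filter(.data$n > 1L) |>
    pull("read_id")
  kept <- event_hits |> filter(!(.data$read_id %in% ambiguous))
  if (nrow(kept) == 0L) return(empty)
  kept |>
    group_by(.data$event_key) |>
    summarise(
      n_support = dplyr::n_distinct(.data$read_id),
      supporting_reads = paste(sort(unique(.data$read_id)), collapse = ";"),
      matched_junction_ids = paste(sort(unique(.data$junction_id)), collapse = ";"),
      .groups = "drop"
    ) |>
    rtc_arrange(.data$event_key)
}

#' Minimum supporting-read filter (post-filter 7)
#'
#' Optional user-facing cutoff on the number of supporting reads per
#' candidate; `min_reads = 1` is the identity.
#'
#' @param candidates Candidate tibble from [read_based_filter()].
#' @param min_reads Minimum supporting reads (>= 1).
#' @return Filtered candidate tibble.
#' @export
min_support_filter <- function(candidates, min_reads = 1) {
  if (!is.numeric(min_reads) || min_reads < 1) {
    stop("min_reads must be >= 1", call. = FALSE)
  }
  candidates |> filter(.data$n_support >= min_reads)
}
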