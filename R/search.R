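# estimated in-memory footprint of one indexed pattern inside the matching
# automaton (bytes); deliberately generous so chunk plans err on the safe side
PATTERN_FOOTPRINT_BYTES <- 2048

#' Plan memory-bounded search chunks
#'
#' Splits the unique pattern set of an index into the smallest number of
#' balanced chunks whose estimated automaton footprint fits a memory budget.
#' With a generous budget the plan is a single chunk; chunk sizes never
#' differ by more than one pattern.
#'
#' @param index Index from [build_index()].
#' @param memory_budget_gb Memory the search may use, in GB.
#' @return List with `n_chunks`, `chunk_sizes`, `patterns` (character
#'   vector of unique k-mers, in deterministic order), class `rtc_plan`.
#' @export
plan_chunks <- function(index, memory_budget_gb = 4) {
  if (!is.numeric(memory_budget_gb) || memory_budget_gb <= 0) {
    stop("memory budget must be positive", call. = FALSE)
  }
  patterns <- sort(unique(index$kmer))
  n <- length(patterns)
  if (n == 0L) {
    return(structure(list(n_chunks = 0L, chunk_sizes = integer(0),
                          patterns = character(0)), class = "rtc_plan"))
  }
  budget_bytes <- memory_budget_gb * 1024^3
  per_chunk <- floor(budget_bytes / PATTERN_FOOTPRINT_BYTES)
  if (per_chunk < 1) {
    stop("memory budget below the single-pattern minimum (",
         PATTERN_FOOTPRINT_BYTES, " bytes)", call. = FALSE)
  }
  n_chunks <- as.integer(ceiling(n / per_chunk))
  sizes <- rep(n %/% n_chunks, n_chunks)
  extra <- n %% n_chunks
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  structure(list(n_chunks = n_chunks, chunk_sizes = sizes, patterns = patterns),
            class = "rtc_plan")
}

# Canonical read ids: fragment name plus mate suffix so paired mates count as
# separate reads. Handles "frag/1", "frag 1:N:0:ACGT" (Casava 1.8+) and bare
# names.
normalize_read_ids <- function(ids) {
  frag <- sub("\\s.*$", "", ids)
  rest <- ifelse(grepl("\\s", ids), sub("^\\S+\\s+", "", ids), "")
  mate <- rep(NA_character_, length(ids))
  slash <- grepl("/[12]$", frag)
  mate[slash] <- sub("^.*/", "", frag[slash])
  frag[slash] <- sub("/[12]$", "", frag[slash])
  casava <- is.na(mate) & grepl("^[12]:[YN]:", rest)
  mate[casava] <- substr(rest[casava], 1L, 1L)
  ifelse(is.na(mate), frag, paste0(frag, "/", mate))
}

read_fastq_reads <- function(path) {
  if (!file.exists(path)) stop("reads file not found: ", path, call. = FALSE)
  fmt <- if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", path)) "fasta" else "fastq"
  reads <- tryCatch(
    Biostrings::readDNAStringSet(path, format = fmt),
    error = function(e) stop("malformed ", toupper(fmt), " '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  names(reads) <- normalize_read_ids(names(reads))
  reads
}

#' Scan reads for exact junction-sequence matches
#'
#' A read supports a junction when it contains the junction k-mer or its
#' reverse complement as an exact contiguous substring (no mismatches;
#' tolerance to common variation comes from the SNP-expanded database, and
#' N never matches). Reads shorter than the junction length cannot match.
#' Matching uses a preprocessed multi-pattern dictionary
#' ([Biostrings::PDict]) per chunk; the result is a pure function of
#' (reads, index) — independent of chunk count, thread count and file
#' order.
#'
#' @param fastq_paths One or more FASTQ(.gz) or FASTA read files.
#' @param index Index from [build_index()].
#' @param plan Optional chunk plan from [plan_chunks()]; built from
#'   `memory_budget_gb` when omitted.
#' @param n_chunks Optional explicit chunk count (overrides `plan`).
#' @param memory_budget_gb Budget used when no plan is given (default 4).
#' @param threads Worker processes for per-chunk scanning (default 1).
#' @return Hit tibble: `read_id`, `junction_id`, `orientation`, ordered by
#'   read id then junction id.
#' @export
scan_reads <- function(fastq_paths, index, plan = NULL, n_chunks = NULL,
                       memory_budget_gb = 4, threads = 1) {
  empty <- tibble(read_id = character(0), junction_id = character(0),
                  orientation = character(0))
  if (nrow(index) == 0L) return(empty)
  if (is.null(plan)) plan <- plan_chunks(index, memory_budget_gb)
  patterns <- plan$patterns
  if (!is.null(n_chunks)) {
    stopifnot(n_chunks >= 1)
    n_chunks <- min(as.integer(n_chunks), length(patterns))
  } else {
    n_chunks <- max(plan$n_chunks, 1L)
  }
  if (length(patterns) == 0L) return(empty)

  reads <- do.call(c, lapply(fastq_paths, read_fastq_reads))
  if (anyDuplicated(names(reads))) {
    warning("duplicate read ids across input files", call. = FALSE)
  }
  if (length(reads) == 0L) return(empty)

  chunk_of <- sort(rep_len(seq_len(n_chunks), length(patterns)))
  chunks <- split(patterns, chunk_of)
  scan_chunk <- function(pats) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
    hit_lists <- Biostrings::vwhichPDict(pd, reads)
    n_hits <- lengths(hit_lists)
    if (sum(n_hits) == 0L) {
      return(tibble(read_id = character(0), kmer = character(0)))
    }
    tibble(
      read_id = rep(names(reads), n_hits),
      kmer = pats[unlist(hit_lists, use.names = FALSE)]
    )
  }
  per_chunk <- if (threads > 1L && length(chunks) > 1L) {
    parallel::mclapply(chunks, scan_chunk, mc.cores = threads,
                       mc.preschedule = TRUE)
  } else {
    lapply(chunks, scan_chunk)
  }
  merge_hits(per_chunk, index)
}

#' Merge per-chunk hits into a single hit table
#'
#' Takes per-chunk (read, k-mer) matches from disjoint pattern chunks,
#' resolves k-mers to junction records through the index, and returns the
#' deduplicated union in deterministic order.
#'
#' @param per_chunk_hits List of tibbles with `read_id`, `kmer`.
#' @param index Index from [build_index()].
#' @return Hit tibble: `read_id`, `junction_id`, `orientation`.
#' @export
merge_hits <- function(per_chunk_hits, index) {
  hits <- bind_rows(per_chunk_hits)
  if (nrow(hits) == 0L) {
    return(tibble(read_id = character(0), junction_id = character(0),
                  orientation = character(0)))
  }
  hits |>
    inner_join(index, by = "kmer", relationship = "many-to-many") |>
    distinct(.data$read_id, .data$junction_id, .data$orientation) |>
    rtc_arrange(.data$read_id, .data$junction_id, .data$orientation)
}
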