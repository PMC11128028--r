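#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over plain character vectors. IUPAC
#' ambiguity codes (including N) are complemented by Biostrings rules.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("AACC", "ACGT"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Complement single bases (vectorised, no reversal)
#' @noRd
complement_base <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan", x)
}

# Slice a genome (DNAStringSet) with 1-based inclusive coordinates and strict
# bounds checking; returns a plain character string.
slice_genome <- function(genome, chrom, start, end) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  idx <- match(chrom, names(genome))
  if (anyNA(idx)) {
    stop("unknown chromosome(s): ",
         paste(unique(chrom[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  len <- Biostrings::width(genome)[idx]
  bad <- start < 1L | end > len | end < start
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("genome slice out of bounds: %s:%d-%d (chromosome length %d)",
                 chrom[i], start[i], end[i], len[i]), call. = FALSE)
  }
  if (length(idx) == 0L) return(character(0))
  out <- character(length(idx))
  for (ch in unique(idx)) {
    sel <- which(idx == ch)
    out[sel] <- as.character(Biostrings::extractAt(
      genome[[ch]], IRanges::IRanges(start[sel], end[sel])))
  }
  out
}

# Deterministic, locale-independent ordering used for all serialized output.
rtc_arrange <- function(df, ...) {
  withr_collate <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", withr_collate)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  dplyr::arrange(df, ...)
}
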