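#' Load common single-nucleotide variants
#'
#' Reads either a VCF 4.x file (allele frequencies taken from the `CAF`
#' INFO key, dbSNP style with the reference frequency first, or from `AF`)
#' or a 6-column TSV (`chrom`, `pos`, `id`, `ref`, `alt`, `caf`). Only
#' single-nucleotide substitutions with an alternate-allele frequency of at
#' least `min_caf` are kept; indels and multi-nucleotide variants are
#' dropped and tallied. Multi-allelic records yield one row per qualifying
#' alternate allele.
#'
#' @param path Path to the VCF (`.vcf`/`.vcf.gz`) or TSV file.
#' @param min_caf Minimum alternate-allele frequency (default 0.10).
#' @return Tibble with `chrom`, `pos` (1-based), `snp_id`, `ref`, `alt`,
#'   `caf`. The attribute `"dropped"` carries a named count vector
#'   (`not_snv`, `low_caf`).
#' @export
load_common_snps <- function(path, min_caf = 0.10) {
  if (!file.exists(path)) stop("SNP file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  is_vcf <- grepl("\\.vcf(\\.gz)?$", path) || startsWith(first, "##fileformat=VCF")
  raw <- if (is_vcf) read_snps_vcf(path) else read_snps_tsv(path)
  is_snv <- nchar(raw$ref) == 1L & nchar(raw$alt) == 1L &
    raw$ref %in% c("A", "C", "G", "T") & raw$alt %in% c("A", "C", "G", "T") &
    raw$ref != raw$alt
  low <- raw$caf < min_caf
  kept <- raw[is_snv & !low, , drop = FALSE] |>
    distinct() |>
    rtc_arrange(.data$chrom, .data$pos, .data$alt)
  attr(kept, "dropped") <- c(not_snv = sum(!is_snv),
                             low_caf = sum(is_snv & low))
  kept
}

read_snps_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alts)
  info <- VariantAnnotation::info(vcf)
  caf_per_alt <- vector("list", length(vcf))
  if ("CAF" %in% names(info)) {
    # dbSNP style: comma list with the reference allele frequency first
    caf_raw <- info$CAF
    for (i in seq_along(vcf)) {
      vals <- suppressWarnings(as.numeric(unlist(strsplit(
        paste(unlist(caf_raw[i]), collapse = ","), ","))))
      caf_per_alt[[i]] <- if (length(vals) >= n_alt[i] + 1L) {
        vals[seq_len(n_alt[i]) + 1L]
      } else rep(NA_real_, n_alt[i])
    }
  } else if ("AF" %in% names(info)) {
    af <- info$AF
    for (i in seq_along(vcf)) {
      vals <- suppressWarnings(as.numeric(unlist(af[i])))
      caf_per_alt[[i]] <- rep_len(vals, n_alt[i])
    }
  } else {
    stop("VCF lacks both CAF and AF INFO fields: ", path, call. = FALSE)
  }
  tibble(
    chrom = rep(as.character(GenomicRanges::seqnames(rr)), n_alt),
    pos = rep(as.integer(GenomicRanges::start(rr)), n_alt),
    snp_id = rep(names(rr) %||% paste0("snp", seq_along(rr)), n_alt),
    ref = rep(ref, n_alt),
    alt = as.character(unlist(alts)),
    caf = unlist(caf_per_alt)
  ) |>
    filter(!is.na(.data$caf))
}

read_snps_tsv <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(0), pos = integer(0), snp_id = character(0),
                  ref = character(0), alt = character(0), caf = numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    stop("SNP TSV line ", which(nf != 6L)[1], ": expected 6 columns, found ",
         nf[nf != 6L][1], call. = FALSE)
  }
  m <- do.call(rbind, fields)
  # tolerate a header line
  if (is.na(suppressWarnings(as.integer(m[1, 2])))) m <- m[-1, , drop = FALSE]
  if (nrow(m) == 0L) {
    return(tibble(chrom = character(0), pos = integer(0), snp_id = character(0),
                  ref = character(0), alt = character(0), caf = numeric(0)))
  }
  pos <- suppressWarnings(as.integer(m[, 2]))
  caf <- suppressWarnings(as.numeric(m[, 6]))
  if (anyNA(pos) || anyNA(caf)) {
    bad <- which(is.na(pos) | is.na(caf))[1]
    stop("SNP TSV line ", bad, ": non-numeric pos or caf", call. = FALSE)
  }
  tibble(chrom = m[, 1], pos = pos, snp_id = m[, 3],
         ref = toupper(m[, 4]), alt = toupper(m[, 5]), caf = caf)
}

#' Genomic windows underlying each junction sequence
#'
#' Returns the two flank-length genomic intervals (1-based inclusive) whose
#' transcribed concatenation is the junction sequence: the donor-side window
#' ends at the donor breakpoint and the acceptor-side window starts at the
#' acceptor breakpoint (sides swap genomically on the minus strand).
#'
#' @param junctions Junction table with `flank` column (from
#'   [make_junctions()]).
#' @return Tibble with `junction_id`, `side` (`"donor"`/`"acceptor"`),
#'   `chrom`, `start`, `end`, `strand`.
#' @export
junction_genomic_intervals <- function(junctions) {
  stopifnot("flank" %in% names(junctions))
  w <- junction_window_coords(junctions, junctions$flank)
  bind_rows(
    tibble(junction_id = junctions$junction_id, side = "donor",
           chrom = junctions$chrom, start = w$donor_win_start,
           end = w$donor_win_end, strand = junctions$strand),
    tibble(junction_id = junctions$junction_id, side = "acceptor",
           chrom = junctions$chrom, start = w$acceptor_win_start,
           end = w$acceptor_win_end, strand = junctions$strand)
  )
}

#' Expand the junction database with common-SNP sequence variants
#'
#' Exact matching misses reads from individuals carrying a common variant
#' inside a junction window. For every SNP falling in a junction's donor or
#' acceptor window and every qualifying alternate allele, one variant
#' junction record is added: same breakpoints, sequence substituted at the
#' single transcribed-orientation offset (on the minus strand the
#' complement of the alternate base is placed). Variants inherit the
#' parent's filter status; `variant_of` names the parent and `snp_ids` the
#' variant(s) applied. A SNP whose reference allele disagrees with the
#' parent sequence at that offset is still applied, with a warning.
#'
#' @param junctions Post-filter junction table.
#' @param snps SNP table from [load_common_snps()].
#' @param pairwise Also emit double-substituted variants for every pair of
#'   SNPs hitting the same junction (default `FALSE`).
#' @return The input table with variant records appended.
#' @export
expand_with_snps <- function(junctions, snps, pairwise = FALSE) {
  if (nrow(junctions) == 0L || is.null(snps) || nrow(snps) == 0L) {
    return(junctions)
  }
  parents <- junctions |> filter(is.na(.data$variant_of), !is.na(.data$sequence))
  if (nrow(parents) == 0L) return(junctions)
  wins <- junction_genomic_intervals(parents) |>
    mutate(.row = rep(seq_len(nrow(parents)), 2L))
  placed <- inner_join(wins, snps, by = "chrom",
                       relationship = "many-to-many") |>
    filter(.data$pos >= .data$start, .data$pos <= .data$end)
  if (nrow(placed) == 0L) return(junctions)

  flank <- parents$flank[placed$.row]
  plus <- placed$strand == "+"
  donor_side <- placed$side == "donor"
  offset <- integer(nrow(placed))
  offset[plus & donor_side] <- (placed$pos - placed$start + 1L)[plus & donor_side]
  offset[plus & !donor_side] <- (flank + placed$pos - placed$start + 1L)[plus & !donor_side]
  offset[!plus & donor_side] <- (placed$end - placed$pos + 1L)[!plus & donor_side]
  offset[!plus & !donor_side] <- (flank + placed$end - placed$pos + 1L)[!plus & !donor_side]
  tx_ref <- ifelse(plus, placed$ref, complement_base(placed$ref))
  tx_alt <- ifelse(plus, placed$alt, complement_base(placed$alt))

  parent_seq <- parents$sequence[placed$.row]
  observed <- substr(parent_seq, offset, offset)
  mismatch <- observed != tx_ref
  if (any(mismatch)) {
    warning(sum(mismatch),
            " SNP(s) whose reference allele disagrees with the junction sequence; ",
            "variant(s) emitted anyway", call. = FALSE)
  }
  var_seq <- parent_seq
  substr(var_seq, offset, offset) <- tx_alt

  variants <- parents[placed$.row, , drop = FALSE]
  variants$sequence <- var_seq
  variants$variant_of <- parents$junction_id[placed$.row]
  variants$snp_ids <- paste0(placed$snp_id, ":", placed$alt)
  variants$junction_id <- paste0(variants$variant_of, "|", variants$snp_ids)
  variants$has_n <- grepl("N", variants$sequence, fixed = TRUE)

  extra <- NULL
  if (pairwise) {
    extra <- snp_pairwise_variants(parents, placed, offset, tx_alt)
  }
  out <- bind_rows(junctions, variants, extra) |>
    distinct(.data$junction_id, .keep_all = TRUE)
  out
}

# double-substituted variants for SNP pairs within one junction
snp_pairwise_variants <- function(parents, placed, offset, tx_alt) {
  res <- list()
  for (r in unique(placed$.row)) {
    idx <- which(placed$.row == r)
    if (length(idx) < 2L) next
    cmb <- utils::combn(idx, 2L)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      if (offset[i] == offset[j]) next  # alleles at the same site don't combine
      s <- parents$sequence[r]
      substr(s, offset[i], offset[i]) <- tx_alt[i]
      substr(s, offset[j], offset[j]) <- tx_alt[j]
      row <- parents[r, , drop = FALSE]
      ids <- paste0(sort(paste0(placed$snp_id[c(i, j)], ":", placed$alt[c(i, j)])),
                    collapse = "+")
      row$sequence <- s
      row$variant_of <- parents$junction_id[r]
      row$snp_ids <- ids
      row$junction_id <- paste0(row$variant_of, "|", ids)
      row$has_n <- grepl("N", s, fixed = TRUE)
      res[[length(res) + 1L]] <- row
    }
  }
  if (length(res) == 0L) NULL else bind_rows(res)
}
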