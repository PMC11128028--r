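# run code under a temporary RNG state so fixture generation is reproducible
# without clobbering the caller's random stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sample integers from an inclusive range; safe for degenerate ranges
# (avoids sample()'s scalar expansion)
sample_range <- function(range, n) {
  v <- seq(range[1], range[2])
  v[sample.int(length(v), n, replace = TRUE)]
}

# lay one multi-exon gene down from a cursor; returns exon rows + new cursor
lay_gene <- function(gene_id, gene_name, chrom, strand, cursor, n_exons,
                     exon_len, intron_len) {
  lens <- sample_range(exon_len, n_exons)
  gaps <- if (n_exons > 1) sample_range(intron_len, n_exons - 1) else integer(0)
  starts <- integer(n_exons)
  pos <- cursor
  rows <- vector("list", n_exons)
  for (i in seq_len(n_exons)) {
    starts[i] <- pos
    rows[[i]] <- tibble(
      gene_id = gene_id, gene_name = gene_name,
      transcript_id = paste0(gene_id, ".t1"),
      chrom = chrom, start = as.integer(pos), end = as.integer(pos + lens[i] - 1L),
      strand = strand
    )
    pos <- pos + lens[i] + (if (i < n_exons) gaps[i] else 0L)
  }
  list(exons = bind_rows(rows), cursor = pos)
}

#' Generate a synthetic test world
#'
#' Builds a fully synthetic, seeded data set exercising every stage of the
#' pipeline: a random genome, a gene annotation laid out as same-strand
#' gene pairs with a planted read-through truth set, a paralog table, a
#' common-SNP table targeting the first planted junction, and per-filter
#' decoy gene pairs. Same seed, same files, byte for byte.
#'
#' Regular pairs alternate strand (`+`, `-`, ...). Each pair is a 5-exon 5'
#' gene and a 4-exon 3' gene (configurable); the planted event joins the
#' rank-2 exon of each. Regions are separated by `region_gap` bp so that,
#' with the default 80 kb gap, genes of different regions never pair under
#' the 70 kb cap.
#'
#' Decoys (each its own extra region, requested by name):
#' * `"paralog"` — a single-exon pair listed in the paralog table.
#' * `"short_exon"` — a pair whose donor exon is 19 bp.
#' * `"same_isoform"` — overlapping genes sharing an exon that is the
#'   donor's immediate successor in the 5' gene's transcript.
#' * `"exon_copy"` — a pair whose junction 40-mer is embedded verbatim in
#'   an unrelated distant exon.
#' * `"similar_exons"` — a pair whose acceptor exon is a 90%-identity copy
#'   of the donor exon.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed (mandatory; reproducibility).
#' @param n_pairs Number of regular planted gene pairs.
#' @param exons5,exons3 Exon counts of the 5' and 3' genes.
#' @param exon_len,intron_len Integer ranges (min, max) in bp.
#' @param pair_gap Range of the intergenic gap inside a pair, bp.
#' @param region_gap Gap between successive regions, bp (default 80000).
#' @param decoys Character vector of decoy names (see Details).
#' @param snp_caf CAF values for the two SNPs planted in the first
#'   junction's donor window (one above, one below the 0.10 default).
#' @return An `rtc_world` list: file paths (`fasta`, `gtf`, `paralogs`,
#'   `snps`, `truth`), in-memory `genome`, `exons`, `truth`, `paralog_pairs`
#'   and `snp_table`.
#' @export
simulate_world <- function(dir, seed, n_pairs = 3, exons5 = 5, exons3 = 4,
                           exon_len = c(80, 200), intron_len = c(300, 900),
                           pair_gap = c(6000, 12000), region_gap = 80000,
                           decoys = character(0),
                           snp_caf = c(0.30, 0.05)) {
  if (missing(seed)) stop("seed is mandatory for reproducible worlds", call. = FALSE)
  known_decoys <- c("paralog", "short_exon", "same_isoform", "exon_copy",
                    "similar_exons")
  if (!all(decoys %in% known_decoys)) {
    stop("unknown decoy(s): ", paste(setdiff(decoys, known_decoys), collapse = ", "),
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  region_gap <- as.integer(region_gap)
  chrom <- "chrT"

  world <- with_seed(seed, {
    cursor <- 1001L
    exon_rows <- list()
    truth_rows <- list()
    paralog_rows <- list()
    edits <- list()  # genome overwrites: list(start, seq)

    for (i in seq_len(n_pairs)) {
      strand <- if (i %% 2L == 1L) "+" else "-"
      idA <- sprintf("RT%02dA", i); idB <- sprintf("RT%02dB", i)
      # left gene first along the genome; on '-' the 5' gene is the right one
      left_id <- if (strand == "+") idA else idB
      right_id <- if (strand == "+") idB else idA
      left_n <- if (strand == "+") exons5 else exons3
      right_n <- if (strand == "+") exons3 else exons5
      g1 <- lay_gene(left_id, left_id, chrom, strand, cursor, left_n,
                     exon_len, intron_len)
      gap <- sample_range(pair_gap, 1)
      g2 <- lay_gene(right_id, right_id, chrom, strand, g1$cursor + gap,
                     right_n, exon_len, intron_len)
      exon_rows[[length(exon_rows) + 1L]] <- g1$exons
      exon_rows[[length(exon_rows) + 1L]] <- g2$exons
      ex5 <- if (strand == "+") g1$exons else g2$exons
      ex3 <- if (strand == "+") g2$exons else g1$exons
      # transcription-order rank 2 exon on each side
      d <- if (strand == "+") ex5[2, ] else ex5[nrow(ex5) - 1L, ]
      a <- if (strand == "+") ex3[2, ] else ex3[nrow(ex3) - 1L, ]
      truth_rows[[length(truth_rows) + 1L]] <- tibble(
        gene5_id = idA, gene3_id = idB, chrom = chrom, strand = strand,
        donor_start = d$start, donor_end = d$end,
        donor_bp = if (strand == "+") d$end else d$start,
        acceptor_start = a$start, acceptor_end = a$end,
        acceptor_bp = if (strand == "+") a$start else a$end
      )
      cursor <- g2$cursor + region_gap
    }

    if ("paralog" %in% decoys) {
      p1 <- lay_gene("PARA", "PARA", chrom, "+", cursor, 1, c(120, 160), intron_len)
      p2 <- lay_gene("PARB", "PARB", chrom, "+", p1$cursor + 3000L, 1,
                     c(120, 160), intron_len)
      exon_rows <- c(exon_rows, list(p1$exons, p2$exons))
      paralog_rows[[length(paralog_rows) + 1L]] <- tibble(a = "PARA", b = "PARB")
      cursor <- p2$cursor + region_gap
    }
    if ("short_exon" %in% decoys) {
      s1 <- lay_gene("SHRTA", "SHRTA", chrom, "+", cursor, 1, c(19, 19), intron_len)
      s2 <- lay_gene("SHRTB", "SHRTB", chrom, "+", s1$cursor + 3000L, 1,
                     c(120, 160), intron_len)
      exon_rows <- c(exon_rows, list(s1$exons, s2$exons))
      cursor <- s2$cursor + region_gap
    }
    if ("same_isoform" %in% decoys) {
      ov <- lay_gene("OVLA", "OVLA", chrom, "+", cursor, 2, c(120, 160),
                     c(1500, 2500))
      # OVLB's single exon reuses the exact coordinates of OVLA's exon 2
      e2 <- ov$exons[2, ]
      ovb <- tibble(gene_id = "OVLB", gene_name = "OVLB",
                    transcript_id = "OVLB.t1", chrom = chrom,
                    start = e2$start, end = e2$end, strand = "+")
      exon_rows <- c(exon_rows, list(ov$exons, ovb))
      cursor <- ov$cursor + region_gap
    }
    if ("exon_copy" %in% decoys) {
      c1 <- lay_gene("CPYA", "CPYA", chrom, "+", cursor, 1, c(120, 160), intron_len)
      c2 <- lay_gene("CPYB", "CPYB", chrom, "+", c1$cursor + 3000L, 1,
                     c(120, 160), intron_len)
      # distant lone gene carrying the CPYA-CPYB junction 40-mer inside its exon
      x <- lay_gene("XCPY", "XCPY", chrom, "+", c2$cursor + region_gap, 1,
                    c(100, 100), intron_len)
      exon_rows <- c(exon_rows, list(c1$exons, c2$exons, x$exons))
      edits[[length(edits) + 1L]] <- list(
        kind = "exon_copy",
        donor_end = c1$exons$end[1], acceptor_start = c2$exons$start[1],
        target = x$exons$start[1] + 30L
      )
      cursor <- x$cursor + region_gap
    }
    if ("similar_exons" %in% decoys) {
      m1 <- lay_gene("SIMA", "SIMA", chrom, "+", cursor, 1, c(150, 150), intron_len)
      m2 <- lay_gene("SIMB", "SIMB", chrom, "+", m1$cursor + 3000L, 1,
                     c(150, 150), intron_len)
      exon_rows <- c(exon_rows, list(m1$exons, m2$exons))
      edits[[length(edits) + 1L]] <- list(
        kind = "similar_exons",
        src_start = m1$exons$start[1], src_end = m1$exons$end[1],
        dst_start = m2$exons$start[1]
      )
      cursor <- m2$cursor + region_gap
    }

    chrom_len <- cursor + 1000L
    seq_chars <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)

    for (ed in edits) {
      if (ed$kind == "exon_copy") {
        kmer <- c(seq_chars[(ed$donor_end - 19L):ed$donor_end],
                  seq_chars[ed$acceptor_start:(ed$acceptor_start + 19L)])
        seq_chars[ed$target:(ed$target + 39L)] <- kmer
      } else if (ed$kind == "similar_exons") {
        src <- seq_chars[ed$src_start:ed$src_end]
        n <- length(src)
        mut_at <- seq(3L, n, by = 10L)  # ~90% identity copy
        src[mut_at] <- vapply(src[mut_at], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, character(1))
        seq_chars[ed$dst_start:(ed$dst_start + n - 1L)] <- src
      }
    }

    exons <- bind_rows(exon_rows) |>
      group_by(.data$transcript_id) |>
      arrange(ifelse(.data$strand == "+", .data$start, -.data$start),
              .by_group = TRUE) |>
      mutate(rank = row_number()) |>
      ungroup() |>
      mutate(exon_id = paste0(.data$chrom, ":", .data$start, "-", .data$end,
                              "(", .data$strand, ")"),
             width = .data$end - .data$start + 1L) |>
      select("gene_id", "gene_name", "transcript_id", "exon_id", "chrom",
             "start", "end", "strand", "rank", "width")
    truth <- bind_rows(truth_rows) |>
      mutate(distance = abs(.data$acceptor_bp - .data$donor_bp))
    paralogs <- if (length(paralog_rows)) bind_rows(paralog_rows) else {
      tibble(a = character(0), b = character(0))
    }

    genome_seq <- paste(seq_chars, collapse = "")

    # two SNPs in the first planted junction's donor window: one common,
    # one rare; plus one indel row that the loader must drop
    snp_tbl <- NULL
    if (nrow(truth) > 0L) {
      t1 <- truth[1, ]
      pos_common <- if (t1$strand == "+") t1$donor_bp - 15L else t1$donor_bp + 15L
      pos_rare <- if (t1$strand == "+") t1$donor_bp - 10L else t1$donor_bp + 10L
      ref_common <- substr(genome_seq, pos_common, pos_common)
      ref_rare <- substr(genome_seq, pos_rare, pos_rare)
      alt_common <- setdiff(c("A", "C", "G", "T"), ref_common)[1]
      alt_rare <- setdiff(c("A", "C", "G", "T"), ref_rare)[1]
      snp_tbl <- tibble(
        chrom = chrom,
        pos = c(pos_common, pos_rare, pos_rare + 200L),
        snp_id = c("rsCOMMON", "rsRARE", "rsINDEL"),
        ref = c(ref_common, ref_rare, "AT"),
        alt = c(alt_common, alt_rare, "A"),
        caf = c(snp_caf[1], snp_caf[2], 0.50)
      )
    }
    list(exons = exons, truth = truth, paralogs = paralogs,
         genome_seq = genome_seq, snp_tbl = snp_tbl)
  })

  genome <- Biostrings::DNAStringSet(setNames(world$genome_seq, chrom))
  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    paralogs = file.path(dir, "paralogs.tsv"),
    snps = file.path(dir, "snps.tsv"),
    truth_tsv = file.path(dir, "truth.tsv")
  )
  Biostrings::writeXStringSet(genome, paths$fasta, width = 70L)
  write_gtf(world$exons, paths$gtf)
  readr::write_tsv(world$paralogs, paths$paralogs, col_names = FALSE)
  if (!is.null(world$snp_tbl)) {
    readr::write_tsv(world$snp_tbl, paths$snps, col_names = FALSE)
  }
  readr::write_tsv(world$truth, paths$truth_tsv)

  structure(c(paths, list(genome = genome, exons = world$exons,
                          truth = world$truth, paralog_pairs = world$paralogs,
                          snp_table = world$snp_tbl, seed = seed, dir = dir)),
            class = "rtc_world")
}

# serialize an exon table as Ensembl-dialect GTF exon features
write_gtf <- function(exons, path) {
  attrs <- sprintf(
    'gene_id "%s"; transcript_id "%s"; gene_name "%s"; exon_number "%d";',
    exons$gene_id, exons$transcript_id, exons$gene_name, exons$rank)
  lines <- paste(exons$chrom, "rtchimera", "exon", exons$start, exons$end,
                 ".", exons$strand, ".", attrs, sep = "\t")
  readr::write_lines(lines, path)
}

# spliced transcript sequences (transcribed orientation), one per transcript
transcript_sequences <- function(exons, genome) {
  exons |>
    group_by(.data$transcript_id) |>
    arrange(.data$rank, .by_group = TRUE) |>
    summarise(gene_id = first(.data$gene_id),
              seq = paste(exon_sequence(dplyr::pick(dplyr::everything()), genome),
                          collapse = ""),
              .groups = "drop")
}

# chimeric transcript per truth row: 5' exons through the donor, then 3'
# exons from the acceptor onward
chimeric_sequences <- function(world, genome) {
  ex <- world$exons
  purrr::pmap(as.list(world$truth), function(gene5_id, gene3_id, chrom, strand,
                                             donor_start, donor_end, donor_bp,
                                             acceptor_start, acceptor_end,
                                             acceptor_bp, ...) {
    e5 <- ex |> filter(.data$gene_id == gene5_id) |> arrange(.data$rank)
    e3 <- ex |> filter(.data$gene_id == gene3_id) |> arrange(.data$rank)
    d_rank <- e5$rank[e5$start == donor_start & e5$end == donor_end][1]
    a_rank <- e3$rank[e3$start == acceptor_start & e3$end == acceptor_end][1]
    part5 <- e5 |> filter(.data$rank <= d_rank)
    part3 <- e3 |> filter(.data$rank >= a_rank)
    seq <- paste(c(exon_sequence(part5, genome), exon_sequence(part3, genome)),
                 collapse = "")
    list(name = paste0(gene5_id, "-", gene3_id), seq = seq,
         junction_at = sum(part5$width))
  })
}

#' Simulate RNA-seq reads from a synthetic world
#'
#' Draws error-free (by default) reads uniformly along every normal
#' transcript and every planted chimeric transcript of the world. With zero
#' error rate, any read overlapping a planted junction by at least the
#' flank on both sides contains the exact junction k-mer. Optionally the
#' reads are drawn from an ALT haplotype: the given SNP alleles are
#' substituted into the genome before transcript extraction.
#'
#' @param world An `rtc_world` from [simulate_world()].
#' @param out Output FASTQ path (`.gz` honoured). For paired mode the mate
#'   files get `_1` / `_2` inserted before the extension.
#' @param read_len Read length in nt (default 101).
#' @param depth Reads drawn per transcript (default 150).
#' @param paired Paired-end mode (default `FALSE`).
#' @param fragment_len Paired-end fragment length (default 250).
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed Integer seed (mandatory).
#' @param alt_snp_ids SNP ids (from the world's SNP table) substituted into
#'   the genome before simulating (ALT haplotype), or `NULL`.
#' @return List: `files` (FASTQ paths), `n_reads`, and
#'   `junction_reads` — tibble counting reads that fully contain each
#'   planted junction k-mer.
#' @export
simulate_reads <- function(world, out, read_len = 101, depth = 150,
                           paired = FALSE, fragment_len = 250,
                           error_rate = 0, seed, alt_snp_ids = NULL) {
  if (missing(seed)) stop("seed is mandatory for reproducible reads", call. = FALSE)
  stopifnot(read_len >= 1)
  genome <- world$genome
  if (!is.null(alt_snp_ids)) {
    stopifnot(!is.null(world$snp_table))
    snps <- world$snp_table |> filter(.data$snp_id %in% alt_snp_ids)
    gseq <- as.character(genome[[1]])
    for (i in seq_len(nrow(snps))) {
      if (nchar(snps$ref[i]) != 1L || nchar(snps$alt[i]) != 1L) next
      substr(gseq, snps$pos[i], snps$pos[i]) <- snps$alt[i]
    }
    genome <- Biostrings::DNAStringSet(setNames(gseq, names(world$genome)[1]))
  }

  normal <- transcript_sequences(world$exons, genome)
  chims <- chimeric_sequences(world, genome)
  templates <- c(
    purrr::map2(normal$transcript_id, normal$seq, ~list(name = .x, seq = .y)),
    chims
  )

  min_len <- if (paired) max(fragment_len, read_len) else read_len
  recs <- with_seed(seed, {
    out_recs <- list()
    for (tp in templates) {
      L <- nchar(tp$seq)
      if (L < min_len) next
      span <- if (paired) fragment_len else read_len
      starts <- sample.int(L - span + 1L, depth, replace = TRUE)
      if (paired) {
        frag <- substr(rep(tp$seq, depth), starts, starts + span - 1L)
        r1 <- substr(frag, 1L, read_len)
        r2 <- revcomp(substr(frag, span - read_len + 1L, span))
        ids <- sprintf("%s_f%04d", tp$name, seq_len(depth))
        out_recs[[length(out_recs) + 1L]] <-
          tibble(id = paste0(ids, "/1"), seq = r1, file = 1L)
        out_recs[[length(out_recs) + 1L]] <-
          tibble(id = paste0(ids, "/2"), seq = r2, file = 2L)
      } else {
        seqs <- substr(rep(tp$seq, depth), starts, starts + read_len - 1L)
        out_recs[[length(out_recs) + 1L]] <- tibble(
          id = sprintf("%s_r%04d", tp$name, seq_len(depth)), seq = seqs,
          file = 1L)
      }
    }
    recs <- bind_rows(out_recs)
    if (nrow(recs) > 0L && error_rate > 0) {
      recs$seq <- vapply(recs$seq, function(s) {
        b <- strsplit(s, "")[[1]]
        hit <- which(stats::runif(length(b)) < error_rate)
        if (length(hit)) {
          b[hit] <- vapply(b[hit], function(x) {
            sample(setdiff(c("A", "C", "G", "T"), x), 1)
          }, character(1))
        }
        paste(b, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    recs
  })

  write_one <- function(df, path) {
    if (nrow(df) == 0L) {
      readr::write_lines(character(0), path)
      return(invisible(NULL))
    }
    lines <- as.vector(rbind(paste0("@", df$id), df$seq, "+",
                             strrep("I", nchar(df$seq))))
    readr::write_lines(lines, path)
  }
  if (paired) {
    f1 <- sub("(\\.f(ast)?q)(\\.gz)?$", "_1\\1\\3", out)
    f2 <- sub("(\\.f(ast)?q)(\\.gz)?$", "_2\\1\\3", out)
    write_one(recs |> filter(.data$file == 1L), f1)
    write_one(recs |> filter(.data$file == 2L), f2)
    files <- c(f1, f2)
  } else {
    write_one(recs, out)
    files <- out
  }

  # bookkeeping: how many reads fully contain each planted junction k-mer
  flank <- 20L
  jr <- purrr::map(chims, function(ch) {
    kmer <- substr(ch$seq, ch$junction_at - flank + 1L, ch$junction_at + flank)
    rc <- revcomp(kmer)
    n <- if (nrow(recs) == 0L) 0L else {
      sum(grepl(kmer, recs$seq, fixed = TRUE) |
            grepl(rc, recs$seq, fixed = TRUE))
    }
    tibble(event = ch$name, kmer = kmer, n_containing_reads = n)
  }) |> bind_rows()

  list(files = files, n_reads = nrow(recs), junction_reads = jr)
}
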