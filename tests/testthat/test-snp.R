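write_snp_tsv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(rows, path)
  path
}

test_that("SNP TSV loading applies the frequency threshold and drops indels", {
  path <- write_snp_tsv(c(
    "chrT\t100\trs1\tA\tG\t0.15",
    "chrT\t200\trs2\tC\tT\t0.05",
    "chrT\t300\trs3\tAT\tA\t0.50",
    "chrT\t400\trs4\tG\tGG\t0.50"
  ))
  snps <- load_common_snps(path)
  expect_identical(snps$snp_id, "rs1")
  dropped <- attr(snps, "dropped")
  expect_identical(unname(dropped["not_snv"]), 2L)
  expect_identical(unname(dropped["low_caf"]), 1L)

  bad <- write_snp_tsv(c("chrT\t100\trs1\tA\tG\t0.15", "chrT\tx"))
  expect_error(load_common_snps(bad), "line 2")
})

test_that("VCF input works with dbSNP-style CAF and with AF, multi-allelic", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=CAF,Number=.,Type=String,Description="ref,alt freqs">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chrT\t150\trsA\tA\tG\t.\t.\tCAF=0.7,0.3",
    "chrT\t250\trsB\tC\tG,T\t.\t.\tCAF=0.6,0.25,0.15",
    "chrT\t350\trsC\tG\tA\t.\t.\tCAF=0.95,0.05"
  ), vcf)
  snps <- load_common_snps(vcf)
  expect_identical(nrow(snps), 3L)
  expect_setequal(snps$snp_id, c("rsA", "rsB"))
  expect_setequal(snps$alt[snps$snp_id == "rsB"], c("G", "T"))
  expect_false("rsC" %in% snps$snp_id)

  vcf2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=AF,Number=A,Type=Float,Description="alt freq">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chrT\t150\trsD\tA\tC\t.\t.\tAF=0.4",
    "chrT\t250\trsE\tT\tG\t.\t.\tAF=0.02"
  ), vcf2)
  snps2 <- load_common_snps(vcf2)
  expect_identical(snps2$snp_id, "rsD")
  expect_equal(snps2$caf, 0.4)
})

test_that("junction windows are the two flank-length genomic intervals", {
  s <- toy_chrom(400)
  g <- dna_set(c(chrT = s))
  ex <- rank_exons(dplyr::bind_rows(
    exon_row("A", "A.t1", "chrT", 101, 200, "+"),
    exon_row("B", "B.t1", "chrT", 251, 300, "+")
  ))
  j <- make_junctions(enumerate_exon_combinations(ex), g)
  w <- junction_genomic_intervals(j)
  expect_identical(nrow(w), 2L)
  expect_identical(w$end - w$start + 1L, c(20L, 20L))
  donor <- w[w$side == "donor", ]
  expect_identical(c(donor$start, donor$end), c(181L, 200L))
  acceptor <- w[w$side == "acceptor", ]
  expect_identical(c(acceptor$start, acceptor$end), c(251L, 270L))
})

test_that("window re-extraction reproduces the stored sequence on both strands", {
  w <- decoy_world()
  combos <- enumerate_exon_combinations(w$exons)
  j <- make_junctions(combos, w$genome, on_short = "na") |>
    dplyr::filter(!is.na(sequence))
  wins <- junction_genomic_intervals(j)
  rebuilt <- wins |>
    dplyr::mutate(piece = exon_sequence(
      tibble::tibble(chrom = chrom, start = start, end = end, strand = strand),
      w$genome)) |>
    dplyr::group_by(junction_id) |>
    dplyr::summarise(seq = paste(piece[side == "donor"],
                                 piece[side == "acceptor"], sep = ""),
                     .groups = "drop")
  cmp <- dplyr::left_join(j, rebuilt, by = "junction_id")
  expect_identical(cmp$seq, cmp$sequence)
})

test_that("SNP expansion substitutes exactly one transcribed-orientation base", {
  s <- toy_chrom(400)
  g <- dna_set(c(chrT = s))
  ex <- rank_exons(dplyr::bind_rows(
    exon_row("A", "A.t1", "chrT", 101, 200, "+"),
    exon_row("B", "B.t1", "chrT", 251, 300, "+")
  ))
  j <- make_junctions(enumerate_exon_combinations(ex), g)
  # donor window is [181,200]; position 185 is transcribed offset 5
  ref5 <- substr(s, 185, 185)
  alt5 <- setdiff(c("A", "C", "G", "T"), ref5)[1]
  snps <- tibble::tibble(chrom = "chrT", pos = 185L, snp_id = "rs5",
                         ref = ref5, alt = alt5, caf = 0.3)
  out <- expand_with_snps(j, snps)
  expect_identical(nrow(out), 2L)
  v <- out[!is.na(out$variant_of), ]
  diffs <- which(strsplit(v$sequence, "")[[1]] !=
                   strsplit(j$sequence, "")[[1]])
  expect_identical(diffs, 5L)
  expect_identical(substr(v$sequence, 5, 5), alt5)
  expect_identical(v$variant_of, j$junction_id)

  # a SNP outside both windows adds nothing
  outside <- tibble::tibble(chrom = "chrT", pos = 220L, snp_id = "rsX",
                            ref = substr(s, 220, 220), alt = "A", caf = 0.3)
  expect_identical(nrow(expand_with_snps(j, outside)), nrow(j))

  # multi-allelic: one variant record per qualifying alt
  alts2 <- setdiff(c("A", "C", "G", "T"), ref5)[1:2]
  multi <- tibble::tibble(chrom = "chrT", pos = 185L,
                          snp_id = "rsM", ref = ref5, alt = alts2,
                          caf = c(0.3, 0.2))
  out2 <- expand_with_snps(j, multi)
  expect_identical(sum(!is.na(out2$variant_of)), 2L)

  # disagreeing reference allele: variant still emitted, with a warning
  wrong <- tibble::tibble(chrom = "chrT", pos = 185L, snp_id = "rsW",
                          ref = alt5, alt = ref5, caf = 0.3)
  expect_warning(out3 <- expand_with_snps(j, wrong), "disagrees")
  expect_identical(sum(!is.na(out3$variant_of)), 1L)
})

test_that("minus-strand expansion places the complemented alternate allele", {
  s <- toy_chrom(400)
  g <- dna_set(c(chrT = s))
  ex <- rank_exons(dplyr::bind_rows(
    exon_row("A", "A.t1", "chrT", 201, 300, "-"),   # 5' gene: larger coords
    exon_row("B", "B.t1", "chrT", 101, 150, "-")
  ))
  j <- make_junctions(enumerate_exon_combinations(ex), g)
  # donor breakpoint is the exon start (201); donor window [201,220];
  # genomic position 210 maps to transcribed offset 220 - 210 + 1 = 11
  ref_g <- substr(s, 210, 210)
  alt_g <- setdiff(c("A", "C", "G", "T"), ref_g)[1]
  snps <- tibble::tibble(chrom = "chrT", pos = 210L, snp_id = "rsm",
                         ref = ref_g, alt = alt_g, caf = 0.5)
  out <- expand_with_snps(j, snps)
  v <- out[!is.na(out$variant_of), ]
  expect_identical(nrow(v), 1L)
  expect_identical(substr(v$sequence, 11, 11),
                   rtchimera:::complement_base(alt_g))
  # exactly one position differs
  expect_identical(sum(strsplit(v$sequence, "")[[1]] !=
                         strsplit(j$sequence, "")[[1]]), 1L)
})

test_that("expansion never removes records and grows by one per in-window alt", {
  w <- figure_world()
  combos <- enumerate_exon_combinations(w$exons)
  j <- make_junctions(combos, w$genome)
  snps <- load_common_snps(w$snps)
  out <- expand_with_snps(j, snps)
  expect_gte(nrow(out), nrow(j))
  expect_true(all(j$junction_id %in% out$junction_id))
  v <- out[!is.na(out$variant_of), ]
  for (k in seq_len(nrow(v))) {
    parent <- out$sequence[out$junction_id == v$variant_of[k]]
    d <- sum(strsplit(v$sequence[k], "")[[1]] != strsplit(parent, "")[[1]])
    expect_identical(d, 1L)
  }
})
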