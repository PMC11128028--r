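test_that("local alignment scores agree with an explicit dynamic-programming oracle", {
  set.seed(31)
  for (i in 1:8) {
    q <- random_dna_str(sample(12:25, 1))
    s <- random_dna_str(sample(20:40, 1))
    got <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(q), s, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = FALSE),
      gapOpening = 5, gapExtension = 2)
    expect_equal(Biostrings::score(got), sw_score(q, s),
                 info = paste(q, s))
  }
})

test_that("local_align reports identity and coverage per the contract", {
  x <- strrep("ACGT", 10)
  ident <- local_align(x, x)
  expect_equal(ident$identity, 1.0)
  expect_equal(ident$query_coverage, 1.0)

  # query whose first half is a verbatim subject block and whose second half
  # cannot extend the alignment: best local hit covers exactly half the query
  block <- strrep("ACT", 7)                      # 21 nt, G-free
  subject <- paste0(substr(block, 1, 20), strrep("C", 20))
  query <- paste0(substr(block, 1, 20), strrep("G", 20))
  half <- local_align(query, subject)
  expect_equal(half$query_coverage, 0.5)
  expect_equal(half$identity, 1.0)

  # empty inputs give a zero-coverage summary
  z <- local_align("", "ACGT")
  expect_equal(z$query_coverage, 0)
  expect_equal(local_align("ACGT", "")$query_coverage, 0)

  # dissimilar random 40-mers never reach discard-grade coverage
  set.seed(77)
  a <- random_dna_str(40); b <- random_dna_str(40)
  dis <- local_align(a, b)
  expect_lt(dis$query_coverage, 0.9)
})

test_that("paralog filter removes exactly the listed gene pairs", {
  jt <- tibble::tibble(gene5_id = c("G1", "G1"), gene3_id = c("G2", "G3"))
  rel <- tibble::tibble(a = "G1", b = "G2")
  expect_identical(paralog_filter(jt, rel)$gene3_id, "G3")
  # membership is order-independent: the reversed pair filters identically
  jt_swapped <- tibble::tibble(gene5_id = c("G2", "G3"),
                               gene3_id = c("G1", "G1"))
  expect_identical(paralog_filter(jt_swapped, rel)$gene5_id, "G3")
  empty <- tibble::tibble(a = character(0), b = character(0))
  expect_identical(paralog_filter(jt, empty), jt)
})

test_that("flank-length filter boundary sits exactly at the flank", {
  jt <- tibble::tibble(donor_len = c(19L, 20L, 1000L),
                       acceptor_len = c(100L, 20L, 1000L))
  kept <- flank_length_filter(jt, flank = 20)
  expect_identical(kept$donor_len, c(20L, 1000L))
})

test_that("same-isoform filter discards only transcript-consecutive shared exons", {
  # gene O1 transcript: e1 [100,150] -> e2 [300,350] -> e3 [500,550]
  # gene O2 single exon at e2's exact coordinates
  ex <- rank_exons(dplyr::bind_rows(
    exon_row("O1", "O1.t1", "chrT", 100, 150, "+"),
    exon_row("O1", "O1.t1", "chrT", 300, 350, "+"),
    exon_row("O1", "O1.t1", "chrT", 500, 550, "+"),
    exon_row("O2", "O2.t1", "chrT", 300, 350, "+")
  ))
  combos <- enumerate_exon_combinations(ex)
  # donor e1 -> acceptor e2-copy: consecutive in O1's transcript => discarded
  adjacent <- combos[combos$donor_end == 150L & combos$acceptor_start == 300L, ]
  expect_identical(nrow(same_isoform_filter(adjacent, ex)), 0L)

  # two ranks downstream: gene O3's exon matches e3 (not e2) => kept
  ex2 <- rank_exons(dplyr::bind_rows(
    ex[ex$gene_id == "O1", ],
    exon_row("O3", "O3.t1", "chrT", 500, 550, "+")
  ))
  combos2 <- enumerate_exon_combinations(ex2)
  skip_one <- combos2[combos2$gene3_id == "O3" & combos2$donor_end == 150L, ]
  expect_identical(nrow(same_isoform_filter(skip_one, ex2)), 1L)

  # non-overlapping genes: identity
  w <- figure_world()
  combos3 <- enumerate_exon_combinations(w$exons)
  expect_identical(nrow(same_isoform_filter(combos3, w$exons)), nrow(combos3))
})

test_that("exon filter discards junctions matching an exon at 90/90", {
  set.seed(41)
  g_seq <- random_dna_str(2000)
  jseq <- substr(g_seq, 1001, 1040)      # junction 40-mer sits inside exon E
  genome <- dna_set(c(chrT = g_seq))
  exons <- rank_exons(exon_row("E", "E.t1", "chrT", 950, 1100, "+"))
  jt <- tibble::tibble(sequence = jseq)
  expect_identical(nrow(exon_filter(jt, exons, genome)), 0L)

  # only 30 of 40 bases present in any exon: 75% coverage, kept
  jt_partial <- tibble::tibble(
    sequence = paste0(substr(g_seq, 1001, 1030), strrep("A", 10)))
  expect_identical(nrow(exon_filter(jt_partial, exons, genome)), 1L)

  # 38/40 identity over the full junction length (95%): discarded
  mutated <- jseq
  substr(mutated, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                   substr(jseq, 5, 5))[1]
  substr(mutated, 25, 25) <- setdiff(c("A", "C", "G", "T"),
                                     substr(jseq, 25, 25))[1]
  expect_identical(nrow(exon_filter(tibble::tibble(sequence = mutated),
                                    exons, genome)), 0L)
})

test_that("exon filter at thresholds 1.0/1.0 equals the substring oracle", {
  set.seed(51)
  g_seq <- random_dna_str(3000)
  genome <- dna_set(c(chrT = g_seq))
  exons <- rank_exons(dplyr::bind_rows(
    exon_row("E1", "E1.t1", "chrT", 101, 400, "+"),
    exon_row("E2", "E2.t1", "chrT", 1001, 1300, "+")
  ))
  exon_seqs <- exon_sequence(exons, genome)
  jt <- tibble::tibble(sequence = c(
    substr(g_seq, 150, 189),               # inside E1
    substr(g_seq, 1200, 1239),             # inside E2
    random_dna_str(40), random_dna_str(40) # not contained
  ))
  kept <- exon_filter(jt, exons, genome, id_min = 1.0, cov_min = 1.0)
  oracle_hit <- substring_hit_oracle(jt$sequence, exon_seqs)
  expect_identical(kept$sequence, jt$sequence[!oracle_hit])
  expect_identical(sum(oracle_hit), 2L)
})

test_that("similarity filter discards cross-similar participating exons", {
  set.seed(61)
  donor_seq <- random_dna_str(150)
  other <- random_dna_str(150)
  g_seq <- paste0(random_dna_str(100), donor_seq, random_dna_str(3000),
                  donor_seq, random_dna_str(200), other, random_dna_str(100))
  genome <- dna_set(c(chrT = g_seq))
  # gene A exon duplicated verbatim as the first exon of gene B
  exA <- exon_row("A", "A.t1", "chrT", 101, 250, "+")
  exB1 <- exon_row("B", "B.t1", "chrT", 3251, 3400, "+")   # copy of A's exon
  exB2 <- exon_row("B", "B.t1", "chrT", 3601, 3750, "+")   # unrelated
  ex <- rank_exons(dplyr::bind_rows(exA, exB1, exB2))
  combos <- enumerate_exon_combinations(ex) |>
    dplyr::filter(gene5_id == "A")
  kept <- similarity_filter(combos, ex, genome)
  expect_identical(nrow(kept), 0L)

  # with the duplicate removed nothing is cross-similar: identity transform
  ex2 <- rank_exons(dplyr::bind_rows(exA, exB2))
  combos2 <- enumerate_exon_combinations(ex2) |>
    dplyr::filter(gene5_id == "A")
  expect_identical(nrow(similarity_filter(combos2, ex2, genome)),
                   nrow(combos2))
})

test_that("the cascade discards one decoy per stage and is order-invariant", {
  w <- decoy_world()
  ex <- load_annotation(w$gtf)
  genome <- load_genome(w$fasta)
  rel <- load_paralogs(w$paralogs)
  combos <- enumerate_exon_combinations(ex)
  res <- run_prefilter_cascade(combos, ex, genome, rel)
  expect_identical(res$tally$stage,
                   c("input", "paralog", "flank_length", "same_isoform",
                     "exon", "similarity"))
  expect_identical(res$tally$discarded, c(0L, 1L, 1L, 1L, 1L, 1L))
  expect_identical(diff(-res$tally$retained), res$tally$discarded[-1])

  # surviving set is independent of stage order (tallies are not)
  perm <- run_prefilter_cascade(
    combos, ex, genome, rel,
    order = c("similarity", "exon", "same_isoform", "flank_length", "paralog"))
  expect_identical(perm$junctions$junction_id, res$junctions$junction_id)
  perm2 <- run_prefilter_cascade(
    combos, ex, genome, rel,
    order = c("same_isoform", "paralog", "similarity", "flank_length", "exon"))
  expect_identical(perm2$junctions$junction_id, res$junctions$junction_id)

  # filters never mutate surviving sequences or coordinates
  survivors <- res$junctions
  rebuilt <- make_junctions(
    combos[combos$donor_bp %in% survivors$donor_bp &
             combos$acceptor_bp %in% survivors$acceptor_bp, ],
    genome)
  expect_true(all(survivors$sequence %in% rebuilt$sequence))
})

test_that("a world without decoys passes the cascade untouched", {
  w <- figure_world()
  combos <- enumerate_exon_combinations(w$exons)
  res <- run_prefilter_cascade(combos, w$exons, w$genome,
                               load_paralogs(NULL))
  expect_identical(nrow(res$junctions), nrow(combos))
  expect_true(all(res$tally$discarded == 0L))
})
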