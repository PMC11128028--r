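test_that("a 5x4-exon same-strand pair yields exactly 20 combinations", {
  w <- figure_world()
  combos <- enumerate_exon_combinations(w$exons)
  expect_identical(nrow(combos), 20L)
  pairs <- enumerate_candidate_pairs(w$exons)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$gene5_id, "RT01A")
  expect_identical(pairs$gene3_id, "RT01B")
  # m x n law holds per flank-eligible pair when all distances are in range
  expect_identical(nrow(combos), 5L * 4L)
})

test_that("opposite strands never pair and the distance cap is enforced", {
  ex <- rank_exons(dplyr::bind_rows(
    exon_row("A", "A.t1", "chrT", 100, 300, "+"),
    exon_row("B", "B.t1", "chrT", 5000, 5200, "-")
  ))
  expect_identical(nrow(enumerate_exon_combinations(ex)), 0L)

  # brute-force distance oracle on the figure world: every reduced cap
  # keeps exactly the combinations whose stored distance is within it
  w <- figure_world()
  all20 <- enumerate_exon_combinations(w$exons)
  for (cap in c(0, min(all20$distance), stats::median(all20$distance),
                max(all20$distance) - 1L)) {
    got <- enumerate_exon_combinations(w$exons, max_distance = cap)
    expect_identical(nrow(got), sum(all20$distance <= cap))
  }
  # cap below the closest possible combination removes the pair entirely
  expect_identical(
    nrow(enumerate_candidate_pairs(w$exons,
                                   max_distance = min(all20$distance) - 1L)),
    0L)
})

test_that("a single-exon x single-exon pair yields exactly one combination", {
  ex <- rank_exons(dplyr::bind_rows(
    exon_row("A", "A.t1", "chrT", 100, 300, "+"),
    exon_row("B", "B.t1", "chrT", 5000, 5200, "+")
  ))
  combos <- enumerate_exon_combinations(ex)
  expect_identical(nrow(combos), 1L)
  expect_identical(combos$donor_bp, 300L)
  expect_identical(combos$acceptor_bp, 5000L)
})

test_that("stored distances always recompute from the stored breakpoints", {
  w <- decoy_world()
  combos <- enumerate_exon_combinations(w$exons)
  expect_identical(combos$distance,
                   abs(combos$acceptor_bp - combos$donor_bp))
})

test_that("junction sequence composition matches a hand-computed example", {
  s <- toy_chrom(400)
  g <- dna_set(c(chrT = s))
  ex <- rank_exons(dplyr::bind_rows(
    exon_row("A", "A.t1", "chrT", 101, 200, "+"),
    exon_row("B", "B.t1", "chrT", 251, 300, "+")
  ))
  combos <- enumerate_exon_combinations(ex)
  j <- make_junctions(combos, g)
  expect_identical(j$donor_bp, 200L)
  expect_identical(j$acceptor_bp, 251L)
  expect_identical(j$distance, 51L)
  expect_identical(j$sequence,
                   paste0(substr(s, 181, 200), substr(s, 251, 270)))
  expect_identical(nchar(j$sequence), 40L)
})

test_that("minus-strand mirror world reproduces the same junction sequence", {
  s <- toy_chrom(400)
  L <- 400L
  g_fwd <- dna_set(c(chrT = s))
  g_rc <- dna_set(c(chrT = revcomp(s)))
  ex_fwd <- rank_exons(dplyr::bind_rows(
    exon_row("A", "A.t1", "chrT", 101, 200, "+"),
    exon_row("B", "B.t1", "chrT", 251, 300, "+")
  ))
  # coordinate-flip the same two exons onto the minus strand of the
  # reverse-complemented chromosome
  ex_rev <- rank_exons(dplyr::bind_rows(
    exon_row("A", "A.t1", "chrT", L + 1L - 200L, L + 1L - 101L, "-"),
    exon_row("B", "B.t1", "chrT", L + 1L - 300L, L + 1L - 251L, "-")
  ))
  j_fwd <- make_junctions(enumerate_exon_combinations(ex_fwd), g_fwd)
  j_rev <- make_junctions(enumerate_exon_combinations(ex_rev), g_rc)
  expect_identical(j_rev$sequence, j_fwd$sequence)
  expect_identical(j_rev$distance, j_fwd$distance)
  expect_identical(j_rev$donor_bp, L + 1L - j_fwd$donor_bp)
  expect_identical(j_rev$acceptor_bp, L + 1L - j_fwd$acceptor_bp)
})

test_that("exons shorter than the flank are a FlankTooShort error (boundary 20)", {
  s <- toy_chrom(400)
  g <- dna_set(c(chrT = s))
  short <- rank_exons(dplyr::bind_rows(
    exon_row("A", "A.t1", "chrT", 101, 119, "+"),   # 19 bp
    exon_row("B", "B.t1", "chrT", 251, 300, "+")
  ))
  combos <- enumerate_exon_combinations(short)
  expect_error(make_junctions(combos, g), "FlankTooShort")
  expect_true(is.na(make_junctions(combos, g, on_short = "na")$sequence))

  ok <- rank_exons(dplyr::bind_rows(
    exon_row("A", "A.t1", "chrT", 101, 120, "+"),   # exactly 20 bp
    exon_row("B", "B.t1", "chrT", 251, 270, "+")
  ))
  j <- make_junctions(enumerate_exon_combinations(ok), g)
  expect_identical(nchar(j$sequence), 40L)
})

test_that("the index maps both orientations and shares keys across duplicates", {
  jt <- tibble::tibble(
    junction_id = c("j1", "j2"),
    sequence = c(strrep("AC", 20), paste0(strrep("A", 20), strrep("C", 20))),
    has_n = FALSE, variant_of = NA_character_)
  idx <- build_index(jt)
  expect_identical(nrow(idx), 4L)
  expect_setequal(unique(idx$orientation), c("forward", "revcomp"))

  dup <- tibble::tibble(
    junction_id = c("j1", "j2"),
    sequence = rep(strrep("AC", 20), 2),
    has_n = FALSE, variant_of = NA_character_)
  idx2 <- build_index(dup)
  expect_identical(length(unique(idx2$kmer)), 2L)
  expect_setequal(idx2$junction_id[idx2$orientation == "forward"], c("j1", "j2"))

  # palindromic 40-mer: one key carrying both orientations
  pal <- paste0(strrep("A", 20), strrep("T", 20))
  expect_identical(pal, revcomp(pal))
  idx3 <- build_index(tibble::tibble(junction_id = "p", sequence = pal,
                                     has_n = FALSE, variant_of = NA_character_))
  expect_identical(length(unique(idx3$kmer)), 1L)
  expect_setequal(idx3$orientation, c("forward", "revcomp"))
})

test_that("junctions containing N are excluded from the index with a message", {
  jt <- tibble::tibble(
    junction_id = c("j1", "j2"),
    sequence = c(strrep("ACGT", 10),
                 paste0(strrep("A", 19), "N", strrep("C", 20))),
    has_n = c(FALSE, TRUE), variant_of = NA_character_)
  expect_message(idx <- build_index(jt), "containing N")
  expect_identical(unique(idx$junction_id), "j1")
})

test_that("reverse-complementing the world mirrors the index key set", {
  w <- figure_world()
  combos <- enumerate_exon_combinations(w$exons)
  idx_fwd <- build_index(make_junctions(combos, w$genome))
  L <- Biostrings::width(w$genome)[1]
  g_rc <- dna_set(setNames(revcomp(as.character(w$genome[[1]])), "chrT"))
  ex_rc <- w$exons |>
    dplyr::mutate(new_start = L + 1L - end, new_end = L + 1L - start,
                  start = new_start, end = new_end,
                  strand = ifelse(strand == "+", "-", "+")) |>
    dplyr::select(-new_start, -new_end)
  ex_rc <- rank_exons(ex_rc)
  idx_rc <- build_index(make_junctions(enumerate_exon_combinations(ex_rc), g_rc))
  expect_setequal(idx_rc$kmer, idx_fwd$kmer)
})
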