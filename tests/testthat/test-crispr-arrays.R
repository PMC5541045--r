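test_that("no arrays are reported on plain random sequence", {
  set.seed(13)
  expect_equal(nrow(detect_arrays(rand_dna_seq(10000))), 0)
  expect_equal(nrow(detect_arrays("ACGT")), 0)
})

test_that("a planted array is found once with near-exact boundaries", {
  spec <- array_spec(n_repeats = 6, spacer_len_range = c(35, 35),
                     terminal_repeat_mutations = 0,
                     leader_at_enrichment = 0)
  g <- generate_array_contig(spec, left_flank = 600, right_flank = 600,
                             seed = 21)
  got <- detect_arrays(g$sequence)
  expect_equal(nrow(got), 1)
  unit <- nchar(g$truth$repeat_seq) + 35
  expect_lte(abs(got$start - g$truth$start), unit)
  expect_lte(abs(got$end - g$truth$end), unit)
  expect_equal(got$n_repeats, 6)
  expect_equal(got$repeat_consensus, g$truth$repeat_seq)
  expect_equal(got$orientation, "undetermined")
})

test_that("arrays 2 kb apart are reported separately, never merged", {
  g <- generate_array_genome(list(array_spec(), array_spec(n_repeats = 5)),
                             length_bp = 20000, min_separation = 2000,
                             seed = 31)
  got <- detect_arrays(g$sequence)
  expect_equal(nrow(got), 2)
  expect_true(all(diff(got$start) > 0))
})

test_that("detection commutes with reverse complementation", {
  g <- generate_array_genome(list(array_spec(), array_spec(n_repeats = 4)),
                             length_bp = 25000, seed = 17)
  n <- nchar(g$sequence)
  fwd <- detect_arrays(g$sequence)
  rev <- detect_arrays(rtcrispr:::revcomp(g$sequence))
  expect_equal(nrow(fwd), nrow(rev))
  mirrored <- tibble::tibble(start = n - rev$end + 1L, end = n - rev$start + 1L)
  mirrored <- mirrored[order(mirrored$start), ]
  expect_equal(fwd$start, mirrored$start)
  expect_equal(fwd$end, mirrored$end)
})

test_that("orientation scoring respects the >200 nt flank rule and signal
           strength", {
  strong <- array_spec(leader_at_enrichment = 0.22,
                       terminal_repeat_mutations = 3)
  g <- generate_array_contig(strong, seed = 41)
  a <- detect_arrays(g$sequence)
  sc <- score_orientation(a[1, ], g$sequence)
  expect_equal(sc$orientation, "forward")
  expect_equal(sc$band, "H")

  short <- generate_array_contig(strong, left_flank = 120,
                                 right_flank = 600, seed = 42)
  a2 <- detect_arrays(short$sequence)
  expect_equal(score_orientation(a2[1, ], short$sequence)$band, "NA")

  # perfectly symmetric array: identical flanks, no degeneracy
  set.seed(43)
  rep_seq <- rand_dna_seq(32)
  spacers <- vapply(1:5, function(i) rand_dna_seq(35), "")
  body <- paste0(paste0(rep(paste0(rep_seq, ""), 6),
                        c(spacers, ""), collapse = ""))
  flank <- rand_dna_seq(400)
  contig <- paste0(flank, body, flank)
  a3 <- detect_arrays(contig)
  expect_equal(nrow(a3), 1)
  sc3 <- score_orientation(a3[1, ], contig)
  expect_true(sc3$band %in% c("L", "NA"))
})

test_that("a reverse-oriented strong array is called reverse", {
  g <- generate_array_contig(array_spec(orientation = "reverse",
                                        leader_at_enrichment = 0.22),
                             seed = 44)
  a <- detect_arrays(g$sequence)
  sc <- score_orientation(a[1, ], g$sequence)
  expect_equal(sc$orientation, "reverse")
  expect_true(sc$band %in% c("H", "M"))
})

test_that("the cascade keeps criterion-i calls and falls back to the
           repeat database and group similarity", {
  db <- repeat_db()
  # criterion i
  g <- generate_array_contig(array_spec(leader_at_enrichment = 0.22),
                             seed = 51)
  a <- resolve_orientation(detect_arrays(g$sequence), g$sequence, db = db)
  expect_equal(a$criterion, "i")
  expect_equal(a$orientation, "forward")

  # criterion ii: short flank (band NA), repeat from the database,
  # planted reverse
  aspec <- array_spec(repeat_seq = db$sequence[3], orientation = "reverse",
                      leader_at_enrichment = 0,
                      terminal_repeat_mutations = 0)
  g2 <- generate_array_contig(aspec, left_flank = 150, seed = 52)
  a2raw <- detect_arrays(g2$sequence)
  a2 <- resolve_orientation(a2raw, g2$sequence, db = db)
  expect_equal(a2$criterion, "ii")
  expect_equal(a2$orientation, "reverse")

  # criterion iii: no db hit, but an oriented group member shares the repeat
  set.seed(53)
  novel <- rand_dna_seq(34)
  g3 <- generate_array_contig(array_spec(repeat_seq = novel,
                                         leader_at_enrichment = 0,
                                         terminal_repeat_mutations = 0),
                              left_flank = 150, seed = 53)
  a3raw <- detect_arrays(g3$sequence)
  group <- tibble::tibble(repeat_consensus = novel,
                          orientation = "reverse", criterion = "i")
  a3 <- resolve_orientation(a3raw, g3$sequence, db = db, group = group)
  expect_equal(a3$criterion, "iii")
  expect_equal(a3$orientation, "reverse")

  # cascade exhaustion
  a4 <- resolve_orientation(a3raw, g3$sequence, db = db)
  expect_equal(a4$criterion, "none")
  expect_equal(a4$orientation, "undetermined")
})
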