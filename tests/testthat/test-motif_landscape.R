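test_that("reverse_complement handles bases, IUPAC codes and errors", {
  expect_identical(reverse_complement("AAA"), "TTT")
  expect_identical(reverse_complement("GCCCGGGC"), "GCCCGGGC")
  expect_identical(reverse_complement("CAACATGTTG"), "CAACATGTTG")
  expect_identical(reverse_complement("ACGTN"), "NACGT")
  expect_identical(reverse_complement("RY"), "RY")
  expect_error(reverse_complement("ACXGT"), "position 3")

  # involution property, checked against an independent character-map oracle
  for (seed in 1:25) {
    s <- random_dna(sample(1:40, 1), seed = seed)
    expect_identical(reverse_complement(reverse_complement(s)), s)
    expect_identical(reverse_complement(s), oracle_revcomp(s))
  }
})

test_that("reverse_complement agrees with Biostrings on random sequences", {
  for (seed in 1:10) {
    s <- random_dna(60, seed = seed)
    expect_identical(
      reverse_complement(s),
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))))
  }
})

test_that("is_rc_palindrome follows the strict-palindrome policy", {
  expect_true(is_rc_palindrome("ACATGT"))
  expect_true(is_rc_palindrome("GCATGC"))
  expect_true(is_rc_palindrome("CCCGGG"))
  expect_false(is_rc_palindrome("AGCAT"))    # odd length: impossible
  expect_false(is_rc_palindrome("GCATGG"))   # revcomp is CCATGC
  expect_false(is_rc_palindrome("ANNT"))     # N blocks strict symmetry
  expect_false(is_rc_palindrome("ACWGT"))    # ambiguity blocks too
})

test_that("enumerate_palindromes reports nested/overlapping hits and rejects odd lengths", {
  hits <- enumerate_palindromes("ACATGT", 6, 10)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 0)
  expect_equal(hits$end, 6)
  expect_equal(hits$strand, "+")

  expect_equal(nrow(enumerate_palindromes("AAAAAA", 6, 10)), 0)
  expect_error(enumerate_palindromes("ACATGT", 5, 9), "even")

  # the 6-mer inside the 8-mer is reported as a distinct hit
  hits8 <- enumerate_palindromes("GCCCGGGC", 6, 10)
  expect_true(any(hits8$end - hits8$start == 6))
  expect_true(any(hits8$end - hits8$start == 8))
})

test_that("enumerate_palindromes matches the exhaustive substring oracle", {
  for (seed in c(11, 42, 99)) {
    s <- random_dna(500, seed = seed)
    got <- enumerate_palindromes(s, 4, 10)
    want <- oracle_palindromes(s, 4, 10)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end - got$start, want$len)
  }
  # with N bases sprinkled in, N windows must be excluded
  s <- random_dna(300, seed = 7, alphabet = c("A", "C", "G", "T", "N"))
  got <- enumerate_palindromes(s, 4, 8)
  want <- oracle_palindromes(s, 4, 8)
  expect_equal(got$start, want$start)
})

test_that("find_box_hits places hits where planted and respects bounds", {
  boxes <- default_motif_boxes()
  hits <- find_box_hits("TTGCCCGGGCTT", boxes["CP1-8mer"])
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 2)
  expect_equal(hits$end, 10)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0)

  expect_equal(nrow(find_box_hits("TT", boxes["CP2-6mer"])), 0)
  expect_error(find_box_hits("ACGT", list()), "empty box list")
})

test_that("N in the matched window blocks hits even with a mismatch budget", {
  box <- motif_box("GP-7mer-L", "AGCATGC", "GP", max_mismatches = 1)
  # one real mismatch is allowed ...
  expect_equal(nrow(find_box_hits("AGCATGG", list(box))), 1)
  # ... but an N is not absorbed as a mismatch
  expect_equal(nrow(find_box_hits("AGCATGN", list(box))), 0)
})

test_that("palindromic boxes give identical hit sets on one or both strands", {
  s <- random_dna(800, seed = 3)
  pal_boxes <- Filter(function(b) b$require_palindrome, default_motif_boxes())
  h1 <- find_box_hits(s, pal_boxes, both_strands = TRUE)
  h2 <- find_box_hits(s, pal_boxes, both_strands = FALSE)
  expect_equal(h1, h2)
})

test_that("find_box_hits agrees with the brute-force IUPAC scanner", {
  s <- random_dna(1000, seed = 5)
  cases <- list(
    list(pattern = "GCCCGGGC", mm = 0),
    list(pattern = "ACATGT", mm = 0),
    list(pattern = "GGGGCGGGG", mm = 0),   # non-palindromic: both strands
    list(pattern = "AGCATGC", mm = 1),     # 7-mer near-match rule
    list(pattern = "GCATGCT", mm = 1))
  for (cs in cases) {
    box <- motif_box("probe", cs$pattern, "GP", max_mismatches = cs$mm)
    got <- find_box_hits(s, list(box), both_strands = TRUE)
    want <- oracle_box_hits(s, cs$pattern, cs$mm, both_strands = TRUE)
    expect_equal(got$start, want$start, info = cs$pattern)
    expect_equal(got$strand, want$strand, info = cs$pattern)
    expect_equal(got$mismatches, want$mismatches, info = cs$pattern)
  }
})

test_that("scanner recovers planted boxes in a simulated window", {
  plan <- data.frame(
    name = c("CP1-8mer", "CP2-10mer", "GP-8mer", "Sp1-Zn", "Sp1-Zn"),
    pattern = c("GCCCGGGC", "CAACATGTTG", "AGCATGCT", "GGGGCGGGG",
                "GGGGCGGGG"),
    position = c(500, 1500, 2500, 3500, 4200),
    strand = c("+", "+", "+", "+", "-"))
  sim <- simulate_sequence_with_boxes(5000, plan, seed = 17)
  boxes <- default_motif_boxes()
  hits <- find_box_hits(sim$sequence, boxes)
  # every planted record must be present with its planted coordinates
  for (i in seq_len(nrow(sim$truth))) {
    match_rows <- hits[hits$box_name == sim$truth$box_name[i] &
                       hits$start == sim$truth$start[i], , drop = FALSE]
    expect_gte(nrow(match_rows), 1)
  }
  # and the full hit set equals an independent rescan of the same sequence
  for (nm in c("CP1-8mer", "GP-8mer", "Sp1-Zn")) {
    b <- boxes[[nm]]
    got <- find_box_hits(sim$sequence, list(b))
    want <- oracle_box_hits(sim$sequence, b$pattern, b$max_mismatches)
    expect_equal(got$start, want$start, info = nm)
    expect_equal(got$strand, want$strand, info = nm)
  }
})

test_that("percent coordinates map linearly onto the scanned window", {
  window <- region_spec("chr19", 54100000, 54300000, "200 kb window")
  hits <- data.frame(box_name = c("a", "b", "c"), category = "CP1",
                     start = c(54100000, 54200000, 54299990),
                     end = c(54100008, 54200008, 54299998),
                     strand = "+", mismatches = 0L,
                     percent_position = NA_real_)
  out <- to_percent_coordinates(hits, window)
  expect_equal(out$percent_position[1], 0)
  expect_equal(out$percent_position[2], 50)
  # monotone map: order of percent positions follows order of starts
  expect_true(all(diff(out$percent_position) > 0))

  bad <- hits; bad$start[1] <- 54099999; bad$end[1] <- 54100007
  expect_error(to_percent_coordinates(bad, window), "outside window")
})

test_that("landscape summary partitions hits into zones; inside-only set from planted truth", {
  window <- region_spec("w", 0, 1000)
  inner <- region_spec("w", 400, 600)
  hits <- data.frame(
    box_name = c("GP-8mer", "GP-8mer", "CP1-8mer", "CP1-8mer", "CP1-8mer"),
    category = "x",
    start = c(450, 500, 100, 450, 900),
    end = c(458, 508, 108, 458, 908),
    strand = "+", mismatches = 0L, percent_position = NA_real_)
  s <- summarize_landscape(hits, window, inner)
  expect_equal(s$inside_only, "GP-8mer")
  expect_equal(sum(s$counts$total), nrow(hits))
  # zone partition: counts sum row-wise to totals
  expect_equal(s$counts$inside + s$counts$left_flank + s$counts$right_flank,
               s$counts$total)

  empty <- summarize_landscape(hits[0, ], window, inner)
  expect_equal(nrow(empty$counts), 0)
  expect_length(empty$inside_only, 0)

  expect_error(summarize_landscape(hits, window, region_spec("w", 400, 1200)),
               "not nested")
})
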