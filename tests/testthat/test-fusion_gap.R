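test_that("bedGraph IO: per-base expansion, gap fill, overlap error, round trip", {
  path <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr17\t0\t5\t3", path)
  tr <- read_bedgraph(path)
  expect_equal(tr$depth, rep(3L, 5))
  expect_equal(tr$offset, 0)
  expect_equal(tr$contig, "chr17")

  writeLines(c("chr17\t0\t5\t2", "chr17\t10\t15\t4"), path)
  tr2 <- read_bedgraph(path)
  expect_equal(tr2$depth, c(rep(2L, 5), rep(0L, 5), rep(4L, 5)))

  writeLines(c("chr17\t0\t5\t2", "chr17\t3\t8\t4"), path)
  expect_error(read_bedgraph(path), "overlapping")

  sim <- simulate_coverage_with_deletion(400, c(150, 300), 20, seed = 3,
                                         offset = 100)
  write_bedgraph(sim$track, path)
  back <- read_bedgraph(path)
  expect_equal(back$depth, sim$track$depth)
  expect_equal(back$offset, sim$track$offset)
})

test_that("gap finder reports maximal runs only above the span threshold", {
  tr <- coverage_track("c", 0, rep(30L, 500))
  expect_equal(nrow(find_coverage_gaps(tr, 0, 10)), 0)

  # two zero runs split by one covered base stay separate
  d <- rep(30L, 100)
  d[11:30] <- 0L; d[31] <- 1L; d[32:50] <- 0L
  tr2 <- coverage_track("c", 0, d)
  gaps <- find_coverage_gaps(tr2, max_depth = 0, min_span_bp = 5)
  expect_equal(gaps$start, c(10, 31))
  expect_equal(gaps$end, c(30, 50))
  # maximality: bases flanking every gap exceed max_depth
  for (i in seq_len(nrow(gaps))) {
    if (gaps$start[i] > 0) expect_gt(d[gaps$start[i]], 0)
    if (gaps$end[i] < length(d)) expect_gt(d[gaps$end[i] + 1], 0)
  }
  # at max_depth = 1 the separating base joins the runs
  gaps1 <- find_coverage_gaps(tr2, max_depth = 1, min_span_bp = 5)
  expect_equal(nrow(gaps1), 1)
  expect_equal(gaps1$span_bp, 40)
  expect_error(find_coverage_gaps(tr2, 0, 0), ">= 1")
})

test_that("planted chr17 deletion is recovered with exact breakpoints", {
  interval <- c(7501000, 7577371)
  sim <- simulate_coverage_with_deletion(180000, interval, 30, seed = 5,
                                         offset = 7450000)
  gaps <- find_coverage_gaps(sim$track, max_depth = 0, min_span_bp = 10000)
  expect_equal(nrow(gaps), 1)
  expect_equal(gaps$start, 7501000)
  expect_equal(gaps$end, 7577371)
  expect_equal(gaps$span_bp, 76371)
})

test_that("Poisson(30) background yields no false focal gaps across seeds", {
  for (seed in 1:20) {
    sim <- simulate_coverage_with_deletion(50000, NULL, 30, seed = seed)
    gaps <- find_coverage_gaps(sim$track, max_depth = 0, min_span_bp = 1000)
    expect_equal(nrow(gaps), 0)
  }
})

test_that("gene models validate exon structure and derive introns", {
  g <- gene_model("G", "chr1", "+", rbind(c(0, 10), c(20, 30), c(40, 50)))
  expect_equal(g$introns[, "start"], c(10, 30))
  expect_equal(g$introns[, "end"], c(20, 40))
  expect_error(gene_model("G", "chr1", "+", rbind(c(0, 10), c(5, 30))),
               "non-overlapping")
  expect_error(gene_model("G", "chr1", "+", rbind(c(10, 10))), "start must be")
})

test_that("gap-to-gene assignment produces the expected fusion call", {
  models <- example_fusion_models()
  call <- assign_gap_to_genes(c(7501000, 7577371), models)
  expect_true(call$is_fusion)
  expect_equal(call$left_gene, "FXR2")
  expect_equal(call$right_gene, "TP53")
  expect_equal(call$left_intron_index, 7)   # transcription order, + strand
  expect_equal(call$right_intron_index, 3)  # transcription order, - strand
  expect_equal(call$span_bp, 76371)
  expect_equal(call$span_kb_rounded, 76)
})

test_that("minus-strand intron numbering reverses genomic order", {
  # 4 exons on "-": genomic introns 1,2,3 are transcription introns 3,2,1
  g <- gene_model("M", "chr1", "-",
                  rbind(c(100, 200), c(300, 400), c(500, 600), c(700, 800)))
  probe <- function(pos) {
    gp <- assign_gap_to_genes(c(50, pos), list(g))
    gp$right_intron_index
  }
  expect_equal(probe(250), 3)  # genomic intron 1
  expect_equal(probe(450), 2)
  expect_equal(probe(650), 1)
})

test_that("single-gene and exonic gaps never yield fusion calls", {
  models <- example_fusion_models()
  # both ends inside FXR2 introns: possible splicing
  call <- assign_gap_to_genes(c(7491500, 7495500), models["FXR2"])
  expect_false(call$is_fusion)
  expect_match(call$note, "splicing")
  # gap entirely inside one exon
  call2 <- assign_gap_to_genes(c(7491010, 7491390), models)
  expect_false(call2$is_fusion)
  expect_equal(call2$left_feature, "exon")
  # intergenic breakpoints
  call3 <- assign_gap_to_genes(c(7520000, 7560000), models)
  expect_false(call3$is_fusion)
  expect_equal(call3$left_feature, "intergenic")
  expect_error(assign_gap_to_genes(c(1, 2), list()), "empty gene list")
})

test_that("junction decomposition: exact fusion, planted linkers, conservation", {
  left <- "ACGGATTACAGGCATGAGCCA"
  right <- "TTGAACTCCTGACCTCAGGTG"

  d0 <- decompose_junction(paste0(left, right), left, right)
  expect_equal(nchar(d0$linker), 0)
  expect_equal(d0$left_match_len + d0$right_match_len,
               nchar(left) + nchar(right))

  # planted 12-nt linker with boundary bases distinct from flank continuation
  linker <- "GGTTGGTTGGTT"   # left continues T..., right starts T...
  j <- make_junction_fixture(left, linker, right)
  d12 <- decompose_junction(j, left, right)
  expect_equal(d12$linker, linker)
  expect_equal(d12$left_match_len, nchar(left))
  expect_equal(d12$right_match_len, nchar(right))
  expect_false(d12$ambiguous)

  expect_error(decompose_junction("A", left, right), "at least 2")
})

test_that("linker recovery is exact for lengths 0 to 50", {
  set.seed(909)
  left <- "ACGGATTACAGGCATGAGCCA"   # ends A
  right <- "TTGAACTCCTGACCTCAGGTG" # starts T
  for (k in 0:50) {
    # boundary-distinct linker: first base != right[1], last base != left[end]
    linker <- if (k == 0) "" else {
      mid <- if (k > 2) random_dna(k - 2) else ""
      first <- "G"  # != T (right start)
      last <- "C"   # != A (left end continuation on the left side)
      if (k == 1) "G" else paste0(first, mid, last)
    }
    # ensure linker's last base differs from right flank's first base region:
    # decomposition is left-maximal, so the relevant boundaries are
    # linker[1] != left-continuation and handled by construction
    j <- make_junction_fixture(left, linker, right)
    d <- decompose_junction(j, left, right)
    expect_equal(nchar(d$linker), k)
    expect_equal(d$left_match_len + nchar(d$linker) + d$right_match_len,
                 nchar(j))
  }
})

test_that("microhomology at the right boundary is flagged ambiguous", {
  # one shared T at the boundary: the junction AAATGGG reads either as
  # AAAT|GGG or AAA|TGGG; the left-maximal split is reported and flagged
  left <- "AAAT"
  right <- "TGGG"
  j <- "AAATGGG"
  d <- decompose_junction(j, left, right)
  expect_equal(d$left_match_len, 4)
  expect_equal(d$right_match_len, 3)
  expect_equal(d$linker, "")
  expect_true(d$ambiguous)
  # sanity: conservation holds in the ambiguous case too
  expect_equal(d$left_match_len + nchar(d$linker) + d$right_match_len,
               nchar(j))
})

test_that("expected amplicon size arithmetic and guards", {
  expect_equal(expected_amplicon_size(c(200, 300), 100, 360, 0), 160)
  # the printed primer/breakpoint coordinates give 241 bp with the 12-nt linker
  expect_equal(
    expected_amplicon_size(c(7501000, 7577371), 7500880, 7577480, 12), 241)
  # linearity in linker length
  base <- expected_amplicon_size(c(200, 300), 100, 360, 0)
  for (k in c(1, 7, 12)) {
    expect_equal(expected_amplicon_size(c(200, 300), 100, 360, k), base + k)
  }
  expect_error(expected_amplicon_size(c(200, 300), 250, 360), "inside")
  expect_error(expected_amplicon_size(c(200, 300), 100, 250), "inside")
  expect_error(expected_amplicon_size(c(200, 300), 100, 300), "inside")
})
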