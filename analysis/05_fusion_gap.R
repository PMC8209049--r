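#!/usr/bin/env Rscript
# Step 5 — call the focal deletion from the chr17 coverage track, assign its
# breakpoints to gene introns, decompose the junction amplicon into
# flank/linker segments, and compute the expected PCR product size across
# the rearrangement. Run after 01_simulate_fixtures.R.

suppressMessages(library(c19mctools))
dir.create("results", showWarnings = FALSE)

track <- read_bedgraph("scratch/fixtures/chr17_coverage.bedGraph")
print(track)
gaps <- find_coverage_gaps(track, max_depth = 0, min_span_bp = 10000)
write.table(gaps, "results/05_coverage_gaps.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

call <- assign_gap_to_genes(gaps[1, ], example_fusion_models())
print(call)

seqs <- read_fasta_sequence("scratch/fixtures/junction.fa")
dec <- decompose_junction(seqs[["synthetic_fusion_junction"]],
                          seqs[["left_flank"]], seqs[["right_flank"]])
print(dec)

# primer anchors at the printed coordinates: sense primer in the FXR2 intron
# (chr17:7,500,880), reverse-complement primer in the TP53 intron
# (chr17:7,577,480)
amp <- expected_amplicon_size(call, 7500880, 7577480,
                              linker_len = nchar(dec$linker))

jsonlite::write_json(
  list(call = list(
         contig = call$contig,
         breakpoints_1based = sprintf("%s:%s-%s", call$contig,
                                      format(call$gap_start + 1,
                                             big.mark = ",", trim = TRUE),
                                      format(call$gap_end, big.mark = ",",
                                             trim = TRUE)),
         left = sprintf("%s intron %d", call$left_gene,
                        call$left_intron_index),
         right = sprintf("%s intron %d", call$right_gene,
                         call$right_intron_index),
         span_bp = call$span_bp, span_kb_rounded = call$span_kb_rounded,
         is_fusion = call$is_fusion),
       junction = list(left_match = dec$left_match_len, linker = dec$linker,
                       right_match = dec$right_match_len,
                       ambiguous = dec$ambiguous),
       expected_amplicon_bp = amp,
       note = paste("expected amplicon from breakpoint/primer coordinates;",
                    "an observed band can differ if the true breakpoints",
                    "deviate from the approximate coordinates used here")),
  "results/05_fusion_call.json", auto_unbox = TRUE, pretty = TRUE,
  digits = NA)

cat(sprintf("Expected fusion amplicon: %d bp (%d + %d + %d).\n", amp,
            call$gap_start - 7500880, nchar(dec$linker),
            7577480 - call$gap_end))
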