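#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study inputs with planted ground truth:
# a 200 kb sequence window with planted p53/Sp1 boxes, a 183-sample
# expression cohort with a TI-like group, a chr17 coverage track with the
# focal deletion, and a fusion-junction amplicon with a 12-nt linker.
# Small truth tables go to results/; bulky fixtures (FASTA, bedGraph, full
# matrices) go to scratch/fixtures/ and are regenerated on demand.

suppressMessages(library(c19mctools))
dir.create("results", showWarnings = FALSE)
dir.create("scratch/fixtures", recursive = TRUE, showWarnings = FALSE)

seed <- 20210616L

## 200 kb window mirroring the scanned region (chr19:54,100,000-54,300,000,
## with the ~96 kb cluster in the middle); boxes planted inside and outside
## the inner cluster region, window-local coordinates
window_len <- 200000L
inner <- c(52000, 148000)  # 96 kb inner cluster region, window-local
plan <- data.frame(
  name = c("CP1-8mer", "CP1-8mer", "CP2-10mer", "CP2-10mer", "GP-8mer",
            "GP-8mer", "GP-8mer", "Sp1-Zn", "Sp1-Zn", "CP1-6mer",
            "CP2-6mer", "Sp1-Zn"),
  pattern = c("GCCCGGGC", "GCCCGGGC", "CAACATGTTG", "CAACATGTTG",
              "AGCATGCT", "AGCATGCT", "AGCATGCT", "GGGGCGGGG", "GGGGCGGGG",
              "CCCGGG", "ACATGT", "GGGGCGGGG"),
  # GP-8mer planted only inside the inner region; others in both zones
  position = c(10000, 60000, 30000, 100000, 70000, 90000, 120000,
               55000, 190000, 140000, 160000, 80000),
  strand = c("+", "+", "+", "+", "+", "+", "+", "+", "-", "+", "+", "-"))
seq_sim <- simulate_sequence_with_boxes(window_len, plan, background_gc = 0.55,
                                        seed = seed)
write_fasta_sequence(seq_sim$sequence, "scratch/fixtures/window_200kb.fa",
                     name = "synthetic_chr19_window")
write.table(seq_sim$truth, "results/01_planted_boxes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## expression cohort at the study conditions (183 samples; TI group with
## suppressed p53-induced genes, elevated repressed genes and cluster miRNAs;
## IFNG-named ligand coupled to cluster load at rho 0.8)
cfg <- sim_config(seed = seed, n_samples = 183)
cohort <- simulate_expression_cohort(cfg)
write_expression_tsv(round(cohort$mrna, 3), "scratch/fixtures/mrna.tsv")
write_expression_tsv(round(cohort$mirna, 3), "scratch/fixtures/mirna.tsv")
jsonlite::write_json(as.list(cohort$labels), "results/01_truth_labels.json",
                     auto_unbox = TRUE)

## chr17 coverage with the printed deletion interval
cov <- simulate_coverage_with_deletion(
  180000L, c(7501000, 7577371), depth_lambda = 30, seed = seed,
  contig = "chr17", offset = 7450000)
write_bedgraph(cov$track, "scratch/fixtures/chr17_coverage.bedGraph")

## junction amplicon with a planted 12-nt linker between schematic flanks
left <- "ACGGATTACAGGCATGAGCCACCGCACCCGGCTTTT"
right <- "TTGAACTCCTGACCTCAGGTGATCCACCCACCTCGG"
linker <- "GGTTGGTTGGTT"
junction <- make_junction_fixture(left, linker, right)
writeLines(c(">synthetic_fusion_junction", junction,
             ">left_flank", left, ">right_flank", right),
           "scratch/fixtures/junction.fa")

summary <- data.frame(
  fixture = c("window_200kb.fa", "mrna.tsv/mirna.tsv",
              "chr17_coverage.bedGraph", "junction.fa"),
  planted_truth = c(
    sprintf("%d boxes (%d inside inner region)", nrow(plan),
            sum(plan$position >= inner[1] & plan$position < inner[2])),
    sprintf("%d TC / %d TI samples; ligand %s at rho %.1f",
            sum(cohort$labels == "TC"), sum(cohort$labels == "TI"),
            cohort$truth$planted_ligand, cohort$truth$ligand_rho),
    "zero coverage chr17:7,501,000-7,577,371 (76,371 bp)",
    sprintf("%d-nt linker between %d-nt flanks", nchar(linker),
            nchar(left))))
write.table(summary, "results/01_fixture_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Fixtures written; planted truth:\n")
print(summary, right = FALSE)
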