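# Synthetic-data generators with planted ground truth.
#
# These stand in for the study's real inputs (tumour-cohort miRNA-seq/RNA-seq
# matrices, cell-line RNA-seq coverage, Sanger amplicons) so that every
# pipeline stage is testable offline against a known truth table.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic cohort and coverage generators. The
#' defaults encode the study conditions the generators emulate: a 183-sample
#' cohort (the integrated-cluster tumour subset), a 2 log2-unit suppression of
#' p53-induced genes (and elevation of p53-repressed genes) in the
#' transcription-incompetent group, a 2 log2-unit elevation of C19MC members
#' in that same group, one ligand coupled to cumulative cluster expression at
#' Pearson rho 0.8, log-scale noise sd 0.5, and mean per-base coverage 30.
#'
#' @param seed Integer seed; a fixed seed gives byte-identical fixtures.
#' @param n_samples Cohort size (>= 4 so both groups have >= 2 samples).
#' @param effect_size_delta Log2-units shift of signature genes between groups.
#' @param c19mc_shift Log2-units shift of cluster miRNAs in the TI-like group.
#' @param ligand_rho Target Pearson correlation in `[-1, 1]` between the
#'   planted ligand and cumulative cluster expression (log scale).
#' @param noise_sd Standard deviation of log2-scale noise (> 0).
#' @param depth_lambda Mean per-base coverage for Poisson depth simulation.
#' @return A `sim_config` object.
#' @examples
#' sim_config(seed = 7, n_samples = 100)
#' @export
sim_config <- function(seed = 1L, n_samples = 183L, effect_size_delta = 2,
                       c19mc_shift = 2, ligand_rho = 0.8, noise_sd = 0.5,
                       depth_lambda = 30) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 4L) {
    stop("n_samples must be >= 4 (two groups of at least 2 samples)")
  }
  if (!is.finite(ligand_rho) || abs(ligand_rho) > 1) {
    stop("ligand_rho must lie in [-1, 1]")
  }
  if (!is.finite(noise_sd) || noise_sd <= 0) stop("noise_sd must be > 0")
  if (!is.finite(depth_lambda) || depth_lambda <= 0) {
    stop("depth_lambda must be > 0")
  }
  structure(list(seed = as.integer(seed), n_samples = n_samples,
                 effect_size_delta = effect_size_delta,
                 c19mc_shift = c19mc_shift, ligand_rho = ligand_rho,
                 noise_sd = noise_sd, depth_lambda = depth_lambda),
            class = "sim_config")
}

#' Default synthetic feature catalogues
#'
#' Placeholder identifiers for testing without real annotation: 46 cluster
#' miRNA names (the cluster's member count), 100 ligand mRNA names with the
#' planted, cluster-coupled ligand named `IFNG` first (mirroring the screen's
#' intended discovery), and a 30-gene signature stand-in built from canonical
#' p53-induced targets and mitotic genes repressed downstream of p53. The
#' study's actual signature gene identities are supplementary material and
#' must be supplied for real analyses; these defaults exist so the synthetic
#' pipeline is runnable end to end.
#'
#' @return Character vectors (`default_c19mc_members`, `default_ligand_names`)
#'   or a [gene_signature()] (`default_gene_signature`).
#' @export
default_c19mc_members <- function() {
  sprintf("C19MC-miR-%02d", 1:46)
}

#' @rdname default_c19mc_members
#' @export
default_ligand_names <- function() {
  c("IFNG", sprintf("LIG-%03d", 2:100))
}

#' @rdname default_c19mc_members
#' @export
default_gene_signature <- function() {
  gene_signature(
    induced = c("CDKN1A", "MDM2", "GADD45A", "BAX", "BBC3", "PMAIP1",
                "TP53I3", "SFN", "TIGAR", "SESN1", "SESN2", "RRM2B",
                "ZMAT3", "DDB2", "XPC", "FAS", "TNFRSF10B", "SERPINB5",
                "THBS1", "CCNG1"),
    repressed = c("CCNB1", "CDC20", "CDK1", "PLK1", "BIRC5",
                  "AURKA", "AURKB", "FOXM1", "CCNB2", "BUB1"))
}

.check_dna <- function(s, what, allow_empty = FALSE, allow_n = TRUE) {
  stopifnot(is.character(s), length(s) == 1L)
  s <- toupper(s)
  if (!nzchar(s)) {
    if (allow_empty) return(s)
    stop(what, " must be non-empty")
  }
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  if (grepl(pat, s)) stop(what, " contains non-", if (allow_n) "ACGTN" else
    "ACGT", " characters: ", s)
  s
}

#' Simulate a sequence window with planted motif boxes
#'
#' Draws an i.i.d. background with the requested GC fraction and overwrites it
#' with the planted motifs (reverse-complemented for minus-strand plants).
#' Every plant is recorded in a truth table so scanners can be validated
#' against a known answer.
#'
#' @param length Window length in bases.
#' @param plan Plant plan: a data frame with columns `name`, `pattern`,
#'   `position` (0-based start), `strand` (`"+"`/`"-"`); `NULL` or zero rows
#'   for a pure background window.
#' @param background_gc Background GC fraction in `(0, 1)` (default 0.5);
#'   background alphabet is ACGT (no N).
#' @param seed Optional seed for reproducibility.
#' @return A list with `sequence` (character string) and `truth` (data frame
#'   `box_name`, `start`, `end`, `strand`, `planted_pattern` -- the pattern as
#'   it appears on the forward strand).
#' @examples
#' sim <- simulate_sequence_with_boxes(
#'   60, data.frame(name = "CP1-8mer", pattern = "GCCCGGGC",
#'                  position = 10, strand = "+"), seed = 1)
#' substr(sim$sequence, 11, 18)
#' @export
simulate_sequence_with_boxes <- function(length, plan = NULL,
                                         background_gc = 0.5, seed = NULL) {
  length <- as.integer(length)
  stopifnot(length >= 1L, background_gc > 0, background_gc < 1)
  if (is.null(plan) || NROW(plan) == 0L) {
    plan <- data.frame(name = character(0), pattern = character(0),
                       position = numeric(0), strand = character(0))
  }
  stopifnot(all(c("name", "pattern", "position", "strand") %in% names(plan)))
  plan$pattern <- toupper(plan$pattern)
  plan$position <- as.numeric(plan$position)
  widths <- nchar(plan$pattern)
  if (any(plan$position < 0 | plan$position + widths > length)) {
    bad <- which(plan$position < 0 | plan$position + widths > length)[1]
    stop("plant ", plan$name[bad], " at ", plan$position[bad],
         " does not fit in a window of length ", length)
  }
  if (NROW(plan) > 1L) {
    ord <- order(plan$position)
    p <- plan[ord, , drop = FALSE]
    ends <- p$position + nchar(p$pattern)
    olap <- which(p$position[-1L] < ends[-NROW(p)])
    if (base::length(olap)) {
      i <- olap[1]
      stop("planted motifs overlap: ", p$name[i], " at ", p$position[i],
           " and ", p$name[i + 1L], " at ", p$position[i + 1L])
    }
  }
  sequence <- .with_seed(seed, {
    probs <- c(A = (1 - background_gc) / 2, C = background_gc / 2,
               G = background_gc / 2, T = (1 - background_gc) / 2)
    paste(sample(names(probs), length, replace = TRUE, prob = probs),
          collapse = "")
  })
  planted <- character(NROW(plan))
  if (NROW(plan)) {
    for (i in seq_len(NROW(plan))) {
      ins <- .check_dna(plan$pattern[i], paste0("plant ", plan$name[i]),
                        allow_n = FALSE)
      if (plan$strand[i] == "-") ins <- reverse_complement(ins)
      planted[i] <- ins
      substr(sequence, plan$position[i] + 1L,
             plan$position[i] + nchar(ins)) <- ins
    }
  }
  truth <- data.frame(box_name = as.character(plan$name),
                      start = plan$position,
                      end = plan$position + widths,
                      strand = as.character(plan$strand),
                      planted_pattern = planted,
                      stringsAsFactors = FALSE)
  list(sequence = sequence, truth = truth)
}

#' Simulate a two-group expression cohort with a planted structure
#'
#' Generates linear-scale, non-negative mRNA and miRNA matrices (features in
#' rows, samples in columns) under a log2-Gaussian model: each feature has a
#' baseline log2 level plus `noise_sd` Gaussian noise. Half the samples
#' (rounding down) are labelled TI; in TI samples the signature's induced
#' genes are shifted *down* and its repressed genes *up* by
#' `effect_size_delta`, and cluster miRNAs are shifted up by `c19mc_shift`
#' (all on the log2 scale). The first ligand name is the planted ligand: its
#' log2 signal mixes the standardized log2 cumulative-cluster variable with
#' weight `ligand_rho` (Gaussian-copula coupling, so the population
#' correlation on the log scale is `ligand_rho`); remaining ligands are
#' independent noise.
#'
#' @param config A [sim_config()].
#' @param signature A [gene_signature()] (default [default_gene_signature()]).
#' @param cluster_members Cluster miRNA names ([default_c19mc_members()]).
#' @param ligand_names Ligand mRNA names; first entry is the planted ligand.
#' @param n_background_mrna,n_background_mirna Extra unstructured features.
#' @return A list with `mrna`, `mirna` (linear-scale matrices), `labels`
#'   (named `"TC"`/`"TI"` per sample), and `truth` (planted ligand name and
#'   generator parameters).
#' @export
simulate_expression_cohort <- function(config,
                                       signature = default_gene_signature(),
                                       cluster_members = default_c19mc_members(),
                                       ligand_names = default_ligand_names(),
                                       n_background_mrna = 50L,
                                       n_background_mirna = 10L) {
  stopifnot(inherits(config, "sim_config"))
  sig_genes <- c(signature$induced, signature$repressed)
  bg_mrna <- sprintf("BG-%03d", seq_len(n_background_mrna))
  bg_mirna <- sprintf("nonC19-miR-%02d", seq_len(n_background_mirna))
  all_names <- c(sig_genes, ligand_names, bg_mrna, cluster_members, bg_mirna)
  if (anyDuplicated(all_names)) {
    stop("signature genes, ligand names, cluster members and background ",
         "features must be disjoint; duplicated: ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "))
  }

  n <- config$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  .with_seed(config$seed, {
    n_ti <- n %/% 2L
    ti_idx <- sample.int(n, n_ti)
    labels <- stats::setNames(rep("TC", n), samples)
    labels[ti_idx] <- "TI"
    is_ti <- labels == "TI"

    draw_log2 <- function(features, shift_ti = 0) {
      mu <- stats::runif(length(features), 3, 10)
      m <- matrix(stats::rnorm(length(features) * n, mean = mu,
                               sd = config$noise_sd),
                  nrow = length(features), ncol = n,
                  dimnames = list(features, samples))
      m[, is_ti] <- m[, is_ti] + shift_ti
      m
    }

    mirna_log <- rbind(
      draw_log2(cluster_members, shift_ti = config$c19mc_shift),
      draw_log2(bg_mirna))
    mirna <- pmax(2 ^ mirna_log - 1, 0)

    sig_log <- rbind(
      draw_log2(signature$induced, shift_ti = -config$effect_size_delta),
      draw_log2(signature$repressed, shift_ti = config$effect_size_delta))

    # planted ligand: Gaussian-copula coupling to the standardized log2
    # cumulative cluster load
    totals <- colSums(mirna[cluster_members, , drop = FALSE])
    s_std <- as.numeric(scale(log2(totals + 1)))
    rho <- config$ligand_rho
    mu_lig <- stats::runif(1, 3, 10)
    eps <- stats::rnorm(n)
    planted_log <- mu_lig + config$noise_sd *
      (rho * s_std + sqrt(1 - rho^2) * eps)
    other_log <- draw_log2(ligand_names[-1L])
    lig_log <- rbind(matrix(planted_log, nrow = 1,
                            dimnames = list(ligand_names[1L], samples)),
                     other_log)

    mrna_log <- rbind(sig_log, lig_log, draw_log2(bg_mrna))
    mrna <- pmax(2 ^ mrna_log - 1, 0)

    list(mrna = mrna, mirna = mirna, labels = labels,
         truth = list(planted_ligand = ligand_names[1L],
                      ligand_rho = rho, config = config))
  })
}

#' Simulate a coverage track with a planted focal deletion
#'
#' Per-base depth is Poisson(`depth_lambda`) outside the deletion and exactly
#' zero inside it. Coordinates are absolute 0-based, half-open: the track
#' covers `[offset, offset + contig_length)` so chromosome-scale breakpoint
#' coordinates can be used without simulating a whole chromosome.
#'
#' @param contig_length Track length in bases.
#' @param deletion_interval `c(start, end)` absolute 0-based half-open, or
#'   `NULL` for no deletion.
#' @param depth_lambda Mean per-base depth (> 0).
#' @param seed Optional seed.
#' @param contig Contig name (default `"chr17"`).
#' @param offset Absolute 0-based start of the simulated track.
#' @return A list with `track` (a [coverage_track()]) and `truth` (the
#'   deletion interval, or `NULL`).
#' @examples
#' sim <- simulate_coverage_with_deletion(1000, c(200, 400), 30, seed = 1)
#' @export
simulate_coverage_with_deletion <- function(contig_length,
                                            deletion_interval = NULL,
                                            depth_lambda = 30, seed = NULL,
                                            contig = "chr17", offset = 0) {
  contig_length <- as.integer(contig_length)
  stopifnot(contig_length >= 1L, depth_lambda > 0, offset >= 0)
  if (!is.null(deletion_interval)) {
    stopifnot(length(deletion_interval) == 2L)
    d0 <- deletion_interval[1]; d1 <- deletion_interval[2]
    if (d0 >= d1 || d0 < offset || d1 > offset + contig_length) {
      stop("deletion interval [", d0, ", ", d1, ") must lie within the ",
           "track bounds [", offset, ", ", offset + contig_length, ")")
    }
  }
  depth <- .with_seed(seed, stats::rpois(contig_length, depth_lambda))
  if (!is.null(deletion_interval)) {
    i0 <- deletion_interval[1] - offset + 1L
    i1 <- deletion_interval[2] - offset
    depth[i0:i1] <- 0L
  }
  list(track = coverage_track(contig, offset, depth),
       truth = deletion_interval)
}

#' Build a fusion-junction amplicon with a planted linker
#'
#' Concatenates `left_flank + linker + right_flank`, modelling a rearrangement
#' junction in which non-templated linker bases were introduced between the
#' two fused flanks. [decompose_junction()] is the matching inverse.
#'
#' @param left_flank,right_flank Non-empty ACGTN strings.
#' @param linker ACGTN string, possibly empty.
#' @return The junction sequence.
#' @examples
#' make_junction_fixture("ACGTACGT", "GGTTGGTTGGTT", "TTAACCGG")
#' @export
make_junction_fixture <- function(left_flank, linker, right_flank) {
  left_flank <- .check_dna(left_flank, "left_flank")
  right_flank <- .check_dna(right_flank, "right_flank")
  linker <- .check_dna(linker, "linker", allow_empty = TRUE)
  paste0(left_flank, linker, right_flank)
}
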