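# Focal-deletion inference from RNA-seq coverage gaps, fusion-junction
# decomposition, and expected PCR product sizes across a rearrangement.
#
# All genomic intervals are 0-based, half-open; printed reports use 1-based
# inclusive coordinates. An RNA-seq coverage gap inside a single gene can be
# mere splicing; a gap whose two ends fall in the introns of two *different*
# genes is the signature of a focal deletion fusing them, so only that case
# yields a fusion call.

#' Per-base coverage track
#'
#' @param contig Contig name.
#' @param offset Absolute 0-based coordinate of the first base of `depth`.
#' @param depth Integer vector of non-negative per-base depths.
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(contig, offset, depth) {
  stopifnot(is.character(contig), length(contig) == 1L)
  offset <- as.numeric(offset)
  stopifnot(is.finite(offset), offset >= 0, length(depth) >= 1L)
  depth <- as.integer(depth)
  if (anyNA(depth) || any(depth < 0L)) stop("depths must be non-negative")
  structure(list(contig = contig, offset = offset, depth = depth),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s:%s-%s (%s bp, mean depth %.1f)\n",
              x$contig, format(x$offset + 1, big.mark = ","),
              format(x$offset + length(x$depth), big.mark = ","),
              format(length(x$depth), big.mark = ","), mean(x$depth)))
  invisible(x)
}

#' Read a single-contig bedGraph into a per-base coverage track
#'
#' Intervals must not overlap; uncovered positions between intervals are
#' filled with depth 0. The track starts at the first covered interval.
#'
#' @param path Path to a bedGraph file (contig, start, end, value).
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L) stop("empty bedGraph: ", path)
  contigs <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (length(contigs) != 1L) {
    stop("expected a single contig per track, found: ",
         paste(contigs, collapse = ", "))
  }
  gr <- GenomicRanges::sort(gr)
  s1 <- BiocGenerics::start(gr)   # 1-based inclusive
  e1 <- BiocGenerics::end(gr)
  if (length(gr) > 1L && any(s1[-1L] <= e1[-length(gr)])) {
    i <- which(s1[-1L] <= e1[-length(gr)])[1]
    stop("overlapping bedGraph intervals: [", s1[i] - 1, ", ", e1[i],
         ") and [", s1[i + 1L] - 1, ", ", e1[i + 1L], ")")
  }
  offset <- s1[1L] - 1          # 0-based
  len <- e1[length(gr)] - offset
  depth <- integer(len)
  score <- as.integer(round(gr$score))
  for (i in seq_along(gr)) {
    depth[(s1[i] - offset):(e1[i] - offset)] <- score[i]
  }
  coverage_track(contigs, offset, depth)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal depth are emitted as single intervals, including zero-depth
#' runs, so that [read_bedgraph()] reproduces the track exactly.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  runs <- rle(track$depth)
  ends0 <- track$offset + cumsum(runs$lengths)        # half-open ends
  starts0 <- ends0 - runs$lengths
  gr <- GenomicRanges::GRanges(
    seqnames = track$contig,
    ranges = IRanges::IRanges(start = starts0 + 1, end = ends0),
    score = runs$values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Find maximal low-coverage gaps in a track
#'
#' Maximal runs of bases with depth at most `max_depth` and length at least
#' `min_span_bp`, in coordinate order. Runs are maximal: any base adjacent to
#' a reported run exceeds `max_depth`.
#'
#' @param track A [coverage_track()].
#' @param max_depth Highest depth still counted as "gap" (default 0).
#' @param min_span_bp Minimum reported run length (default 10000: the scale
#'   at which a zero-coverage run stops looking like splicing and starts
#'   looking like a focal deletion; the motivating event spans 76 kb).
#' @return Data frame with absolute 0-based half-open `start`, `end`, and
#'   `span_bp`.
#' @export
find_coverage_gaps <- function(track, max_depth = 0L, min_span_bp = 10000L) {
  stopifnot(inherits(track, "coverage_track"))
  min_span_bp <- as.numeric(min_span_bp)
  if (min_span_bp < 1) stop("min_span_bp must be >= 1")
  runs <- rle(track$depth <= max_depth)
  ends0 <- track$offset + cumsum(runs$lengths)
  starts0 <- ends0 - runs$lengths
  keep <- runs$values & runs$lengths >= min_span_bp
  data.frame(start = starts0[keep], end = ends0[keep],
             span_bp = runs$lengths[keep])
}

#' Gene model with exon structure
#'
#' @param name Gene name.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data frame of 0-based half-open exon
#'   intervals, sorted and non-overlapping (genomic order).
#' @return A `gene_model` object; introns are derived as the inter-exon gaps.
#' @export
gene_model <- function(name, contig, strand, exons) {
  strand <- match.arg(strand, c("+", "-"))
  exons <- as.matrix(exons)
  stopifnot(ncol(exons) == 2L, nrow(exons) >= 1L)
  colnames(exons) <- c("start", "end")
  if (any(exons[, 1] >= exons[, 2])) stop("exon start must be < end")
  if (nrow(exons) > 1L) {
    if (is.unsorted(exons[, 1], strictly = TRUE) ||
        any(exons[-1L, 1] < exons[-nrow(exons), 2])) {
      stop("exons must be sorted and non-overlapping in genomic order")
    }
  }
  introns <- if (nrow(exons) > 1L) {
    cbind(start = exons[-nrow(exons), 2], end = exons[-1L, 1])
  } else {
    matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  }
  structure(list(name = name, contig = contig, strand = strand,
                 exons = exons, introns = introns),
            class = "gene_model")
}

# Locate a breakpoint within a gene list: returns gene name, feature type
# (exon/intron/intergenic) and the feature index in *transcription* order
# (for "-" genes, intron k in genomic order is intron n_introns - k + 1).
.locate_breakpoint <- function(pos, genes) {
  for (g in genes) {
    span0 <- g$exons[1, 1]; span1 <- g$exons[nrow(g$exons), 2]
    if (pos < span0 || pos >= span1) next
    ex <- which(pos >= g$exons[, 1] & pos < g$exons[, 2])
    if (length(ex)) {
      idx <- if (g$strand == "+") ex else nrow(g$exons) - ex + 1L
      return(list(gene = g$name, feature = "exon", index = idx,
                  strand = g$strand))
    }
    intr <- which(pos >= g$introns[, 1] & pos < g$introns[, 2])
    if (length(intr)) {
      n_int <- nrow(g$introns)
      idx <- if (g$strand == "+") intr else n_int - intr + 1L
      return(list(gene = g$name, feature = "intron", index = idx,
                  strand = g$strand))
    }
  }
  list(gene = NA_character_, feature = "intergenic", index = NA_integer_,
       strand = NA_character_)
}

#' Assign a coverage gap to gene features and build a fusion call
#'
#' The gap's left breakpoint (`gap start`) and right breakpoint (`gap end`)
#' are each assigned to the gene and feature containing them, with intron and
#' exon indices counted in transcription order (reversed relative to genomic
#' order for minus-strand genes). A fusion call (`is_fusion = TRUE`) is
#' emitted only when both breakpoints fall in introns of two different genes;
#' a gap confined to one gene is annotated `"possible splicing"`, and a gap
#' inside an exon or intergenic space is annotated accordingly.
#'
#' @param gap Numeric `c(start, end)` (0-based half-open) or a one-row data
#'   frame from [find_coverage_gaps()].
#' @param genes Non-empty list of [gene_model()] objects on the gap's contig.
#' @return A `fusion_call` object: `left_gene`, `right_gene`,
#'   `left_feature`/`right_feature`, `left_intron_index`/`right_intron_index`
#'   (transcription order; `NA` unless the breakpoint is intronic),
#'   `gap_start`, `gap_end`, `span_bp`, `span_kb_rounded`, `is_fusion`,
#'   `note`.
#' @export
assign_gap_to_genes <- function(gap, genes) {
  if (is.data.frame(gap)) {
    stopifnot(nrow(gap) == 1L)
    gap <- c(gap$start, gap$end)
  }
  stopifnot(length(gap) == 2L, gap[1] < gap[2])
  if (!length(genes)) stop("empty gene list")
  if (inherits(genes, "gene_model")) genes <- list(genes)
  stopifnot(all(vapply(genes, inherits, logical(1), "gene_model")))
  contigs <- unique(vapply(genes, `[[`, character(1), "contig"))
  if (length(contigs) != 1L) {
    stop("gene models span multiple contigs: ",
         paste(contigs, collapse = ", "))
  }

  left <- .locate_breakpoint(gap[1], genes)
  right <- .locate_breakpoint(gap[2], genes)
  span_bp <- gap[2] - gap[1]
  is_fusion <- left$feature == "intron" && right$feature == "intron" &&
    !is.na(left$gene) && !is.na(right$gene) && left$gene != right$gene
  note <- if (is_fusion) {
    "focal deletion joining two genes' introns"
  } else if (!is.na(left$gene) && identical(left$gene, right$gene)) {
    "possible splicing (both breakpoints within one gene)"
  } else if (left$feature == "exon" || right$feature == "exon") {
    "breakpoint in exon; no fusion call"
  } else {
    "breakpoint(s) intergenic; no fusion call"
  }
  structure(list(
    left_gene = left$gene, right_gene = right$gene,
    left_feature = left$feature, right_feature = right$feature,
    left_intron_index = if (left$feature == "intron") left$index else NA_integer_,
    right_intron_index = if (right$feature == "intron") right$index else NA_integer_,
    gap_start = gap[1], gap_end = gap[2],
    span_bp = span_bp, span_kb_rounded = round(span_bp / 1000),
    is_fusion = is_fusion, contig = contigs, note = note),
    class = "fusion_call")
}

#' @export
print.fusion_call <- function(x, ...) {
  cat(sprintf("<fusion_call> %s:%s-%s (1-based inclusive), span %s bp (~%d kb)\n",
              x$contig, format(x$gap_start + 1, big.mark = ","),
              format(x$gap_end, big.mark = ","),
              format(x$span_bp, big.mark = ","), x$span_kb_rounded))
  fmt_bp <- function(g, f, i) {
    if (f == "intron") sprintf("%s intron %d", g, i)
    else if (f == "exon") sprintf("%s (exon)", g)
    else "intergenic"
  }
  cat("  left breakpoint: ",
      fmt_bp(x$left_gene, x$left_feature, x$left_intron_index), "\n",
      "  right breakpoint:",
      fmt_bp(x$right_gene, x$right_feature, x$right_intron_index), "\n")
  cat("  ", if (x$is_fusion) "FUSION: " else "", x$note, "\n", sep = "")
  invisible(x)
}

#' Decompose a fusion-junction sequence into flank matches and a linker
#'
#' `left_match_len` is the longest prefix of the junction equal to a prefix
#' of the left flank; `right_match_len` is then the longest suffix of the
#' *remaining* junction equal to a suffix of the right flank (left maximized
#' first, segments never overlap); whatever is left in between is the linker
#' -- the non-templated bases inserted at the rearrangement breakpoint.
#' `ambiguous = TRUE` flags microhomology: the right match could be extended
#' further if it were allowed to overlap the left match, so the exact split
#' point is conventional rather than determined by the sequence.
#'
#' @param junction Junction sequence (>= 2 bases, ACGTN).
#' @param left_flank,right_flank Flank sequences (non-empty, ACGTN).
#' @return A list of class `junction_decomposition`: `left_match_len`,
#'   `linker`, `right_match_len`, `ambiguous`. The three segment lengths
#'   always sum to the junction length.
#' @examples
#' decompose_junction("AAACGGTTT", "AAACAA", "CCGGTTT")
#' @export
decompose_junction <- function(junction, left_flank, right_flank) {
  junction <- .check_dna(junction, "junction")
  if (nchar(junction) < 2L) stop("junction must be at least 2 bases")
  left_flank <- .check_dna(left_flank, "left_flank")
  right_flank <- .check_dna(right_flank, "right_flank")

  jc <- strsplit(junction, "", fixed = TRUE)[[1]]
  lc <- strsplit(left_flank, "", fixed = TRUE)[[1]]
  rc <- strsplit(right_flank, "", fixed = TRUE)[[1]]

  k <- min(length(jc), length(lc))
  neq <- which(jc[seq_len(k)] != lc[seq_len(k)])
  left_len <- if (length(neq)) neq[1] - 1L else k

  suffix_match <- function(x, y) {
    k <- min(length(x), length(y))
    if (k == 0L) return(0L)
    neq <- which(rev(x)[seq_len(k)] != rev(y)[seq_len(k)])
    if (length(neq)) neq[1] - 1L else k
  }
  remaining <- jc[seq_len(length(jc) - left_len) + left_len]
  right_len <- suffix_match(remaining, rc)
  right_full <- suffix_match(jc, rc)

  linker <- paste(remaining[seq_len(length(remaining) - right_len)],
                  collapse = "")
  structure(list(left_match_len = left_len, linker = linker,
                 right_match_len = right_len,
                 ambiguous = right_full > right_len),
            class = "junction_decomposition")
}

#' @export
print.junction_decomposition <- function(x, ...) {
  cat(sprintf("<junction_decomposition> left %d | linker %d nt%s | right %d%s\n",
              x$left_match_len, nchar(x$linker),
              if (nzchar(x$linker)) paste0(" (", x$linker, ")") else "",
              x$right_match_len,
              if (x$ambiguous) " [ambiguous: boundary microhomology]" else ""))
  invisible(x)
}

#' Expected PCR product size across a focal deletion
#'
#' For primers flanking the deleted interval, the rearranged template yields
#' a product of `(gap_start - fwd_primer_start) + linker_len +
#' (rev_primer_end - gap_end)` bases: the retained left and right template
#' segments plus any junction linker.
#'
#' @param call A `fusion_call` (or numeric `c(gap_start, gap_end)`).
#' @param fwd_primer_start 0-based start of the forward primer's 5' end,
#'   upstream of the gap.
#' @param rev_primer_end 0-based half-open end of the reverse primer's
#'   binding site, downstream of the gap.
#' @param linker_len Junction linker length in bases (default 0).
#' @return Expected amplicon size in bases.
#' @examples
#' expected_amplicon_size(c(200, 300), 100, 360)  # 160
#' @export
expected_amplicon_size <- function(call, fwd_primer_start, rev_primer_end,
                                   linker_len = 0) {
  if (inherits(call, "fusion_call")) {
    gap <- c(call$gap_start, call$gap_end)
  } else {
    stopifnot(length(call) == 2L)
    gap <- as.numeric(call)
  }
  stopifnot(gap[1] < gap[2], linker_len >= 0)
  inside <- function(p) p >= gap[1] && p < gap[2]
  if (inside(fwd_primer_start) || inside(rev_primer_end - 1)) {
    stop("primer lies inside the deleted interval [", gap[1], ", ", gap[2],
         "): no template")
  }
  if (fwd_primer_start >= gap[1]) {
    stop("forward primer start (", fwd_primer_start,
         ") must lie upstream of the gap start (", gap[1], ")")
  }
  if (rev_primer_end <= gap[2]) {
    stop("reverse primer end (", rev_primer_end,
         ") must lie downstream of the gap end (", gap[2], ")")
  }
  (gap[1] - fwd_primer_start) + linker_len + (rev_primer_end - gap[2])
}

#' Schematic gene models around the chr17 focal deletion
#'
#' Synthetic exon layouts for a minus-strand TP53-like gene and a plus-strand
#' FXR2-like gene, built so that the printed breakpoint pair
#' chr17:7,501,000-7,577,371 falls in the FXR2-like gene's intron 7 and the
#' TP53-like gene's intron 3 (both in transcription order). The exon
#' coordinates are schematic stand-ins, not annotation: only the breakpoint
#' containment structure matters for the gap-to-gene assignment.
#'
#' @return A list of two [gene_model()] objects (`FXR2`, `TP53`).
#' @export
example_fusion_models <- function() {
  # FXR2-like, "+" strand: 17 exons; genomic intron 7 contains 7,501,000
  fxr2_starts <- c(7491000, 7492000, 7493000, 7494000, 7495000, 7496000,
                   7497000, 7503000, 7504000, 7505000, 7506000, 7507000,
                   7508000, 7509000, 7510000, 7511000, 7512000)
  fxr2 <- gene_model("FXR2", "chr17", "+",
                     cbind(fxr2_starts, fxr2_starts + 400))
  # TP53-like, "-" strand: 11 exons; transcription intron 3 = genomic
  # intron 8 (n_introns = 10), which must contain 7,577,371
  tp53_starts <- c(7565000, 7566000, 7567000, 7568000, 7569000, 7570000,
                   7571000, 7572000, 7578000, 7579000, 7580000)
  tp53 <- gene_model("TP53", "chr17", "-",
                     cbind(tp53_starts, tp53_starts + 400))
  list(FXR2 = fxr2, TP53 = tp53)
}
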