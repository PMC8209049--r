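# Palindrome and box scanning over genomic windows.
#
# All hit coordinates are window-local, 0-based, half-open. The driving idea
# is that p53 dimer/tetramer response elements are built from DNA strings
# equal to their own reverse complement (necessarily even-length over ACGT),
# so a scan for such strings plus a catalogue of named consensus boxes maps
# the p53/Sp1 binding landscape of a region.

IUPAC_FROM <- "ACGTNRYSWKMBDHV"
IUPAC_TO   <- "TGCANYRSWMKVHDB"

.complement_chars <- function(chars) {
  chartr(IUPAC_FROM, IUPAC_TO, chars)
}

#' Reverse complement of a DNA string
#'
#' Watson--Crick complement, reversed. IUPAC ambiguity codes are complemented
#' to their mirror codes (e.g. R to Y); length is preserved.
#'
#' @param seq A single DNA string (uppercase or lowercase; returned uppercase).
#' @return The reverse complement string.
#' @examples
#' reverse_complement("AAA")        # "TTT"
#' reverse_complement("GCCCGGGC")   # itself: a reverse-complement palindrome
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!nzchar(seq)) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% strsplit(IUPAC_FROM, "")[[1]])
  if (length(bad)) {
    stop("invalid DNA character '", chars[bad[1]], "' at position ", bad[1])
  }
  paste(rev(.complement_chars(chars)), collapse = "")
}

#' Test whether a DNA string is a reverse-complement palindrome
#'
#' `TRUE` iff the string equals its own reverse complement. Strings containing
#' N or other IUPAC ambiguity codes are never palindromes under this policy
#' (an ambiguous base cannot anchor strict dyad symmetry), and odd-length
#' ACGT strings never qualify.
#'
#' @param seq A single DNA string.
#' @return Logical flag.
#' @examples
#' is_rc_palindrome("ACATGT")      # TRUE
#' is_rc_palindrome("AGCAT")       # FALSE (odd length)
#' @export
is_rc_palindrome <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) return(FALSE)
  identical(reverse_complement(seq), seq)
}

.empty_hits <- function() {
  data.frame(box_name = character(0), category = character(0),
             start = numeric(0), end = numeric(0), strand = character(0),
             mismatches = integer(0), percent_position = numeric(0),
             stringsAsFactors = FALSE)
}

#' Enumerate all reverse-complement palindromic substrings
#'
#' Reports every substring of even length in `[min_len, max_len]` that equals
#' its own reverse complement, once per (start, length). Overlapping and
#' nested hits are all reported: the 6-mer CCCGGG inside the 8-mer GCCCGGGC
#' counts as a separate box. Windows containing non-ACGT characters never
#' match. Palindromes are strand-symmetric, so strand is always `"+"`.
#'
#' @param seq A single DNA string.
#' @param min_len,max_len Even substring lengths to scan (defaults 6 and 10,
#'   the range used for the C19MC landscape maps). Odd values are an error:
#'   an odd-length ACGT string can never equal its reverse complement, since
#'   its central base would have to be its own complement.
#' @return A data frame of hits with columns `box_name` (e.g.
#'   `"palindrome-8mer"`), `category`, 0-based half-open `start`/`end`,
#'   `strand`, `mismatches`, `percent_position` (`NA` until mapped by
#'   [to_percent_coordinates()]).
#' @examples
#' enumerate_palindromes("ACATGT")
#' @export
enumerate_palindromes <- function(seq, min_len = 6L, max_len = 10L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (min_len %% 2L != 0L || max_len %% 2L != 0L) {
    stop("min_len and max_len must be even: odd-length ACGT strings can ",
         "never be reverse-complement palindromes (the central base would ",
         "need to complement itself)")
  }
  if (min_len < 2L || min_len > max_len) stop("need 2 <= min_len <= max_len")
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < min_len) return(.empty_hits())

  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- .complement_chars(chars)
  acgt_bad <- cumsum(!chars %in% c("A", "C", "G", "T"))

  out <- vector("list", 0L)
  upper <- min(max_len, if (L %% 2L == 0L) L else L - 1L)
  if (upper < min_len) return(.empty_hits())
  for (len in seq(min_len, upper, by = 2L)) {
    n_win <- L - len + 1L
    if (n_win < 1L) break
    starts <- seq_len(n_win)                       # 1-based window starts
    ok <- rep(TRUE, n_win)
    for (i in seq_len(len %/% 2L) - 1L) {
      ok <- ok & (chars[starts + i] == comp[starts + len - 1L - i])
    }
    # reject windows with any non-ACGT base
    n_bad <- acgt_bad[starts + len - 1L] - c(0L, acgt_bad)[starts]
    ok <- ok & (n_bad == 0L)
    if (any(ok)) {
      s0 <- starts[ok] - 1L                        # back to 0-based
      out[[length(out) + 1L]] <- data.frame(
        box_name = sprintf("palindrome-%dmer", len),
        category = "PALINDROME",
        start = as.numeric(s0), end = as.numeric(s0 + len),
        strand = "+", mismatches = 0L, percent_position = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_hits())
  hits <- do.call(rbind, out)
  hits[order(hits$start, hits$end), , drop = FALSE]
}

#' Length of the longest reverse-complement palindromic substring
#'
#' @param seq A single DNA string.
#' @return Integer length (0 if no palindromic substring of length >= 2).
#' @examples
#' longest_rc_palindrome("CAACATGTTG")  # 10
#' @export
longest_rc_palindrome <- function(seq) {
  L <- nchar(seq)
  max_even <- if (L %% 2L == 0L) L else L - 1L
  if (max_even < 2L) return(0L)
  hits <- enumerate_palindromes(seq, 2L, max_even)
  if (nrow(hits) == 0L) return(0L)
  as.integer(max(hits$end - hits$start))
}

.scan_one_pattern <- function(subject, pattern, max_mm) {
  m <- Biostrings::matchPattern(pattern, subject,
                                max.mismatch = max_mm,
                                fixed = "subject")
  if (length(m) == 0L) return(NULL)
  starts <- BiocGenerics::start(m)
  mm <- Biostrings::neditStartingAt(Biostrings::DNAString(pattern), subject,
                                    starting.at = starts, fixed = "subject")
  list(starts = starts, mismatches = as.integer(mm))
}

#' Scan a sequence for motif box hits
#'
#' Every position where a box pattern matches with at most its allowed number
#' of mismatches is reported. Non-palindromic boxes are additionally matched
#' on the reverse strand when `both_strands = TRUE` and reported in
#' window-forward coordinates with strand `"-"`; palindromic patterns are
#' strand-symmetric and scanned once. A window containing N never matches
#' (mismatch allowances do not absorb N). Overlapping hits are all kept.
#'
#' @param seq A single DNA string (uppercased internally).
#' @param boxes A list of [motif_box()] objects, e.g. [default_motif_boxes()].
#' @param both_strands Also scan the reverse strand for non-palindromic
#'   patterns (default `TRUE`).
#' @return A hit data frame as in [enumerate_palindromes()], ordered by start.
#' @examples
#' find_box_hits("TTGCCCGGGCTT", default_motif_boxes()["CP1-8mer"])
#' @export
find_box_hits <- function(seq, boxes, both_strands = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!length(boxes)) stop("empty box list: supply at least one motif_box")
  if (inherits(boxes, "motif_box")) boxes <- list(boxes)
  ok <- vapply(boxes, inherits, logical(1), "motif_box")
  if (!all(ok)) stop("boxes must all be motif_box objects")

  seq <- toupper(seq)
  subject <- Biostrings::DNAString(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_run <- cumsum(chars == "N")
  has_n <- function(s0, len) {                     # s0 0-based
    (n_run[s0 + len] - c(0L, n_run)[s0 + 1L]) > 0L
  }

  rows <- list()
  add <- function(box, starts1, mismatches, strand) {
    s0 <- starts1 - 1L
    len <- nchar(box$pattern)
    keep <- !has_n(s0, len) & s0 >= 0L & (s0 + len) <= nchar(seq)
    if (!any(keep)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      box_name = box$name, category = box$category,
      start = as.numeric(s0[keep]), end = as.numeric(s0[keep] + len),
      strand = strand, mismatches = mismatches[keep],
      percent_position = NA_real_, stringsAsFactors = FALSE)
  }

  for (box in boxes) {
    if (nchar(box$pattern) > nchar(seq)) next
    fwd <- .scan_one_pattern(subject, box$pattern, box$max_mismatches)
    if (!is.null(fwd)) add(box, fwd$starts, fwd$mismatches, "+")
    rc <- reverse_complement(box$pattern)
    if (both_strands && !identical(rc, box$pattern)) {
      rev <- .scan_one_pattern(subject, rc, box$max_mismatches)
      if (!is.null(rev)) add(box, rev$starts, rev$mismatches, "-")
    }
  }
  if (!length(rows)) return(.empty_hits())
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$start, hits$end, hits$box_name, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Map hit coordinates to percent-of-window positions
#'
#' Linear map placing the window start at 0 and the window end at 100, the
#' percent-coordinate convention of the C19MC binding-site maps.
#'
#' @param hits Hit data frame ([find_box_hits()]/[enumerate_palindromes()]),
#'   with `start` in the same coordinate system as `window` (pass window-local
#'   hits with a window starting at 0, or contig-level hits with contig
#'   coordinates).
#' @param window A [region_spec()].
#' @return `hits` with `percent_position` filled in; order preserved.
#' @export
to_percent_coordinates <- function(hits, window) {
  stopifnot(inherits(window, "region_spec"))
  if (nrow(hits) == 0L) return(hits)
  outside <- hits$start < window$start | hits$end > window$end
  if (any(outside)) {
    i <- which(outside)[1]
    stop("hit ", hits$box_name[i], " [", hits$start[i], ", ", hits$end[i],
         ") lies outside window [", window$start, ", ", window$end, ")")
  }
  hits$percent_position <-
    100 * (hits$start - window$start) / (window$end - window$start)
  hits
}

#' Summarise a box landscape relative to an inner region
#'
#' Assigns every hit to exactly one zone by its start coordinate -- inside the
#' inner region, in the left flank, or in the right flank -- and reports
#' per-box counts plus the set of boxes occurring only inside (e.g. the
#' 8-mer GP box confined to the miRNA cluster proper).
#'
#' @param hits Hit data frame, coordinates matching `window`.
#' @param window Outer [region_spec()] (the scanned window).
#' @param inner Inner [region_spec()], nested in `window`.
#' @return A list with `counts` (data frame: box_name, inside, left_flank,
#'   right_flank, total) and `inside_only` (character vector of box names with
#'   hits inside and none in either flank).
#' @export
summarize_landscape <- function(hits, window, inner) {
  stopifnot(inherits(window, "region_spec"), inherits(inner, "region_spec"))
  if (inner$start < window$start || inner$end > window$end) {
    stop("inner region [", inner$start, ", ", inner$end,
         ") is not nested in window [", window$start, ", ", window$end, ")")
  }
  boxes <- unique(hits$box_name)
  counts <- data.frame(box_name = boxes,
                       inside = integer(length(boxes)),
                       left_flank = integer(length(boxes)),
                       right_flank = integer(length(boxes)),
                       stringsAsFactors = FALSE)
  if (nrow(hits)) {
    zone <- ifelse(hits$start < inner$start, "left_flank",
                   ifelse(hits$start < inner$end, "inside", "right_flank"))
    tab <- table(hits$box_name, factor(zone, c("inside", "left_flank",
                                               "right_flank")))
    counts$inside <- as.integer(tab[boxes, "inside"])
    counts$left_flank <- as.integer(tab[boxes, "left_flank"])
    counts$right_flank <- as.integer(tab[boxes, "right_flank"])
  }
  counts$total <- counts$inside + counts$left_flank + counts$right_flank
  inside_only <- counts$box_name[counts$inside > 0L &
                                 counts$left_flank == 0L &
                                 counts$right_flank == 0L]
  list(counts = counts, inside_only = inside_only)
}

#' Write motif hits as BED6
#'
#' @param hits Hit data frame.
#' @param path Output path.
#' @param contig Contig name for column 1.
#' @param offset Added to `start`/`end`, e.g. the window's contig start, so
#'   window-local hits can be written in contig coordinates.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path, contig = "window", offset = 0) {
  bed <- data.frame(chrom = contig,
                    chromStart = format(hits$start + offset, scientific = FALSE,
                                        trim = TRUE),
                    chromEnd = format(hits$end + offset, scientific = FALSE,
                                      trim = TRUE),
                    name = hits$box_name,
                    score = hits$mismatches,
                    strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
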