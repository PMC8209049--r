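#' DNA motif box definitions
#'
#' A `motif_box` is a named DNA pattern with a category and a mismatch policy.
#' Boxes model the palindromic sub-elements of the p53 binding consensuses of
#' the CDKN1A ("CP box") and GADD45 ("GP box") genes, and Sp1 zinc/nickel
#' dependent binding elements, as scanned by [find_box_hits()].
#'
#' @param name Box label, e.g. `"CP1-8mer"`.
#' @param pattern Uppercase IUPAC DNA string, length 4--12.
#' @param category One of `"CP1"`, `"CP2"`, `"GP"`, `"SP1_ZN"`, `"SP1_NI"`.
#' @param max_mismatches Allowed mismatches per hit, 0 (default) or 1.
#' @param require_palindrome If `TRUE` the pattern must equal its own reverse
#'   complement (checked at construction).
#'
#' @return A `motif_box` object (a validated list).
#' @examples
#' motif_box("CP1-8mer", "GCCCGGGC", "CP1", require_palindrome = TRUE)
#' @export
motif_box <- function(name, pattern, category,
                      max_mismatches = 0L, require_palindrome = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(pattern), length(pattern) == 1L)
  pattern <- toupper(pattern)
  if (!grepl("^[ACGTNRYSWKMBDHV]+$", pattern)) {
    stop("pattern must be an uppercase IUPAC DNA string, got: ", pattern)
  }
  if (nchar(pattern) < 4L || nchar(pattern) > 12L) {
    stop("pattern length must be in [4, 12], got ", nchar(pattern),
         " for box ", name)
  }
  category <- match.arg(category, c("CP1", "CP2", "GP", "SP1_ZN", "SP1_NI"))
  max_mismatches <- as.integer(max_mismatches)
  if (!max_mismatches %in% c(0L, 1L)) {
    stop("max_mismatches must be 0 or 1")
  }
  if (isTRUE(require_palindrome) && reverse_complement(pattern) != pattern) {
    stop("box ", name, " declares require_palindrome but pattern ", pattern,
         " is not its own reverse complement")
  }
  structure(
    list(name = name, pattern = pattern, category = category,
         max_mismatches = max_mismatches,
         require_palindrome = isTRUE(require_palindrome)),
    class = "motif_box"
  )
}

#' @export
print.motif_box <- function(x, ...) {
  cat(sprintf("<motif_box> %s [%s] %s (max mm %d%s)\n",
              x$name, x$category, x$pattern, x$max_mismatches,
              if (x$require_palindrome) ", palindrome" else ""))
  invisible(x)
}

#' Default p53 / Sp1 box set
#'
#' The shipped box catalogue:
#' * CP box-1 (CDKN1A): 6-mer `CCCGGG` and the encompassing 8-mer `GCCCGGGC`.
#' * CP box-2 (CDKN1A): 6-mer `ACATGT` and the extended 10-mer `CAACATGTTG`.
#' * GP box (GADD45): 6-mers `ACATGT` and `GCATGC`, the extended 8-mer
#'   `AGCATGCT`, and two 7-mer probes (the first and last 7 bases of
#'   `AGCATGCT`) matched with up to one mismatch -- an explicit, configurable
#'   reading of the "7-mer palindrome with 1 nucleotide match to the 8-mer"
#'   element (a 7-mer over ACGT can never itself be a reverse-complement
#'   palindrome, so these probes are near-matches, not palindromes).
#' * Sp1 zinc box: canonical GC-box `GGGGCGGGG`. The nickel-dependent Sp1
#'   element has no universally agreed sequence; supply one via `sp1_ni`.
#'
#' @param sp1_ni Optional Sp1 nickel-box pattern (IUPAC string). `NULL`
#'   (default) omits the nickel box from the catalogue.
#' @return A list of [motif_box()] objects.
#' @examples
#' names(default_motif_boxes())
#' @export
default_motif_boxes <- function(sp1_ni = NULL) {
  boxes <- list(
    motif_box("CP1-6mer", "CCCGGG", "CP1", require_palindrome = TRUE),
    motif_box("CP1-8mer", "GCCCGGGC", "CP1", require_palindrome = TRUE),
    motif_box("CP2-6mer", "ACATGT", "CP2", require_palindrome = TRUE),
    motif_box("CP2-10mer", "CAACATGTTG", "CP2", require_palindrome = TRUE),
    motif_box("GP-6mer-a", "ACATGT", "GP", require_palindrome = TRUE),
    motif_box("GP-6mer-b", "GCATGC", "GP", require_palindrome = TRUE),
    motif_box("GP-8mer", "AGCATGCT", "GP", require_palindrome = TRUE),
    motif_box("GP-7mer-L", "AGCATGC", "GP", max_mismatches = 1L),
    motif_box("GP-7mer-R", "GCATGCT", "GP", max_mismatches = 1L),
    motif_box("Sp1-Zn", "GGGGCGGGG", "SP1_ZN")
  )
  if (!is.null(sp1_ni)) {
    boxes <- c(boxes, list(motif_box("Sp1-Ni", sp1_ni, "SP1_NI")))
  }
  names(boxes) <- vapply(boxes, `[[`, character(1), "name")
  boxes
}

#' Genomic region specification
#'
#' Coordinates are 0-based, half-open (`[start, end)`), the BED convention
#' used throughout the package; human-readable reports print 1-based
#' inclusive.
#'
#' @param contig Contig/chromosome name.
#' @param start,end 0-based half-open bounds, `start < end`.
#' @param label Free-text label.
#' @return A `region_spec` object.
#' @examples
#' region_spec("chr19", 54100000, 54300000, "C19MC 200 kb window")
#' @export
region_spec <- function(contig, start, end, label = "") {
  stopifnot(is.character(contig), length(contig) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start < 0 || start >= end) {
    stop("need 0 <= start < end, got [", start, ", ", end, ")")
  }
  structure(list(contig = contig, start = start, end = end, label = label),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region_spec> %s:%s-%s (%s bp)%s\n",
              x$contig, format(x$start + 1, big.mark = ","),
              format(x$end, big.mark = ","),
              format(x$end - x$start, big.mark = ","),
              if (nzchar(x$label)) paste0(" ", x$label) else ""))
  invisible(x)
}
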