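# Ligand / cluster-miRNA correlation screen and qPCR utilities.
#
# The screen mirrors a corrplot-style analysis: split the cohort by
# cumulative cluster-miRNA load, log10-transform, correlate every ligand mRNA
# with every cluster miRNA (Pearson), blank out statistically insignificant
# cells, and order rows/columns by hierarchical clustering so the
# top-correlated ligand stands out.

#' Cumulative cluster miRNA expression per sample
#'
#' Sum of linear-scale expression of the cluster members in each sample.
#' Members missing from the matrix are reported via `message()` and skipped,
#' never imputed.
#'
#' @param mirna Linear-scale miRNA matrix (features x samples).
#' @param members Character vector of cluster member names.
#' @return Named numeric vector of per-sample totals.
#' @export
cumulative_cluster_expression <- function(mirna, members) {
  stopifnot(is.matrix(mirna))
  found <- intersect(members, rownames(mirna))
  missing <- setdiff(members, rownames(mirna))
  if (length(missing)) {
    message("cluster members absent from matrix: ",
            paste(missing, collapse = ", "))
  }
  if (!length(found)) {
    stop("no cluster members found in the matrix; expected any of: ",
         paste(members, collapse = ", "))
  }
  colSums(mirna[found, , drop = FALSE])
}

#' Split samples into high/low groups by a per-sample total
#'
#' The top `n_per_group` samples by total are labelled `"high"`, the bottom
#' `n_per_group` `"low"`, and the middle samples are left unlabelled (`NA`) --
#' the 61-high / 61-low design applied to a 183-sample cohort. Ties at either
#' boundary are broken by sample identifier (lexicographic) and recorded in
#' `method_record`; a fully tied boundary triggers a warning.
#'
#' @param totals Named numeric vector (names are sample identifiers).
#' @param n_per_group Group size, `>= 1` with `2 * n_per_group <= length(totals)`.
#' @return A list of class `partition`: `labels` (named `"high"`/`"low"`/`NA`),
#'   `method_record`, `degenerate`.
#' @examples
#' split_high_low(stats::setNames(1:10, sprintf("S%02d", 1:10)), 3)
#' @export
split_high_low <- function(totals, n_per_group) {
  n_per_group <- as.integer(n_per_group)
  if (n_per_group < 1L) stop("n_per_group must be >= 1")
  n <- length(totals)
  if (2L * n_per_group > n) {
    stop("2 * n_per_group = ", 2L * n_per_group, " exceeds the ", n,
         " available samples")
  }
  ids <- names(totals)
  if (is.null(ids)) ids <- sprintf("sample%03d", seq_len(n))
  # descending by total, ascending by id for ties -> deterministic
  ord <- order(-totals, ids)
  labels <- stats::setNames(rep(NA_character_, n), ids)
  labels[ord[seq_len(n_per_group)]] <- "high"
  labels[ord[(n - n_per_group + 1L):n]] <- "low"

  tie_note <- ""
  hi_cut <- totals[ord[n_per_group]]
  lo_cut <- totals[ord[n - n_per_group + 1L]]
  tied_hi <- sum(totals == hi_cut) > 1L
  tied_lo <- sum(totals == lo_cut) > 1L
  if (tied_hi || tied_lo) {
    tie_note <- "; boundary ties broken by sample id (lexicographic)"
    if (all(totals == totals[1L])) {
      warning("all totals equal; high/low split is determined entirely by ",
              "sample-id tie-breaking")
    }
  }
  structure(list(labels = labels,
                 method_record = paste0("top/bottom n=", n_per_group,
                                        " by cumulative cluster expression",
                                        tie_note),
                 degenerate = all(totals == totals[1L])),
            class = "partition")
}

#' Log10 transform with pseudocount
#'
#' @param matrix Non-negative numeric matrix.
#' @param pseudocount Added before the log; must be > 0 if any value is 0
#'   (default 1, the usual choice for count-like values with zeros).
#' @return `log10(matrix + pseudocount)` with attribute `space = "log10"`.
#' @examples
#' log10_transform(rbind(x = c(0, 999)))
#' @export
log10_transform <- function(matrix, pseudocount = 1) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (any(matrix < 0)) stop("negative values in expression matrix")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(matrix == 0)) {
    stop("matrix contains zeros; a pseudocount > 0 is required")
  }
  out <- log10(matrix + pseudocount)
  attr(out, "space") <- "log10"
  attr(out, "pseudocount") <- pseudocount
  out
}

.hclust_order <- function(m) {
  # deterministic average-linkage leaf order on correlation distance between
  # the rows of m; falls back to the identity order for degenerate shapes
  if (nrow(m) < 3L || ncol(m) < 2L) return(seq_len(nrow(m)))
  cm <- suppressWarnings(stats::cor(t(m)))
  cm[!is.finite(cm)] <- 0
  d <- stats::as.dist(1 - cm)
  stats::hclust(d, method = "average")$order
}

#' Ligand x cluster-miRNA correlation screen
#'
#' Pairwise Pearson (or Spearman) correlations between every ligand mRNA and
#' every cluster miRNA over the shared samples, with two-sided p-values from
#' the t distribution (`t = r * sqrt((n-2) / (1-r^2))`, df = n - 2). Cells
#' with `p >= alpha` are masked (the "insignificant = white" convention);
#' rows and columns are ordered by average-linkage hierarchical clustering on
#' correlation distance (1 - r) between their correlation profiles, with the
#' deterministic leaf order returned by the clustering. Ligands are ranked by
#' mean correlation across the miRNAs to surface the top candidate.
#'
#' @param ligands,mirnas Log-space matrices (features x samples) over the
#'   same samples, at least 3 of them.
#' @param alpha Mask threshold (default 0.05).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param p_adjust Multiple-testing adjustment applied before masking;
#'   `"none"` (default, mirroring the unadjusted mask) or `"BH"`.
#' @return A list of class `correlation_screen`: `r` and `p` matrices
#'   (ligands x miRNAs), logical `mask` (`TRUE` = significant, kept),
#'   `row_order`/`col_order` permutations, `top_ligands` data frame, `alpha`,
#'   `method`, and `flagged` (zero-variance features, masked throughout).
#' @export
correlation_screen <- function(ligands, mirnas, alpha = 0.05,
                               method = c("pearson", "spearman"),
                               p_adjust = c("none", "BH")) {
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  stopifnot(is.matrix(ligands), is.matrix(mirnas))
  if (!identical(colnames(ligands), colnames(mirnas))) {
    stop("ligand and miRNA matrices must share the same samples in the ",
         "same order")
  }
  n <- ncol(ligands)
  if (n < 3L) stop("need at least 3 samples (df = n - 2 > 0), got ", n)

  zero_var <- c(rownames(ligands)[apply(ligands, 1, stats::sd) == 0],
                rownames(mirnas)[apply(mirnas, 1, stats::sd) == 0])
  r <- suppressWarnings(stats::cor(t(ligands), t(mirnas), method = method))
  df <- n - 2
  tval <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  p[abs(r) >= 1] <- 0
  if (p_adjust == "BH") {
    p_masked <- matrix(stats::p.adjust(p, method = "BH"), nrow = nrow(p),
                       dimnames = dimnames(p))
  } else {
    p_masked <- p
  }
  mask <- is.finite(p_masked) & p_masked < alpha
  mask[!is.finite(r)] <- FALSE

  mean_r <- rowMeans(r, na.rm = TRUE)
  top <- data.frame(ligand = rownames(r), mean_r = mean_r,
                    stringsAsFactors = FALSE)
  top <- top[order(-top$mean_r), , drop = FALSE]
  rownames(top) <- NULL

  structure(list(r = r, p = p, mask = mask,
                 row_order = .hclust_order(ifelse(is.finite(r), r, 0)),
                 col_order = .hclust_order(t(ifelse(is.finite(r), r, 0))),
                 top_ligands = top, alpha = alpha, method = method,
                 p_adjust = p_adjust, n = n, flagged = zero_var),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat(sprintf("<correlation_screen> %d ligands x %d miRNAs over %d samples (%s)\n",
              nrow(x$r), ncol(x$r), x$n, x$method))
  cat(sprintf("  significant cells (p < %g%s): %d / %d\n", x$alpha,
              if (x$p_adjust != "none") paste0(", ", x$p_adjust) else "",
              sum(x$mask), length(x$mask)))
  cat("  top ligands by mean r:",
      paste(utils::head(x$top_ligands$ligand, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Heatmap of a correlation screen
#'
#' Renders the clustered, masked correlation matrix with the red/white/black
#' diverging code: red for positive, black for negative, white for masked
#' (insignificant or undefined) cells.
#'
#' @param screen A [correlation_screen()] result.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the plotted matrix.
#' @export
plot_correlation_screen <- function(screen, ...) {
  stopifnot(inherits(screen, "correlation_screen"))
  m <- screen$r[screen$row_order, screen$col_order, drop = FALSE]
  keep <- screen$mask[screen$row_order, screen$col_order, drop = FALSE]
  m[!keep] <- NA
  pal <- grDevices::colorRampPalette(c("black", "white", "red"))(100)
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  zlim = c(-1, 1), col = pal, xlab = "cluster miRNAs",
                  ylab = "ligand mRNAs", ...)
  invisible(m)
}

#' Relative expression by the comparative Ct method
#'
#' `fold = 2^-(dCt_treated - dCt_control)` with
#' `dCt = Ct_target - Ct_reference`; the standard relative quantification of
#' qPCR after normalizing the target to a reference assay (e.g. a miRNA
#' normalized to RNU6B).
#'
#' @param ct_target_treated,ct_reference_treated Ct values in the treated
#'   (or test) condition.
#' @param ct_target_control,ct_reference_control Ct values in the control
#'   (calibrator) condition.
#' @return Relative expression fold (vectorized over its inputs).
#' @examples
#' delta_delta_ct(24, 18, 25, 18)  # target one cycle earlier: fold 2
#' @export
delta_delta_ct <- function(ct_target_treated, ct_reference_treated,
                           ct_target_control, ct_reference_control) {
  vals <- c(ct_target_treated, ct_reference_treated,
            ct_target_control, ct_reference_control)
  if (!all(is.finite(vals))) stop("all Ct values must be finite")
  d_treated <- ct_target_treated - ct_reference_treated
  d_control <- ct_target_control - ct_reference_control
  2 ^ -(d_treated - d_control)
}
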