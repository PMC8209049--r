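# TC/TI stratification from a p53 activity signature.
#
# Tumours competent for p53-dependent transcription (TC) show high expression
# of p53-induced genes and low expression of p53-repressed genes; the
# incompetent group (TI) shows the opposite. A 30-gene signature (20 induced,
# 10 repressed) drives a reproducible two-cluster split of an expression
# cohort, replacing the visual heatmap-cluster selection of the original
# analysis with Ward clustering (or a score-threshold fallback).

#' p53 transcription signature
#'
#' @param induced,repressed Disjoint, non-empty character vectors of gene
#'   identifiers (the canonical signature uses 20 induced and 10 repressed).
#' @return A `gene_signature` object.
#' @examples
#' default_gene_signature()
#' @export
gene_signature <- function(induced, repressed) {
  stopifnot(is.character(induced), is.character(repressed),
            length(induced) > 0L, length(repressed) > 0L)
  if (length(intersect(induced, repressed))) {
    stop("induced and repressed gene lists must be disjoint: ",
         paste(intersect(induced, repressed), collapse = ", "))
  }
  if (anyDuplicated(induced) || anyDuplicated(repressed)) {
    stop("duplicate gene identifiers in signature")
  }
  structure(list(induced = induced, repressed = repressed),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %d induced, %d repressed genes\n",
              length(x$induced), length(x$repressed)))
  invisible(x)
}

#' Read a signature from a two-column text file
#'
#' Expected format: tab- or whitespace-separated columns `gene` and `class`
#' (`induced` or `repressed`), with or without a header.
#'
#' @param path File path.
#' @return A [gene_signature()].
#' @export
read_signature_file <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("signature file needs two columns: gene, class")
  names(df)[1:2] <- c("gene", "class")
  if (tolower(df$gene[1]) == "gene") df <- df[-1L, , drop = FALSE]
  cls <- tolower(df$class)
  if (!all(cls %in% c("induced", "repressed"))) {
    stop("signature class column must be 'induced' or 'repressed'")
  }
  gene_signature(induced = df$gene[cls == "induced"],
                 repressed = df$gene[cls == "repressed"])
}

#' Per-feature z-scores of a linear-scale expression matrix
#'
#' Applies `log2(x + 1)` then standardizes each feature (row) to mean 0 and
#' *population* standard deviation 1 (divisor n, matching the heatmap-style
#' standardization the partition is built on). Zero-variance features are set
#' to all-0 and flagged in the `"constant_features"` attribute.
#'
#' @param matrix Non-negative numeric matrix, features in rows, samples in
#'   columns. Set `log2 = FALSE` if the values are already on a log scale.
#' @param log2 Apply the `log2(x + 1)` transform first (default `TRUE`).
#' @return Matrix of z-scores with attributes `space = "zscore"` and
#'   `constant_features`.
#' @examples
#' zscore_features(rbind(g1 = c(0, 3)))
#' @export
zscore_features <- function(matrix, log2 = TRUE) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (!all(is.finite(matrix))) stop("expression values must be finite")
  if (log2) {
    if (any(matrix < 0)) {
      stop("negative values in a linear-scale expression matrix")
    }
    m <- base::log2(matrix + 1)
  } else {
    m <- matrix
  }
  mu <- rowMeans(m)
  centered <- m - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  constant <- sd_pop == 0
  z <- centered / ifelse(constant, 1, sd_pop)
  z[constant, ] <- 0
  attr(z, "space") <- "zscore"
  attr(z, "constant_features") <- rownames(m)[constant]
  z
}

.signature_rows <- function(z_matrix, signature) {
  stopifnot(inherits(signature, "gene_signature"))
  ind <- intersect(signature$induced, rownames(z_matrix))
  rep_ <- intersect(signature$repressed, rownames(z_matrix))
  missing <- setdiff(c(signature$induced, signature$repressed),
                     rownames(z_matrix))
  if (length(missing)) {
    message("signature genes absent from matrix: ",
            paste(missing, collapse = ", "))
  }
  if (!length(ind) || !length(rep_)) {
    stop("need at least one induced and one repressed signature gene in the ",
         "matrix; expected any of: ",
         paste(c(signature$induced, signature$repressed), collapse = ", "))
  }
  list(induced = ind, repressed = rep_)
}

#' Per-sample p53 transcription-activity score
#'
#' `score(s) = mean(z of induced genes in s) - mean(z of repressed genes in
#' s)`. Higher scores indicate transcription-competent (TC-like) samples:
#' p53 output genes up, p53-repressed mitotic genes down.
#'
#' @param z_matrix Z-scored matrix from [zscore_features()].
#' @param signature A [gene_signature()]; genes missing from the matrix are
#'   reported via `message()`.
#' @return Named numeric vector of per-sample scores.
#' @export
p53_activity_score <- function(z_matrix, signature) {
  rows <- .signature_rows(z_matrix, signature)
  colMeans(z_matrix[rows$induced, , drop = FALSE]) -
    colMeans(z_matrix[rows$repressed, , drop = FALSE])
}

#' Partition a cohort into p53-TC and p53-TI groups
#'
#' `method = "cluster"` (default): agglomerative hierarchical clustering
#' (Ward linkage on Euclidean distances) of samples over the z-scored
#' signature genes, cut at k = 2; the cluster with the higher mean induced-
#' gene z-score is labelled TC. `method = "threshold"`: samples with
#' [p53_activity_score()] >= 0 are TC, the rest TI. Both rules make the
#' original visual two-cluster choice reproducible; the rule and parameters
#' are recorded in `method_record`.
#'
#' @param matrix Linear-scale expression matrix (features x samples).
#' @param signature A [gene_signature()].
#' @param method `"cluster"` or `"threshold"`.
#' @return A list of class `partition`: `labels` (named `"TC"`/`"TI"`),
#'   `scores`, `method_record`, and `degenerate` (`TRUE` when all samples are
#'   identical and only one label could be assigned).
#' @export
partition_tc_ti <- function(matrix, signature, method = c("cluster",
                                                          "threshold")) {
  method <- match.arg(method)
  stopifnot(is.matrix(matrix))
  if (ncol(matrix) < 4L) stop("need at least 4 samples to partition")
  z <- zscore_features(matrix)
  rows <- .signature_rows(z, signature)
  zsig <- z[c(rows$induced, rows$repressed), , drop = FALSE]
  scores <- p53_activity_score(z, signature)

  degenerate <- all(apply(zsig, 1, function(r) length(unique(r)) == 1L))
  if (degenerate) {
    warning("all samples identical over the signature; single-label ",
            "degenerate partition")
    labels <- stats::setNames(rep("TC", ncol(matrix)), colnames(matrix))
    return(structure(list(labels = labels, scores = scores,
                          method_record = paste0(method, "; degenerate"),
                          degenerate = TRUE),
                     class = "partition"))
  }

  if (method == "cluster") {
    hc <- stats::hclust(stats::dist(t(zsig)), method = "ward.D2")
    grp <- stats::cutree(hc, k = 2)
    mean_ind <- tapply(colMeans(z[rows$induced, , drop = FALSE]), grp, mean)
    tc_grp <- as.integer(names(which.max(mean_ind)))
    labels <- ifelse(grp == tc_grp, "TC", "TI")
    record <- "cluster: hclust ward.D2 on Euclidean distance over z-scored signature genes, k=2; TC = cluster with higher mean induced-gene z"
  } else {
    labels <- ifelse(scores >= 0, "TC", "TI")
    record <- "threshold: TC iff activity score (mean induced z - mean repressed z) >= 0"
  }
  labels <- stats::setNames(as.character(labels), colnames(matrix))
  structure(list(labels = labels, scores = scores, method_record = record,
                 degenerate = FALSE),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("<partition>", paste(names(table(x$labels)), table(x$labels),
                           sep = "=", collapse = ", "), "\n")
  cat("  method:", x$method_record, "\n")
  invisible(x)
}

#' Mann--Whitney U test (two-sided)
#'
#' U is computed from midranks. When the combined sample size is at most 12
#' and there are no ties, the two-sided p-value is exact, obtained by
#' enumerating all ways to assign the pooled ranks to group a and counting
#' arrangements with `|U - n_a n_b / 2|` at least as large as observed.
#' Otherwise the tie-corrected normal approximation is used, without
#' continuity correction (so U at its null mean gives p = 1 even with ties).
#'
#' @param a,b Numeric vectors, each non-empty.
#' @return A list with `U` (the U statistic of group `a`), `p` (two-sided),
#'   and `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (!all(is.finite(c(a, b)))) stop("values must be finite")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  has_ties <- anyDuplicated(pooled) > 0L

  if (n <= 12L && !has_ties) {
    combs <- utils::combn(n, na)
    Us <- colSums(base::matrix(seq_len(n)[combs], nrow = na)) -
      na * (na + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  list(U = U, p = p, method = method)
}

#' 10--90 percentile box-whisker summary
#'
#' Percentiles use linear interpolation (the inclusive convention,
#' `stats::quantile` type 7). Outliers are the values falling strictly
#' outside `[p10, p90]`, the whisker span of a 10--90 percentile box-whisker
#' plot.
#'
#' @param values Numeric vector with at least one finite value.
#' @return A list `p10`, `p25`, `p50`, `p75`, `p90`, `outliers`.
#' @examples
#' boxwhisker_stats(1:11)
#' @export
boxwhisker_stats <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("empty input")
  if (!all(is.finite(values))) stop("values must be finite")
  q <- stats::quantile(values, c(.10, .25, .50, .75, .90), type = 7,
                       names = FALSE)
  list(p10 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p90 = q[5],
       outliers = values[values < q[1] | values > q[5]])
}
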