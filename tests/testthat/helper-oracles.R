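# Independent brute-force oracles. These deliberately avoid the package's
# code paths (no reverse_complement(), no Biostrings): simple loops over
# substrings, so scanner results can be checked against exhaustive
# enumeration.

random_dna <- function(n, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(s, "")[[1]]
  paste(rev(unname(map[chars])), collapse = "")
}

# all even-length rc-palindromic substrings, looped one by one
oracle_palindromes <- function(s, min_len, max_len) {
  L <- nchar(s)
  out <- list()
  for (len in seq(min_len, max_len, by = 2)) {
    if (len > L) next
    for (start0 in 0:(L - len)) {
      sub <- substr(s, start0 + 1, start0 + len)
      if (grepl("[^ACGT]", sub)) next
      if (identical(oracle_revcomp(sub), sub)) {
        out[[length(out) + 1]] <- c(start = start0, len = len)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = numeric(0), len = numeric(0)))
  }
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$start, df$len), , drop = FALSE]
}

# IUPAC-aware sliding-window match counter; N in the window blocks the match
iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

oracle_box_hits <- function(s, pattern, max_mm = 0, both_strands = TRUE) {
  scan_one <- function(pat, strand) {
    L <- nchar(s); k <- nchar(pat)
    pchars <- strsplit(pat, "")[[1]]
    out <- list()
    if (k > L) return(out)
    for (start0 in 0:(L - k)) {
      win <- strsplit(substr(s, start0 + 1, start0 + k), "")[[1]]
      if (any(win == "N")) next
      mm <- sum(!mapply(function(w, p) w %in% iupac_sets[[p]], win, pchars))
      if (mm <= max_mm) {
        out[[length(out) + 1]] <- data.frame(start = start0, end = start0 + k,
                                             strand = strand, mismatches = mm)
      }
    }
    out
  }
  rows <- scan_one(pattern, "+")
  rcpat <- oracle_revcomp(pattern)
  if (both_strands && !identical(rcpat, pattern)) {
    rows <- c(rows, scan_one(rcpat, "-"))
  }
  if (!length(rows)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      strand = character(0), mismatches = numeric(0)))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# exact two-sided Mann-Whitney p by enumerating group-a rank assignments
oracle_mw_exact <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  ranks <- rank(c(a, b))
  U_obs <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  combs <- utils::combn(n, na)
  Us <- apply(combs, 2, function(idx) sum(ranks[idx]) - na * (na + 1) / 2)
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

# small deterministic cohort helpers used across files
small_cohort <- function(seed = 1, n = 20, delta = 2, shift = 2, rho = 0.8,
                         noise = 0.5) {
  simulate_expression_cohort(
    sim_config(seed = seed, n_samples = n, effect_size_delta = delta,
               c19mc_shift = shift, ligand_rho = rho, noise_sd = noise))
}
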