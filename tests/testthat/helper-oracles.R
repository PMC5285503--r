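# Independent oracles, deliberately written as plain brute force so they
# share no code with the implementation they check.

# best (and all) ungapped window scores by direct double loop
oracle_window_scores <- function(residues, profile) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  W <- profile$width
  L <- length(chars)
  if (L < W) return(numeric(0))
  vapply(seq_len(L - W + 1), function(o) {
    s <- 0
    for (j in seq_len(W)) {
      r <- chars[o + j - 1]
      s <- s + if (r %in% colnames(profile$score)) profile$score[j, r] else 0
    }
    s
  }, numeric(1))
}

# quadratic-space affine-gap global alignment score (gap of length k costs
# open + k * ext, the same convention as Biostrings::pairwiseAlignment)
oracle_nw_score <- function(a, b, open = 11, ext = 1) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  submat <- e$BLOSUM62
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in a gap in b (a consumed)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in a gap in a (b consumed)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                     Y[i - 1, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                     X[i, j - 1] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# brute-force hydropathy window means (centers only)
oracle_window_means <- function(residues, window) {
  kd <- hhkmine::KYTE_DOOLITTLE
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  v <- unname(kd[chars]); v[is.na(v)] <- 0
  half <- window %/% 2
  L <- length(v)
  centers <- (half + 1):(L - half)
  vapply(centers, function(c) mean(v[(c - half):(c + half)]), numeric(1))
}
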