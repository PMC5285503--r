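# Position-specific scoring matrices with empirical E-values.
#
# Profiles are built from small seed alignments, calibrated against random
# background sequences (Gumbel fitted to per-sequence maximum window scores
# by the method of moments), and used for ungapped sliding-window scans.
# Hits are retained at E < 1e-4 by default, the screening threshold the
# pipeline inherits from genome-mining practice.

EULER_GAMMA <- 0.5772156649015329

#' Read an aligned-FASTA seed alignment
#'
#' @param path Aligned FASTA; rows must have equal length, gaps as `-`.
#' @param family Family name; defaults to the file name stem.
#' @param source Free-text provenance tag.
#' @return An object of class `hhk_seed`.
#' @export
read_seed_alignment <- function(path, family = NULL, source = basename(path)) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2) abort("a seed alignment needs at least 2 rows",
                             class = "hhk_seed_error")
  rows <- str_to_upper(as.character(set))
  names(rows) <- sub("\\s.*$", "", names(set))
  new_seed(rows,
           family = family %||% sub("_seed.*$", "", basename(path)),
           source = source)
}

new_seed <- function(rows, family, source = "in-memory") {
  if (length(unique(nchar(rows))) != 1) {
    abort("seed alignment rows differ in length", class = "hhk_seed_error")
  }
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  if (!any(gap_frac < 0.5)) {
    abort("seed alignment has no column with < 50% gaps",
          class = "hhk_seed_error")
  }
  structure(list(family = family, rows = rows, matrix = mat,
                 source = source),
            class = "hhk_seed")
}

#' @export
print.hhk_seed <- function(x, ...) {
  cat(sprintf("<hhk_seed> %s: %d rows x %d columns (%s)\n",
              x$family, length(x$rows), ncol(x$matrix), x$source))
  invisible(x)
}

#' Build a log-odds profile (PSSM) from a seed alignment
#'
#' Match columns are the alignment columns with < 50% gaps. Per-column
#' residue counts receive a flat pseudocount, are normalized, divided by the
#' background composition (floored at 1e-4 and renormalized), and logged
#' base 2, giving scores in bits.
#'
#' The default background is the package's fixed Swiss-Prot-like
#' composition rather than the seed's own composition: the null model for
#' scanning whole proteomes must reflect the database being scanned, and a
#' composition-biased seed (e.g. a transmembrane domain with no tryptophan
#' at all) would otherwise hand absent residues absurd log-odds rewards.
#'
#' @param seed An `hhk_seed`.
#' @param pseudocount Flat pseudocount added to every residue count
#'   (default 0.5).
#' @param background Named background frequencies over the 20 residues.
#' @return An object of class `hhk_profile` (uncalibrated: no null model yet).
#' @export
build_profile <- function(seed, pseudocount = 0.5,
                          background = AA_BACKGROUND) {
  stopifnot(inherits(seed, "hhk_seed"), pseudocount > 0)
  mat <- seed$matrix
  gap_frac <- colMeans(mat == "-")
  match_cols <- which(gap_frac < 0.5)
  if (length(match_cols) < 5) {
    abort(sprintf("profile '%s' would have only %d match columns (minimum 5)",
                  seed$family, length(match_cols)),
          class = "hhk_profile_too_short")
  }
  bg <- background[AA_LETTERS]
  stopifnot(!anyNA(bg), all(bg > 0))
  bg <- pmax(bg / sum(bg), 1e-4)
  bg <- bg / sum(bg)
  names(bg) <- AA_LETTERS
  W <- length(match_cols)
  score <- matrix(0, nrow = W, ncol = 20,
                  dimnames = list(NULL, AA_LETTERS))
  for (j in seq_len(W)) {
    col <- mat[, match_cols[j]]
    counts <- table(factor(col[col %in% AA_LETTERS], levels = AA_LETTERS))
    freq <- (as.numeric(counts) + pseudocount) /
      (sum(counts) + 20 * pseudocount)
    score[j, ] <- log2(freq / bg)
  }
  consensus <- paste(AA_LETTERS[apply(score, 1, which.max)], collapse = "")
  structure(list(family = seed$family, width = W, match_cols = match_cols,
                 score = score, background = bg, consensus = consensus,
                 pseudocount = pseudocount, null = NULL),
            class = "hhk_profile")
}

#' @export
print.hhk_profile <- function(x, ...) {
  cat(sprintf("<hhk_profile> %s: width %d, %s\n", x$family, x$width,
              if (is.null(x$null)) "uncalibrated"
              else sprintf("Gumbel null (mu=%.2f, beta=%.2f, %d shuffles)",
                           x$null$mu, x$null$beta, x$null$n_shuffles)))
  invisible(x)
}

#' @rdname build_profile
#' @param x An `hhk_profile`.
#' @param ... Unused.
#' @export
tidy.hhk_profile <- function(x, ...) {
  as_tibble(x$score) |>
    mutate(column = dplyr::row_number(), .before = 1) |>
    mutate(consensus = strsplit(x$consensus, "")[[1]])
}

#' @export
glance.hhk_profile <- function(x, ...) {
  tibble(family = x$family, width = x$width,
         calibrated = !is.null(x$null),
         mu = x$null$mu %||% NA_real_, beta = x$null$beta %||% NA_real_)
}

# per-window PSSM scores at every offset of an index-encoded sequence;
# unknown residues (index 21) score 0 at any column
window_scores <- function(idx, score) {
  W <- nrow(score)
  L <- length(idx)
  n_off <- L - W + 1
  if (n_off < 1) return(numeric(0))
  padded <- cbind(score, X = 0)
  acc <- numeric(n_off)
  for (j in seq_len(W)) {
    acc <- acc + padded[j, idx[j:(j + n_off - 1)]]
  }
  unname(acc)
}

#' Calibrate a profile's null score model
#'
#' Draws random sequences from the profile background, records each
#' sequence's maximum window score, and fits a Gumbel distribution by the
#' method of moments. E-values reported by [scan_profile()] are derived from
#' this fit with a per-sequence window-count correction.
#'
#' @param profile An `hhk_profile`.
#' @param n_shuffles Number of random null sequences (minimum 200).
#' @param length Length of each null sequence (default 400).
#' @param seed Integer seed; calibration is deterministic given it.
#' @return The profile with its `null` slot populated.
#' @export
calibrate_null <- function(profile, n_shuffles = 500, length = 400, seed = 1L) {
  stopifnot(inherits(profile, "hhk_profile"))
  if (n_shuffles < 200) abort("n_shuffles must be >= 200",
                              class = "hhk_calibration_error")
  if (length < profile$width) abort("null sequence length below profile width",
                                    class = "hhk_calibration_error")
  maxima <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      idx <- sample.int(20, length, replace = TRUE, prob = profile$background)
      max(window_scores(idx, profile$score))
    }, numeric(1))
  })
  if (sd(maxima) == 0) {
    abort("degenerate null score distribution (variance 0)",
          class = "hhk_calibration_error")
  }
  beta <- sd(maxima) * sqrt(6) / pi
  mu <- mean(maxima) - EULER_GAMMA * beta
  profile$null <- list(mu = mu, beta = beta,
                       n_shuffles = n_shuffles,
                       shuffle_length = length,
                       n_windows = length - profile$width + 1,
                       seed = seed)
  profile
}

#' E-value of a bit score under a calibrated profile
#'
#' The expected number of windows at or above `score` in a query exposing
#' `n_windows` windows, from the calibrated Gumbel with a window-count
#' normalization relative to the calibration length.
#'
#' @param profile Calibrated `hhk_profile`.
#' @param score Bit score(s).
#' @param n_windows Number of windows in the query sequence.
#' @return E-value(s), strictly positive, strictly decreasing in `score`.
#' @export
profile_evalue <- function(profile, score, n_windows) {
  null <- profile$null
  if (is.null(null)) abort("profile is not calibrated",
                           class = "hhk_calibration_missing")
  (n_windows / null$n_windows) * exp(-(score - null$mu) / null$beta)
}

#' Scan proteins with one profile
#'
#' Ungapped sliding-window scoring at every offset. Offsets whose E-value is
#' below `e_max` are candidate hits; overlapping candidates are reduced to
#' the best-scoring one (ties to the leftmost window).
#'
#' @param proteins Protein record tibble ([read_fasta()]).
#' @param profile Calibrated `hhk_profile`.
#' @param e_max Retention threshold on the E-value (default 1e-4).
#' @return Tibble of hits: `protein_id`, `family`, `start`, `end`,
#'   `score`, `evalue`, sorted by protein then start.
#' @export
scan_profile <- function(proteins, profile, e_max = 1e-4) {
  stopifnot(inherits(profile, "hhk_profile"))
  null <- profile$null
  if (is.null(null)) abort("profile is not calibrated",
                           class = "hhk_calibration_missing")
  W <- profile$width
  res <- map(seq_len(nrow(proteins)), function(i) {
    L <- proteins$length[i]
    if (L < W) return(NULL)
    idx <- seq_to_index(proteins$residues[i])
    sc <- window_scores(idx, profile$score)
    m <- length(sc)
    # score at which E equals e_max for this query length
    s_min <- null$mu - null$beta * log(e_max * null$n_windows / m)
    cand <- which(sc >= s_min)
    if (length(cand) == 0) return(NULL)
    # best-score-wins overlap reduction, ties to the leftmost window
    ord <- cand[order(-sc[cand], cand)]
    kept <- integer(0)
    for (o in ord) {
      if (!any(abs(kept - o) < W)) kept <- c(kept, o)
    }
    kept <- sort(kept)
    tibble(protein_id = proteins$id[i], family = profile$family,
           start = kept, end = kept + W - 1L,
           score = sc[kept],
           evalue = profile_evalue(profile, sc[kept], m))
  })
  out <- list_rbind(keep(res, ~ !is.null(.x)))
  if (nrow(out) == 0) {
    return(tibble(protein_id = character(), family = character(),
                  start = integer(), end = integer(),
                  score = numeric(), evalue = numeric()))
  }
  arrange(out, .data$protein_id, .data$start)
}

#' Scan proteins with a set of profiles
#'
#' @param proteins Protein record tibble.
#' @param profiles A named list of calibrated profiles
#'   (see [hhk_profiles()]).
#' @param e_max Retention threshold on the E-value.
#' @return Hits tibble over all families, sorted by protein then start.
#' @export
scan_profiles <- function(proteins, profiles, e_max = 1e-4) {
  out <- list_rbind(map(profiles, ~ scan_profile(proteins, .x, e_max)))
  arrange(out, .data$protein_id, .data$start)
}

# ---- profile serialization (versioned TSV) ----

#' Serialize / restore a calibrated profile as TSV
#'
#' One row per match column with the 20 per-residue bit scores; background
#' and null-model parameters travel in `#`-prefixed header lines.
#'
#' @param profile An `hhk_profile`.
#' @param path Output path.
#' @return `path` invisibly; `read_profile_tsv()` returns the profile.
#' @export
write_profile_tsv <- function(profile, path) {
  hdr <- c(
    "# hhkmine profile v1",
    paste0("# family\t", profile$family),
    paste0("# pseudocount\t", format(profile$pseudocount, digits = 17)),
    paste0("# background\t",
           paste(format(profile$background, digits = 17), collapse = "\t"))
  )
  if (!is.null(profile$null)) {
    hdr <- c(hdr, paste0(
      "# null\t",
      paste(format(c(profile$null$mu, profile$null$beta,
                     profile$null$n_shuffles, profile$null$shuffle_length,
                     profile$null$n_windows, profile$null$seed),
                   digits = 17), collapse = "\t")))
  }
  body <- apply(profile$score, 1, function(r)
    paste(format(r, digits = 17), collapse = "\t"))
  writeLines(c(hdr, paste("column", paste(AA_LETTERS, collapse = "\t"),
                          sep = "\t"),
               paste(seq_len(profile$width), body, sep = "\t")), path)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# hhkmine profile")) {
    abort("not an hhkmine profile TSV", class = "hhk_io_error")
  }
  meta <- lines[startsWith(lines, "# ")]
  get <- function(key) {
    hit <- meta[startsWith(meta, paste0("# ", key, "\t"))]
    if (length(hit) == 0) return(NULL)
    strsplit(sub(paste0("^# ", key, "\t"), "", hit[1]), "\t")[[1]]
  }
  body <- lines[!startsWith(lines, "#")]
  tab <- read.delim(text = body, check.names = FALSE)
  score <- as.matrix(tab[, AA_LETTERS])
  dimnames(score) <- list(NULL, AA_LETTERS)
  bg <- as.numeric(get("background"))
  names(bg) <- AA_LETTERS
  null <- NULL
  nf <- get("null")
  if (!is.null(nf)) {
    nf <- as.numeric(nf)
    null <- list(mu = nf[1], beta = nf[2], n_shuffles = as.integer(nf[3]),
                 shuffle_length = as.integer(nf[4]),
                 n_windows = as.integer(nf[5]), seed = as.integer(nf[6]))
  }
  structure(list(family = get("family"), width = nrow(score),
                 match_cols = seq_len(nrow(score)), score = score,
                 background = bg,
                 consensus = paste(AA_LETTERS[apply(score, 1, which.max)],
                                   collapse = ""),
                 pseudocount = as.numeric(get("pseudocount")),
                 null = null),
            class = "hhk_profile")
}
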