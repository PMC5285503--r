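# Transmembrane helix prediction by Kyte-Doolittle hydropathy.
#
# A deterministic sliding-window scanner: maximal runs of window centers
# whose mean hydropathy exceeds the cutoff are expanded by half a window on
# each side, nearby runs are merged, and short runs are discarded.

#' Predict transmembrane helices from hydropathy
#'
#' Sliding mean of per-residue Kyte-Doolittle hydropathy (window default 19).
#' Runs of window centers above `cutoff` are expanded by `window %/% 2` on
#' each side and clipped to the sequence; runs separated by fewer than
#' `merge_gap` residues are merged; helices shorter than `min_length`
#' residues are discarded. Unknown residues contribute hydropathy 0.
#'
#' @param proteins Protein record tibble ([read_fasta()]).
#' @param window Odd window width (default 19).
#' @param cutoff Mean-hydropathy calling threshold (default 1.6).
#' @param min_length Minimum helix length in residues (default 15).
#' @param merge_gap Runs closer than this many residues are merged
#'   (default 5).
#' @return Tibble `protein_id`, `start`, `end`, `mean_hydropathy` (the peak
#'   window mean inside the helix, which is `>= cutoff` by construction),
#'   helices disjoint and sorted by start within each protein. Proteins
#'   shorter than `window` yield no rows.
#' @export
predict_tm <- function(proteins, window = 19, cutoff = 1.6,
                       min_length = 15, merge_gap = 5) {
  stopifnot(window %% 2 == 1, window > 0)
  half <- window %/% 2
  res <- map(seq_len(nrow(proteins)), function(i) {
    L <- proteins$length[i]
    if (L < window) {
      inform(sprintf("protein '%s' shorter than the hydropathy window; skipped",
                     proteins$id[i]))
      return(NULL)
    }
    kd <- kd_values(proteins$residues[i])
    means <- as.numeric(stats::filter(kd, rep(1 / window, window), sides = 2))
    centers <- which(!is.na(means) & means > cutoff)
    if (length(centers) == 0) return(NULL)
    runs <- split(centers, cumsum(c(1, diff(centers) != 1)))
    spans <- map(runs, function(r) {
      c(max(1L, min(r) - half), min(L, max(r) + half))
    })
    spans <- do.call(rbind, spans)
    # merge spans separated by < merge_gap residues
    merged <- list(spans[1, ])
    if (nrow(spans) > 1) {
      for (k in 2:nrow(spans)) {
        last <- merged[[length(merged)]]
        if (spans[k, 1] - last[2] - 1 < merge_gap) {
          merged[[length(merged)]] <- c(last[1], spans[k, 2])
        } else {
          merged[[length(merged) + 1]] <- spans[k, ]
        }
      }
    }
    merged <- do.call(rbind, merged)
    len <- merged[, 2] - merged[, 1] + 1
    merged <- merged[len >= min_length, , drop = FALSE]
    if (nrow(merged) == 0) return(NULL)
    peak <- vapply(seq_len(nrow(merged)), function(k) {
      inside <- centers[centers >= merged[k, 1] & centers <= merged[k, 2]]
      max(means[inside])
    }, numeric(1))
    tibble(protein_id = proteins$id[i],
           start = as.integer(merged[, 1]), end = as.integer(merged[, 2]),
           mean_hydropathy = peak)
  })
  out <- list_rbind(keep(res, ~ !is.null(.x)))
  if (nrow(out) == 0) {
    return(tibble(protein_id = character(), start = integer(),
                  end = integer(), mean_hydropathy = numeric()))
  }
  out
}

kd_values <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  v <- KYTE_DOOLITTLE[chars]
  v[is.na(v)] <- 0
  unname(v)
}
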