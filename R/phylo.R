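# Distance phylogeny of classified HHKs: center-star MSA over the
# HisKA+HATPase_c core, Poisson-corrected p-distances, neighbor joining
# (via ape), and column-resampling bootstrap supports.

#' Extract the concatenated kinase-core region of each protein
#'
#' Concatenates the residues of the first retained HisKA and HATPase_c hits
#' of each protein; proteins lacking either domain are dropped.
#'
#' @param features Assembled feature tibble.
#' @param proteins Protein record tibble.
#' @return Tibble `id`, `residues`.
#' @export
hhk_core_regions <- function(features, proteins) {
  rows <- map(seq_len(nrow(proteins)), function(i) {
    f <- features[features$protein_id == proteins$id[i] &
                    features$type == "domain", , drop = FALSE]
    hk <- f[f$family == "HisKA", , drop = FALSE]
    ha <- f[f$family == "HATPase_c", , drop = FALSE]
    if (nrow(hk) == 0 || nrow(ha) == 0) return(NULL)
    hk <- hk[which.min(hk$start), ]
    ha <- ha[which.min(ha$start), ]
    tibble(id = proteins$id[i],
           residues = paste0(
             substr(proteins$residues[i], hk$start, hk$end),
             substr(proteins$residues[i], ha$start, ha$end)))
  })
  list_rbind(keep(rows, ~ !is.null(.x)))
}

#' Center-star multiple alignment
#'
#' The center is the sequence maximizing the summed pairwise global
#' alignment score (ties to the lexicographically smallest id); all other
#' sequences are aligned to it and their gaps merged into common
#' coordinates. Deterministic.
#'
#' @param seqs Tibble with `id` and `residues`, or a named character vector.
#' @return An `hhk_msa`: a character matrix, rows named by sequence id.
#' @export
align_center_star <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$residues, seqs$id)
  n <- length(seqs)
  if (n < 3) abort("center-star alignment needs at least 3 sequences",
                   class = "hhk_too_few_taxa")
  ids <- names(seqs)
  total <- setNames(numeric(n), ids)
  pair_score <- function(a, b) {
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
      type = "global", scoreOnly = TRUE)
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- pair_score(seqs[[i]], seqs[[j]])
      total[i] <- total[i] + s
      total[j] <- total[j] + s
    }
  }
  center_id <- sort(ids[total == max(total)])[1]
  center <- seqs[[center_id]]
  Lc <- nchar(center)
  others <- ids[ids != center_id]
  # per-sequence slot contents: slot k holds residues inserted after center
  # position k (slot 0 before the first); match_char[k] is the residue (or
  # gap) aligned to center position k
  aligned <- map(others, function(id) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqs[[id]]), Biostrings::AAString(center),
      substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
      type = "global")
    pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    slots <- vector("list", Lc + 1)
    for (k in seq_len(Lc + 1)) slots[[k]] <- character(0)
    match_char <- character(Lc)
    k <- 0
    for (col in seq_along(pat)) {
      if (sub[col] == "-") {
        slots[[k + 1]] <- c(slots[[k + 1]], pat[col])
      } else {
        k <- k + 1
        match_char[k] <- pat[col]
      }
    }
    list(slots = slots, match_char = match_char)
  })
  names(aligned) <- others
  ins <- vapply(seq_len(Lc + 1), function(k) {
    if (length(aligned) == 0) return(0L)
    max(vapply(aligned, function(a) length(a$slots[[k]]), integer(1)))
  }, integer(1))
  build_row <- function(slots, match_char) {
    out <- character(0)
    for (k in 0:Lc) {
      s <- slots[[k + 1]]
      out <- c(out, s, rep("-", ins[k + 1] - length(s)))
      if (k < Lc) out <- c(out, match_char[k + 1])
    }
    out
  }
  center_row <- build_row(rep(list(character(0)), Lc + 1),
                          strsplit(center, "")[[1]])
  mat <- matrix("-", nrow = n, ncol = length(center_row),
                dimnames = list(ids, NULL))
  mat[center_id, ] <- center_row
  for (id in others) {
    mat[id, ] <- build_row(aligned[[id]]$slots, aligned[[id]]$match_char)
  }
  structure(mat, class = c("hhk_msa", "matrix", "array"))
}

#' Poisson-corrected distances from an alignment
#'
#' p-distance over columns where neither row has a gap, corrected as
#' `d = -ln(1 - p)`. Pairs with no shared columns, or saturated pairs
#' (`p = 1`), are an error naming the pair.
#'
#' @param msa An `hhk_msa` or plain character matrix with row names.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
hhk_distances <- function(msa) {
  mat <- unclass(msa)
  n <- nrow(mat)
  stopifnot(n >= 2)
  ids <- rownames(mat)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(shared)) {
        abort(sprintf("no comparable columns between '%s' and '%s'",
                      ids[i], ids[j]),
              class = "hhk_incomparable_pair")
      }
      p <- mean(mat[i, shared] != mat[j, shared])
      if (p >= 1) {
        abort(sprintf("saturated pair '%s'/'%s' (p = 1)", ids[i], ids[j]),
              class = "hhk_incomparable_pair")
      }
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining (via `ape::nj`), with negative branch-length
#' estimates clamped to zero (the clamped deficit is reported).
#'
#' @param d Symmetric distance matrix with labeled rows.
#' @return An unrooted `ape::phylo` tree.
#' @export
hhk_nj <- function(d) {
  if (!all(is.finite(d))) abort("non-finite distances",
                                class = "hhk_matrix_error")
  stopifnot(nrow(d) >= 3)
  tree <- ape::nj(as.dist(d))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    inform(sprintf("clamped %d negative NJ branch length(s), total deficit %.4g",
                   sum(neg), -sum(tree$edge.length[neg])))
  }
  # assignment (not pmax) so that negative zero also becomes +0
  tree$edge.length[tree$edge.length <= 0] <- 0
  tree
}

#' Bootstrap supports for the NJ tree of an alignment
#'
#' Resamples alignment columns with replacement, recomputes distances and
#' the NJ tree per replicate, and reports for each internal edge of the
#' full-alignment tree the percentage of replicates containing the same
#' bipartition. Replicates yielding an incomparable pair are skipped; more
#' than 20% skipped is an error.
#'
#' @param msa An `hhk_msa`.
#' @param n_reps Number of replicates (minimum 10, default 100).
#' @param seed Integer seed; supports are deterministic given it.
#' @return The NJ tree with `node.label` set to integer percent supports
#'   and a `supports` attribute.
#' @export
hhk_bootstrap <- function(msa, n_reps = 100, seed = 1L) {
  stopifnot(n_reps >= 10)
  mat <- unclass(msa)
  ref <- hhk_nj(hhk_distances(mat))
  reps <- withr::with_seed(seed, {
    map(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      tryCatch(hhk_nj(hhk_distances(mat[, cols, drop = FALSE])),
               hhk_incomparable_pair = function(e) NULL)
    })
  })
  ok <- !vapply(reps, is.null, logical(1))
  if (mean(!ok) > 0.2) {
    abort(sprintf("%d of %d bootstrap replicates were unusable",
                  sum(!ok), n_reps),
          class = "hhk_bootstrap_unstable")
  }
  trees <- reps[ok]
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(ref, trees, rooted = FALSE)
  supports <- round(100 * counts / length(trees))
  ref$node.label <- ifelse(is.na(supports), "", as.character(supports))
  attr(ref, "supports") <- supports
  ref
}

#' Newick output / input
#'
#' Bootstrap supports, when present, travel as internal node labels.
#'
#' @param tree An `ape::phylo`.
#' @param path File path.
#' @return `path` invisibly; `read_newick()` returns the tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
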