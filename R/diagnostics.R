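.hhk_cache <- new.env(parent = emptyenv())

# cached BLOSUM62 substitution matrix from Biostrings
blosum62 <- function() {
  if (is.null(.hhk_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .hhk_cache$blosum62 <- e$BLOSUM62
  }
  .hhk_cache$blosum62
}

# Residue-level receptor diagnostics.
#
# A candidate sensing region is aligned globally to a packaged reference
# (an EBD reference for ethylene, a CHASE reference for cytokinin),
# diagnostic reference positions are mapped through the alignment, and each
# is reported as conserved / similar / mismatch / gap. A candidate passes
# when at least `pass_threshold` of its non-gap diagnostic positions are
# conserved or similar.

#' Global pairwise alignment with a reference-position mapping
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps: open 11,
#' extend 1, as in `Biostrings::pairwiseAlignment`), returning, for every
#' reference position, the aligned candidate position or `NA` for a gap.
#'
#' @param candidate Candidate residue string (length >= 10).
#' @param reference Reference residue string (length >= 10).
#' @return List with `score` and `mapping`, a tibble `ref_pos`, `cand_pos`.
#' @export
align_global <- function(candidate, reference) {
  stopifnot(nchar(candidate) >= 10, nchar(reference) >= 10)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(candidate), Biostrings::AAString(reference),
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
    type = "global")
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ref_pos <- cumsum(sub != "-")
  cand_pos <- cumsum(pat != "-")
  keep <- sub != "-"
  mapping <- tibble(ref_pos = ref_pos[keep],
                    cand_pos = ifelse(pat[keep] == "-", NA_integer_,
                                      cand_pos[keep]))
  list(score = Biostrings::score(pa), mapping = mapping)
}

#' Load diagnostic sets and their reference sequences
#'
#' A diagnostic set names a reference protein, the region of it used for
#' alignment, and a list of diagnostic positions (absolute residue indices
#' on the reference) with their primary and allowed residues.
#'
#' @param set_path TSV with columns `set`, `reference_id`, `region_start`,
#'   `region_end`, `position`, `primary`, `allowed`, `weight`.
#' @param reference_path FASTA holding the reference proteins.
#' @return Named list of `hhk_diagnostic_set` objects (one per `set` value).
#' @export
read_diagnostic_sets <- function(set_path, reference_path) {
  tab <- as_tibble(read.delim(set_path, check.names = FALSE,
                              colClasses = c(allowed = "character")))
  refs <- read_fasta(reference_path, alphabet = "protein")
  sets <- map(split(tab, tab$set), function(s) {
    rid <- s$reference_id[1]
    ref <- refs$residues[refs$id == rid]
    if (length(ref) != 1) {
      abort(sprintf("reference '%s' not found in %s", rid, reference_path),
            class = "hhk_io_error")
    }
    pos <- s |>
      transmute(position = as.integer(.data$position),
                primary = .data$primary,
                allowed = .data$allowed,
                weight = as.numeric(.data$weight)) |>
      arrange(.data$position)
    stopifnot(all(diff(pos$position) > 0), all(nchar(pos$allowed) > 0))
    structure(list(name = s$set[1], reference_id = rid, reference = ref,
                   region_start = as.integer(s$region_start[1]),
                   region_end = as.integer(s$region_end[1]),
                   positions = pos),
              class = "hhk_diagnostic_set")
  })
  sets
}

#' @export
print.hhk_diagnostic_set <- function(x, ...) {
  cat(sprintf("<hhk_diagnostic_set> %s on %s [%d..%d], %d positions\n",
              x$name, x$reference_id, x$region_start, x$region_end,
              nrow(x$positions)))
  invisible(x)
}

#' Packaged receptor references and diagnostic sets
#'
#' Loads the packaged ethylene (EBD) and cytokinin (CHASE, with the
#' canonical threonine at reference position 301, allowed residues T/S)
#' diagnostic sets. Both reference proteins are constructed synthetic
#' stand-ins for AtETR1 and AtAHK4 (see the package vignette).
#'
#' @return List with elements `ethylene` and `cytokinin`.
#' @export
hhk_references <- function() {
  sets <- read_diagnostic_sets(
    system.file("extdata", "diagnostic_sets_synthetic.tsv",
                package = "hhkmine"),
    system.file("extdata", "references_synthetic.fasta",
                package = "hhkmine"))
  list(ethylene = sets[["ethylene"]], cytokinin = sets[["cytokinin"]])
}

#' Diagnose a candidate sensing region against a reference set
#'
#' Aligns the candidate region to the reference region and maps every
#' diagnostic position. A position is `conserved` when the candidate
#' residue equals the primary allowed residue, `similar` when it is in the
#' allowed set, `mismatch` otherwise, and `gap` when unaligned. The report
#' passes when the fraction of non-gap positions that are conserved or
#' similar reaches `pass_threshold`.
#'
#' @param candidate Candidate region residue string.
#' @param set An `hhk_diagnostic_set`.
#' @param pass_threshold Fraction of non-gap diagnostic positions that must
#'   be conserved or similar (default 0.8).
#' @param score_floor Minimum acceptable alignment score; below it the
#'   region is considered unalignable and no report is produced.
#' @return An `hhk_diagnosis`: a tibble `ref_pos`, `cand_pos`,
#'   `cand_residue`, `status`, with attributes `pass`, `fraction`, `score`.
#' @export
diagnose <- function(candidate, set, pass_threshold = 0.8,
                     score_floor = 50) {
  stopifnot(inherits(set, "hhk_diagnostic_set"))
  ref_region <- substr(set$reference, set$region_start, set$region_end)
  al <- align_global(candidate, ref_region)
  if (al$score < score_floor) {
    abort(sprintf("alignment score %.1f below floor %.1f for set '%s'",
                  al$score, score_floor, set$name),
          class = "hhk_unalignable_region")
  }
  rel <- set$positions$position - set$region_start + 1L
  cand_pos <- al$mapping$cand_pos[match(rel, al$mapping$ref_pos)]
  cand_res <- ifelse(is.na(cand_pos), NA_character_,
                     substring(candidate, cand_pos, cand_pos))
  primary <- substr(set$positions$primary, 1, 1)
  allowed <- strsplit(set$positions$allowed, "", fixed = TRUE)
  status <- map_chr(seq_along(cand_pos), function(k) {
    if (is.na(cand_pos[k])) return("gap")
    if (cand_res[k] == primary[k]) return("conserved")
    if (cand_res[k] %in% allowed[[k]]) return("similar")
    "mismatch"
  })
  out <- tibble(ref_pos = set$positions$position,
                cand_pos = cand_pos, cand_residue = cand_res,
                status = status)
  non_gap <- status != "gap"
  frac <- if (any(non_gap)) mean(status[non_gap] %in% c("conserved", "similar"))
          else 0
  structure(out, class = c("hhk_diagnosis", class(out)),
            pass = frac >= pass_threshold, fraction = frac,
            score = al$score, set = set$name)
}

#' @export
tidy.hhk_diagnosis <- function(x, ...) as_tibble(x)

#' @export
glance.hhk_diagnosis <- function(x, ...) {
  tibble(set = attr(x, "set"), pass = attr(x, "pass"),
         fraction = attr(x, "fraction"), score = attr(x, "score"))
}
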