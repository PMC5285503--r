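# FASTA input/output and CDS translation.
#
# Parsing and writing go through Biostrings; this layer adds the pipeline's
# record model (tibbles with id/description/residues), alphabet validation
# with positional error reporting, and CDS translation semantics.

PROTEIN_ALPHABET <- c(AA_LETTERS, "X")
NUCLEOTIDE_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a FASTA file into a tibble of records
#'
#' Headers are split into an `id` (first whitespace-delimited token) and a
#' free-text `description`. Sequences are uppercased on read; for nucleotide
#' input `U` is converted to `T`; a single trailing translation-stop `*` on a
#' protein sequence is stripped and never stored.
#'
#' @param path Path to a FASTA file (may be wrapped at any column width).
#' @param alphabet `"protein"` (20 letters plus `X`) or `"nucleotide"`
#'   (`ACGTN`).
#' @return A tibble with columns `id`, `description`, `residues`, `length`,
#'   one row per record, in file order.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "hhk_io_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("could not parse FASTA file ", path, ": ",
                   conditionMessage(e)),
            class = "hhk_empty_input")
    }
  )
  if (length(set) == 0) {
    abort(paste0("empty FASTA input: ", path), class = "hhk_empty_input")
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- str_to_upper(as.character(set))
  if (alphabet == "nucleotide") seqs <- gsub("U", "T", seqs, fixed = TRUE)
  # one trailing stop symbol is tolerated on proteins and stripped
  if (alphabet == "protein") seqs <- sub("\\*$", "", seqs)
  allowed <- if (alphabet == "protein") PROTEIN_ALPHABET else NUCLEOTIDE_ALPHABET
  pattern <- paste0("[^", paste(allowed, collapse = ""), "]")
  bad <- regexpr(pattern, seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    abort(
      sprintf("record '%s': character '%s' at position %d is not in the %s alphabet",
              ids[i], substr(seqs[i], bad[i], bad[i]), bad[i], alphabet),
      class = "hhk_alphabet_error"
    )
  }
  if (any(nchar(seqs) == 0)) {
    i <- which(nchar(seqs) == 0)[1]
    abort(sprintf("record '%s' has an empty sequence", ids[i]),
          class = "hhk_empty_input")
  }
  if (anyDuplicated(ids)) {
    inform(paste0("duplicate record ids in ", path, ": ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  tibble(id = ids, description = desc, residues = seqs,
         length = nchar(seqs))
}

#' Write records to a wrapped FASTA file
#'
#' @param records Tibble with at least `id` and `residues`; an optional
#'   `description` column is appended to the header after a space.
#' @param path Output path.
#' @param width Wrap column (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    abort("no records to write", class = "hhk_empty_input")
  }
  headers <- records$id
  if ("description" %in% names(records)) {
    has_desc <- !is.na(records$description) & nzchar(records$description)
    headers[has_desc] <- paste(records$id[has_desc],
                               records$description[has_desc])
  }
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- headers
  ok <- tryCatch({
    Biostrings::writeXStringSet(set, filepath = path, width = width)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(paste0("cannot write FASTA to ", path), class = "hhk_io_error")
  invisible(path)
}

#' Translate CDS records to protein
#'
#' Standard genetic code only; translation stops at the first stop codon;
#' trailing bases that do not fill a codon are dropped with a warning; any
#' codon containing `N` translates to `X`.
#'
#' @param records Nucleotide tibble as returned by
#'   `read_fasta(..., alphabet = "nucleotide")`.
#' @param frame Reading frame, 1, 2 or 3.
#' @return A protein record tibble (`id`, `description`, `residues`, `length`).
#' @export
translate_cds <- function(records, frame = 1) {
  stopifnot(frame %in% 1:3)
  code <- Biostrings::GENETIC_CODE
  out <- vapply(seq_len(nrow(records)), function(i) {
    bases <- substr(records$residues[i], frame, nchar(records$residues[i]))
    n_cod <- nchar(bases) %/% 3
    if (n_cod == 0) {
      abort(sprintf("record '%s': no complete codon in frame %d",
                    records$id[i], frame),
            class = "hhk_empty_translation")
    }
    if (nchar(bases) %% 3 != 0) {
      warn(sprintf("record '%s': %d trailing base(s) dropped",
                   records$id[i], nchar(bases) %% 3))
    }
    codons <- substring(bases, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"   # N-containing or otherwise ambiguous codons
    stop_at <- which(aa == "*")
    if (length(stop_at)) {
      if (stop_at[1] == 1) {
        abort(sprintf("record '%s': translation stops at the first codon",
                      records$id[i]),
              class = "hhk_empty_translation")
      }
      aa <- aa[seq_len(stop_at[1] - 1)]
    }
    paste(aa, collapse = "")
  }, character(1))
  tibble(id = records$id,
         description = if ("description" %in% names(records)) records$description else "",
         residues = out,
         length = nchar(out))
}
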