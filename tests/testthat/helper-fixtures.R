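# Shared fixtures: the packaged profile set is calibrated once per test run.

.test_cache <- new.env(parent = emptyenv())

cached_profiles <- function() {
  if (is.null(.test_cache$profiles)) {
    .test_cache$profiles <- hhk_profiles(seed = 421L)
  }
  .test_cache$profiles
}

cached_references <- function() {
  if (is.null(.test_cache$references)) {
    .test_cache$references <- hhk_references()
  }
  .test_cache$references
}

protein_tbl <- function(residues, id = paste0("p", seq_along(residues))) {
  tibble::tibble(id = id, description = "", residues = residues,
                 length = nchar(residues))
}

random_protein <- function(len, seed) {
  withr::with_seed(seed, {
    paste(sample(hhkmine::AA_LETTERS, len, replace = TRUE), collapse = "")
  })
}
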