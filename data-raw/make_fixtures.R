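# Regenerates the packaged synthetic fixtures (seed alignments, receptor
# references, diagnostic sets). Run from the repository root:
#   Rscript data-raw/make_fixtures.R
devtools::load_all(".", quiet = TRUE)

seed_dir <- file.path("inst", "extdata", "seeds")
dir.create(seed_dir, recursive = TRUE, showWarnings = FALSE)

bank <- synthetic_seed_bank()
for (fam in names(bank)) {
  rows <- bank[[fam]]$rows
  write_fasta(tibble::tibble(id = names(rows), description = "",
                             residues = unname(rows)),
              file.path(seed_dir, paste0(fam, "_seed_synthetic.afa")))
}

profiles <- hhk_profiles(calibrate = FALSE)
bundle <- make_reference_bundle(profiles)
write_fasta(bundle$references,
            file.path("inst", "extdata", "references_synthetic.fasta"))
write_tsv_report(bundle$sets,
                 file.path("inst", "extdata", "diagnostic_sets_synthetic.tsv"))
cat("fixtures written\n")
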