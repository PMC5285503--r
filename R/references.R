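# Construction of the packaged receptor references.
#
# Real AtETR1/AtAHK4 sequences are not bundled; instead the package ships
# synthetic stand-ins assembled from the synthetic profile consensus
# sequences, with the canonical CHASE threonine placed at reference
# position 301 (the residue numbering convention the cytokinin diagnostics
# use). The fixtures under inst/extdata are exactly the output of
# `make_reference_bundle()` on the packaged profiles.

#' Build the synthetic receptor reference bundle
#'
#' Assembles the two reference proteins (`AtETR1_synthetic`: EBD + GAF +
#' hybrid core; `AtAHK4_synthetic`: TM-flanked CHASE + hybrid core with the
#' diagnostic threonine at position 301) and their diagnostic-position
#' tables from profile consensus sequences. Deterministic.
#'
#' @param profiles Profile set ([hhk_profiles()]; calibration not needed).
#' @param seed Seed for the linker/TM filler residues.
#' @return List with `references` (protein record tibble) and `sets`
#'   (diagnostic-set table as written to
#'   `inst/extdata/diagnostic_sets_synthetic.tsv`).
#' @export
make_reference_bundle <- function(profiles, seed = SEED_BANK_SEED + 999L) {
  cons <- function(fam) profiles[[fam]]$consensus
  allowed_for <- function(res) {
    partner <- AA_SIMILAR[res]
    ifelse(partner == res, res, paste0(res, partner))
  }
  withr::with_seed(seed, {
    lnk <- function(n) sample_residues(n, LINKER_ALPHABET)
    tm21 <- function() sample_residues(21, TM_ALPHABET)

    # ethylene reference: EBD at 11..133 so diagnostic EBD columns map to
    # fixed absolute positions
    etr1 <- paste0(lnk(10), cons("EBD"), lnk(30), cons("GAF"), lnk(30),
                   cons("HisKA"), lnk(30), cons("HATPase_c"), lnk(30),
                   cons("REC"), lnk(10))
    ebd_diag <- SEED_BANK_SPEC$EBD$diag
    ebd_start <- 11L
    ebd_end <- ebd_start + SEED_BANK_SPEC$EBD$width - 1L
    eth_sets <- tibble(
      set = "ethylene", reference_id = "AtETR1_synthetic",
      region_start = max(1L, ebd_start - 30L),
      region_end = ebd_end + 30L,
      position = ebd_start - 1L + as.integer(names(ebd_diag)),
      primary = unname(ebd_diag),
      allowed = allowed_for(unname(ebd_diag)),
      weight = 1)

    # cytokinin reference: CHASE at 126..315, placing the conserved
    # threonine (CHASE column 176) at absolute position 301
    ahk4 <- paste0(lnk(95), tm21(), lnk(9), cons("CHASE"), lnk(10), tm21(),
                   lnk(30), cons("HisKA"), lnk(30), cons("HATPase_c"),
                   lnk(30), cons("REC"), lnk(10))
    chase_diag <- SEED_BANK_SPEC$CHASE$diag
    chase_start <- 126L
    chase_end <- chase_start + SEED_BANK_SPEC$CHASE$width - 1L
    cyt_sets <- tibble(
      set = "cytokinin", reference_id = "AtAHK4_synthetic",
      region_start = chase_start - 30L,
      region_end = chase_end + 30L,
      position = chase_start - 1L + as.integer(names(chase_diag)),
      primary = unname(chase_diag),
      allowed = allowed_for(unname(chase_diag)),
      weight = 1)

    refs <- tibble(
      id = c("AtETR1_synthetic", "AtAHK4_synthetic"),
      description = c(
        "synthetic ethylene-receptor reference (EBD+GAF+hybrid core)",
        "synthetic cytokinin-receptor reference (TM-CHASE-TM+hybrid core)"),
      residues = c(etr1, ahk4),
      length = c(nchar(etr1), nchar(ahk4)))
    list(references = refs, sets = bind_rows(eth_sets, cyt_sets))
  })
}
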