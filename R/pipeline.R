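# Pipeline configuration and the end-to-end driver.

#' Pipeline configuration
#'
#' All tunable thresholds of the pipeline in one validated list. Defaults:
#' profile-hit retention at E < 1e-4; hydropathy window 19 with cutoff 1.6
#' (Kyte-Doolittle units); EBD inter-helix gap at most 40 residues; CHASE
#' flanking-helix windows of 60 residues; diagnostic pass threshold 0.8;
#' 100 bootstrap replicates.
#'
#' @param e_max Profile-hit E-value retention threshold.
#' @param tm_window,tm_cutoff Hydropathy window (odd) and calling cutoff.
#' @param ebd_max_gap Maximum gap between EBD member helices (residues).
#' @param chase_flank CHASE flanking-helix window (residues).
#' @param diag_threshold Diagnostic pass threshold (fraction of non-gap
#'   positions conserved or similar).
#' @param diag_score_floor Minimum acceptable diagnostic alignment score.
#' @param bootstrap_reps Bootstrap replicates for [hhk_tree()].
#' @param seed Default seed for the pipeline's stochastic stages.
#' @return An `hhk_config` list.
#' @export
hhk_config <- function(e_max = 1e-4, tm_window = 19, tm_cutoff = 1.6,
                       ebd_max_gap = 40, chase_flank = 60,
                       diag_threshold = 0.8, diag_score_floor = 50,
                       bootstrap_reps = 100, seed = 1L) {
  cfg <- list(e_max = e_max, tm_window = tm_window, tm_cutoff = tm_cutoff,
              ebd_max_gap = ebd_max_gap, chase_flank = chase_flank,
              diag_threshold = diag_threshold,
              diag_score_floor = diag_score_floor,
              bootstrap_reps = bootstrap_reps, seed = as.integer(seed))
  num <- cfg[setdiff(names(cfg), "seed")]
  stopifnot(all(vapply(num, function(v) is.numeric(v) && v > 0, logical(1))),
            cfg$tm_window %% 2 == 1, cfg$diag_threshold <= 1)
  structure(cfg, class = "hhk_config")
}

#' @export
print.hhk_config <- function(x, ...) {
  cat("<hhk_config>\n")
  for (k in names(x)) cat(sprintf("  %-16s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Scan a protein set for domains and TM helices
#'
#' @param proteins Protein record tibble.
#' @param profiles Calibrated profile set ([hhk_profiles()]).
#' @param config Pipeline configuration.
#' @return List with `hits` and `helices` tibbles.
#' @export
hhk_scan <- function(proteins, profiles, config = hhk_config()) {
  hits <- scan_profiles(proteins, profiles, e_max = config$e_max)
  helices <- predict_tm(proteins, window = config$tm_window,
                        cutoff = config$tm_cutoff)
  list(hits = hits, helices = helices)
}

#' Run the full mining pipeline
#'
#' Profile scan, TM prediction, architecture assembly, grammar
#' classification with residue diagnostics, and the group census.
#'
#' @param proteins Protein record tibble ([read_fasta()]).
#' @param profiles Calibrated profile set; built from the packaged seeds
#'   when `NULL`.
#' @param diagnostics Diagnostic bundle ([hhk_references()]), or `NULL` to
#'   classify on geometry alone.
#' @param catalog Group catalog for the census ([dikarya_catalog()]).
#' @param config Pipeline configuration.
#' @return An `hhk_result` with elements `proteins`, `hits`, `helices`,
#'   `features`, `classes`, `census`, `config`.
#' @export
run_hhk_pipeline <- function(proteins, profiles = NULL,
                             diagnostics = hhk_references(),
                             catalog = dikarya_catalog(),
                             config = hhk_config()) {
  if (is.null(profiles)) profiles <- hhk_profiles(seed = config$seed)
  scan <- hhk_scan(proteins, profiles, config)
  features <- assemble_architectures(scan$hits, scan$helices, proteins)
  classes <- classify_architectures(features, proteins, diagnostics, config)
  census <- census_hhk(classes, catalog)
  structure(list(proteins = proteins, hits = scan$hits,
                 helices = scan$helices, features = features,
                 classes = classes, census = census, config = config),
            class = "hhk_result")
}

#' @export
print.hhk_result <- function(x, ...) {
  cat(sprintf("<hhk_result> %d proteins, %d domain hits, %d TM helices\n",
              nrow(x$proteins), nrow(x$hits), nrow(x$helices)))
  print(count(x$classes, .data$label))
  invisible(x)
}

#' @rdname run_hhk_pipeline
#' @param x An `hhk_result`.
#' @param ... Unused.
#' @export
tidy.hhk_result <- function(x, ...) x$classes

#' @export
glance.hhk_result <- function(x, ...) {
  tibble(n_proteins = nrow(x$proteins),
         n_hhk = sum(x$classes$label != "not-HHK"),
         n_ethylene = sum(x$classes$label == "ethylene-receptor-like"),
         n_cytokinin = sum(x$classes$label == "cytokinin-receptor-like"),
         groups_present = sum(x$census$groups_present$groups_present))
}

#' Bootstrap NJ tree of the classified HHKs
#'
#' Builds a center-star alignment of the concatenated HisKA+HATPase_c
#' regions of all proteins classified as HHKs (any label but `not-HHK`),
#' then the neighbor-joining tree with column-bootstrap supports.
#'
#' @param result An `hhk_result`.
#' @param n_reps Bootstrap replicates (default from the result's config).
#' @param seed Bootstrap seed (default from the result's config).
#' @return An `ape::phylo` with percent supports as node labels.
#' @export
hhk_tree <- function(result, n_reps = NULL, seed = NULL) {
  stopifnot(inherits(result, "hhk_result"))
  keep_ids <- result$classes$protein_id[result$classes$label != "not-HHK"]
  prot <- result$proteins[result$proteins$id %in% keep_ids, , drop = FALSE]
  cores <- hhk_core_regions(result$features, prot)
  if (nrow(cores) < 3) {
    abort("need at least 3 classified HHKs with a HisKA+HATPase_c core",
          class = "hhk_too_few_taxa")
  }
  msa <- align_center_star(cores)
  hhk_bootstrap(msa, n_reps = n_reps %||% result$config$bootstrap_reps,
                seed = seed %||% result$config$seed)
}

#' Write a pipeline table as TSV
#'
#' Plain tab-separated output with a header row, the exchange format of all
#' tabular reports (hits, helices, features, classes, census, truth).
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path` invisibly; `read_tsv_report()` returns a tibble.
#' @export
write_tsv_report <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_tsv_report
#' @export
read_tsv_report <- function(path) {
  as_tibble(utils::read.delim(path, check.names = FALSE))
}
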