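# Synthetic proteomes with planted, ground-truth HHK architectures.
#
# Everything here is deterministic given a seed. Planted proteins
# concatenate, in a class's canonical order, the consensus strings of the
# packaged profiles (domains), hydrophobic 21-mers (TM helices), and
# disorder-biased linkers, then apply i.i.d. substitutions at a configurable
# rate. Decoys are background-only, REC-only and TM-only proteins. The seed
# alignments the profiles are built from are themselves synthetic: small
# families simulated as a conserved ancestral consensus plus per-row noise,
# with designated diagnostic columns held invariant.

SEED_BANK_SEED <- 20260915L

# family layout of the synthetic seed bank: alignment width, transmembrane
# column blocks, hydrophilic loop blocks, and strictly conserved diagnostic
# columns (named by column, value = residue)
SEED_BANK_SPEC <- list(
  HisKA = list(width = 66L),
  HATPase_c = list(width = 110L),
  REC = list(width = 112L),
  GAF = list(width = 140L),
  PAS = list(width = 70L),
  HAMP = list(width = 50L),
  CHASE = list(width = 190L,
               diag = c(`30` = "F", `58` = "G", `92` = "D", `120` = "R",
                        `151` = "P", `176` = "T", `185` = "W")),
  PHY = list(width = 100L),
  EBD = list(width = 123L,
             tm = list(c(1L, 21L), c(52L, 72L), c(103L, 123L)),
             loops = list(c(22L, 51L), c(73L, 102L)),
             diag = c(`8` = "F", `15` = "I", `57` = "C", `61` = "H",
                      `108` = "Y", `115` = "L"))
)

in_blocks <- function(pos, blocks) {
  if (is.null(blocks)) return(rep(FALSE, length(pos)))
  Reduce(`|`, lapply(blocks, function(b) pos >= b[1] & pos <= b[2]))
}

#' Simulate one synthetic seed alignment
#'
#' An ancestral consensus is drawn position-wise (hydrophobic residues in
#' transmembrane blocks, disorder-biased residues in loop blocks, background
#' elsewhere; diagnostic columns are fixed), then each row receives i.i.d.
#' substitutions and sparse gaps. Diagnostic columns are never mutated.
#'
#' @param family One of the families in the packaged seed bank
#'   (HisKA, HATPase_c, REC, GAF, PAS, HAMP, CHASE, PHY, EBD).
#' @param n_rows Number of rows (default 12).
#' @param sub_rate Per-position substitution rate per row (default 0.15).
#' @param gap_rate Per-position gap rate per row (default 0.02).
#' @param seed Integer seed.
#' @return An `hhk_seed`.
#' @export
simulate_seed_alignment <- function(family, n_rows = 12, sub_rate = 0.15,
                                    gap_rate = 0.02, seed = SEED_BANK_SEED) {
  spec <- SEED_BANK_SPEC[[family]]
  if (is.null(spec)) abort(paste0("unknown seed family: ", family),
                           class = "hhk_spec_error")
  W <- spec$width
  pos <- seq_len(W)
  tm <- in_blocks(pos, spec$tm)
  loop <- in_blocks(pos, spec$loops)
  diag_pos <- as.integer(names(spec$diag %||% character(0)))
  withr::with_seed(seed, {
    anc <- character(W)
    anc[!tm & !loop] <- sample(names(AA_BACKGROUND), sum(!tm & !loop),
                               replace = TRUE, prob = AA_BACKGROUND)
    if (any(tm)) anc[tm] <- sample(names(TM_ALPHABET), sum(tm),
                                   replace = TRUE, prob = TM_ALPHABET)
    if (any(loop)) anc[loop] <- sample(names(LINKER_ALPHABET), sum(loop),
                                       replace = TRUE, prob = LINKER_ALPHABET)
    anc[diag_pos] <- unname(spec$diag)
    rows <- vapply(seq_len(n_rows), function(r) {
      row <- anc
      free <- setdiff(pos, diag_pos)
      mut <- free[runif(length(free)) < sub_rate]
      if (length(mut)) {
        tm_mut <- mut[tm[mut]]
        other <- setdiff(mut, tm_mut)
        if (length(tm_mut)) {
          row[tm_mut] <- sample(names(TM_ALPHABET), length(tm_mut),
                                replace = TRUE, prob = TM_ALPHABET)
        }
        if (length(other)) {
          row[other] <- sample(names(AA_BACKGROUND), length(other),
                               replace = TRUE, prob = AA_BACKGROUND)
        }
      }
      gap <- free[runif(length(free)) < gap_rate]
      row[gap] <- "-"
      paste(row, collapse = "")
    }, character(1))
    names(rows) <- sprintf("%s_syn_%02d", family, seq_len(n_rows))
    new_seed(rows, family = family,
             source = sprintf("synthetic seed bank (seed %d)", seed))
  })
}

#' The packaged synthetic seed bank
#'
#' All nine family seed alignments, regenerated deterministically. The
#' shipped `inst/extdata/seeds/*_seed_synthetic.afa` fixtures are exactly
#' these alignments.
#'
#' @param seed Master seed (each family derives its own from it).
#' @return Named list of `hhk_seed` objects.
#' @export
synthetic_seed_bank <- function(seed = SEED_BANK_SEED) {
  fams <- names(SEED_BANK_SPEC)
  setNames(lapply(seq_along(fams), function(i) {
    simulate_seed_alignment(fams[i], seed = seed + i)
  }), fams)
}

#' Build (and calibrate) the packaged profile set
#'
#' Reads the packaged synthetic seed alignments, builds one PSSM per family
#' and calibrates each null model against random background sequences.
#'
#' @param calibrate Calibrate the null models (needed for scanning).
#' @param n_shuffles,length Calibration settings, see [calibrate_null()].
#' @param seed Base seed for calibration (each family derives its own).
#' @param pseudocount Profile pseudocount.
#' @return Named list of `hhk_profile` objects.
#' @export
hhk_profiles <- function(calibrate = TRUE, n_shuffles = 500, length = 400,
                         seed = 1903L, pseudocount = 0.5) {
  dir <- system.file("extdata", "seeds", package = "hhkmine")
  files <- list.files(dir, pattern = "_seed_synthetic\\.afa$",
                      full.names = TRUE)
  seeds <- lapply(files, function(f) {
    read_seed_alignment(f, family = sub("_seed_synthetic\\.afa$", "",
                                        basename(f)))
  })
  names(seeds) <- vapply(seeds, function(s) s$family, character(1))
  seeds <- seeds[intersect(names(SEED_BANK_SPEC), names(seeds))]
  profs <- lapply(seeds, build_profile, pseudocount = pseudocount)
  if (calibrate) {
    profs <- lapply(seq_along(profs), function(i) {
      calibrate_null(profs[[i]], n_shuffles = n_shuffles, length = length,
                     seed = seed + i)
    })
    names(profs) <- vapply(profs, function(p) p$family, character(1))
  }
  profs
}

# ---- planted architectures ----

CORE_LAYOUT <- list(list(kind = "domain", family = "HisKA"),
                    list(kind = "domain", family = "HATPase_c"),
                    list(kind = "domain", family = "REC"))

synth_layout <- function(class) {
  d <- function(f) list(list(kind = "domain", family = f))
  tm <- list(list(kind = "tm"))
  switch_ok <- switch(
    class,
    "canonical" = CORE_LAYOUT,
    "ethylene-sf1" = c(d("EBD"), d("GAF"), CORE_LAYOUT),
    "ethylene-sf2" = c(tm, d("EBD"), d("GAF"), CORE_LAYOUT),
    "ethylene-truncated" = c(d("EBD"), d("GAF"), d("HisKA")),
    "cytokinin" = c(tm, d("CHASE"), tm, CORE_LAYOUT),
    "phytochrome" = c(d("PAS"), d("GAF"), d("PHY"), CORE_LAYOUT),
    "dual" = c(CORE_LAYOUT, CORE_LAYOUT),
    "group-iii" = c(d("HAMP"), d("HAMP"), d("HAMP"), d("HAMP"), d("HAMP"),
                    CORE_LAYOUT),
    "decoy-background" = list(list(kind = "background")),
    "decoy-rec" = d("REC"),
    "decoy-tm" = c(tm, tm, tm),
    NULL)
  if (!is.null(switch_ok)) return(switch_ok)
  if (startsWith(class, "sensor:")) {
    fams <- strsplit(sub("^sensor:", "", class), "-", fixed = TRUE)[[1]]
    if (!all(fams %in% c("GAF", "PAS", "HAMP", "PHY"))) {
      abort(paste0("unknown sensing family in class: ", class),
            class = "hhk_spec_error")
    }
    return(c(unlist(lapply(fams, d), recursive = FALSE), CORE_LAYOUT))
  }
  abort(paste0("unknown planted class label: ", class),
        class = "hhk_spec_error")
}

synth_truth_label <- function(class) {
  eth <- function(sf, tr) list(label = "ethylene-receptor-like",
                               subfamily = sf, truncation = tr)
  other <- function(comp) list(label = "HHK-other", subfamily = "none",
                               truncation = "none", composition = comp)
  base <- switch(
    class,
    "canonical" = other("none"),
    "ethylene-sf1" = eth("1", "none"),
    "ethylene-sf2" = eth("2", "none"),
    "ethylene-truncated" = eth("1", "HATPase-and-REC-missing"),
    "cytokinin" = list(label = "cytokinin-receptor-like"),
    "phytochrome" = list(label = "phytochrome-VIII-Fph"),
    "dual" = list(label = "dual-HHK"),
    "group-iii" = list(label = "group-III"),
    "decoy-background" = ,
    "decoy-rec" = ,
    "decoy-tm" = list(label = "not-HHK"),
    NULL)
  if (is.null(base) && startsWith(class, "sensor:")) {
    base <- other(sub("^sensor:", "", class))
  }
  if (is.null(base)) abort(paste0("unknown planted class label: ", class),
                           class = "hhk_spec_error")
  list(label = base$label,
       subfamily = base$subfamily %||% "none",
       truncation = base$truncation %||% "none",
       composition = base$composition %||% NA_character_)
}

#' Class-ancestor consensus of a domain family
#'
#' Each planted class descends from its own ancestral variant of a family:
#' the profile consensus carrying a deterministic set of substitutions at
#' `rate`, seeded by the class and family names. Diagnostic columns are
#' never touched (essential residues stay essential along a subfamily), and
#' transmembrane columns are re-drawn from the hydrophobic alphabet so the
#' ancestor remains membrane-like. This is what gives different planted
#' classes distinguishable kinase cores, and hence phylogenetic structure.
#'
#' @param profiles Profile set.
#' @param family Family name.
#' @param class Planted class label.
#' @param rate Ancestral substitution rate (default 0.15).
#' @return Residue string of the class ancestor.
#' @export
class_consensus <- function(profiles, family, class, rate = 0.15) {
  cons <- strsplit(profiles[[family]]$consensus, "", fixed = TRUE)[[1]]
  spec <- SEED_BANK_SPEC[[family]]
  diag_pos <- as.integer(names(spec$diag %||% character(0)))
  tm <- in_blocks(seq_along(cons), spec$tm)
  key <- utf8ToInt(paste(class, family))
  seed <- sum(key * seq_along(key)) %% 2147483647L
  withr::with_seed(as.integer(seed), {
    free <- setdiff(seq_along(cons), diag_pos)
    mut <- free[runif(length(free)) < rate]
    tm_mut <- mut[tm[mut]]
    other <- setdiff(mut, tm_mut)
    for (i in tm_mut) {
      cons[i] <- sample(setdiff(names(TM_ALPHABET), cons[i]), 1)
    }
    for (i in other) {
      cons[i] <- sample(setdiff(AA_LETTERS, cons[i]), 1)
    }
  })
  paste(cons, collapse = "")
}

# substitute each unprotected position with probability p_sub to a uniformly
# random *different* residue; runs in the caller's RNG stream
mutate_chars <- function(chars, p_sub, protected = integer(0)) {
  if (p_sub <= 0) return(chars)
  n <- length(chars)
  hit <- which(runif(n) < p_sub)
  hit <- setdiff(hit, protected)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA_LETTERS, chars[i]), 1)
  }
  chars
}

#' Mutate a sequence at a fixed substitution rate
#'
#' Each unprotected position is substituted with probability `p_sub` to a
#' uniformly random different residue. Deterministic given `seed`.
#'
#' @param residues Residue string.
#' @param p_sub Substitution probability per position, in `[0, 0.3]`.
#' @param protected Integer positions never altered.
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @return Mutated residue string.
#' @export
mutate_sequence <- function(residues, p_sub, protected = integer(0),
                            seed = NULL) {
  stopifnot(p_sub >= 0, p_sub <= 0.3)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  run <- function() paste(mutate_chars(chars, p_sub, protected),
                          collapse = "")
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

build_planted <- function(class, profiles, p_sub, linker_range) {
  layout <- synth_layout(class)
  lnk <- function() sample(linker_range[1]:linker_range[2], 1)
  chars <- character(0)
  feats <- list()
  protected <- integer(0)
  push <- function(block) c(chars, block)
  chars <- push(strsplit(sample_residues(lnk(), LINKER_ALPHABET), "")[[1]])
  for (el in layout) {
    at <- length(chars) + 1L
    if (el$kind == "domain") {
      cons <- strsplit(class_consensus(profiles, el$family, class),
                       "", fixed = TRUE)[[1]]
      chars <- push(cons)
      feats[[length(feats) + 1]] <-
        list(family = el$family, start = at, end = at + length(cons) - 1L)
      spec <- SEED_BANK_SPEC[[el$family]]
      if (!is.null(spec$diag)) {
        protected <- c(protected, at - 1L + as.integer(names(spec$diag)))
      }
      if (!is.null(spec$tm)) {
        for (b in spec$tm) {
          feats[[length(feats) + 1]] <-
            list(family = "TM", start = at - 1L + b[1], end = at - 1L + b[2])
        }
      }
    } else if (el$kind == "tm") {
      block <- strsplit(sample_residues(21, TM_ALPHABET), "")[[1]]
      chars <- push(block)
      feats[[length(feats) + 1]] <-
        list(family = "TM", start = at, end = at + 20L)
    } else {  # background decoy body
      chars <- push(strsplit(sample_residues(sample(300:600, 1)),
                             "")[[1]])
    }
    chars <- push(strsplit(sample_residues(lnk(), LINKER_ALPHABET), "")[[1]])
  }
  # diagnostic positions stay intact at low mutation rates so that residue
  # diagnostics remain meaningful; above 5% substitution everything is fair
  # game
  prot <- if (p_sub <= 0.05) protected else integer(0)
  chars <- mutate_chars(chars, p_sub, prot)
  list(residues = paste(chars, collapse = ""),
       features = list_rbind(map(feats, as_tibble)))
}

#' Generate a synthetic proteome with planted ground truth
#'
#' @param specs Tibble (or data frame) with columns `class`, `count` and
#'   optionally `p_sub` (default 0). Recognized classes: `canonical`,
#'   `ethylene-sf1`, `ethylene-sf2`, `ethylene-truncated`, `cytokinin`,
#'   `phytochrome`, `dual`, `group-iii`, `sensor:<FAM[-FAM...]>` (sensing
#'   prefix over GAF/PAS/HAMP/PHY), and the decoys `decoy-background`,
#'   `decoy-rec`, `decoy-tm`.
#' @param profiles Profile set supplying consensus strings
#'   ([hhk_profiles()]; calibration is not needed here).
#' @param seed Integer seed; output is fully deterministic given it.
#' @param linker_range Inter-element linker length range (default 30..40).
#' @return List with `proteins` (record tibble), `truth` (per-protein
#'   expected classification: `protein_id`, `class`, `label`, `subfamily`,
#'   `truncation`, `composition`) and `features` (planted coordinates:
#'   `protein_id`, `family`, `start`, `end`).
#' @export
synth_proteome <- function(specs, profiles, seed = 1L,
                           linker_range = c(30, 40)) {
  specs <- as_tibble(specs)
  if (!"p_sub" %in% names(specs)) specs$p_sub <- 0
  stopifnot(all(specs$count >= 0), all(specs$p_sub >= 0),
            all(specs$p_sub <= 0.3))
  if (sum(specs$count) < 1) abort("no proteins requested",
                                  class = "hhk_spec_error")
  withr::with_seed(seed, {
    proteins <- list(); truth <- list(); feats <- list()
    for (s in seq_len(nrow(specs))) {
      lab <- synth_truth_label(specs$class[s])  # validates the class early
      for (k in seq_len(specs$count[s])) {
        id <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]+", "_", specs$class[s]), k)
        built <- build_planted(specs$class[s], profiles, specs$p_sub[s],
                               linker_range)
        proteins[[length(proteins) + 1]] <-
          tibble(id = id,
                 description = paste0("synthetic ", specs$class[s]),
                 residues = built$residues,
                 length = nchar(built$residues))
        truth[[length(truth) + 1]] <- tibble(protein_id = id,
                                             class = specs$class[s], !!!lab)
        if (nrow(built$features)) {
          feats[[length(feats) + 1]] <-
            built$features |> mutate(protein_id = id, .before = 1)
        }
      }
    }
    list(proteins = list_rbind(proteins),
         truth = list_rbind(truth),
         features = if (length(feats)) list_rbind(feats) else
           tibble(protein_id = character(), family = character(),
                  start = integer(), end = integer()))
  })
}
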