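# Domain-architecture assembly and the HHK classification grammar.
#
# Features (profile hits + TM helices) are merged into one ordered track per
# protein, then classified: ethylene-receptor-like (EBD triple + residue
# diagnostics; subfamily 1 with GAF, subfamily 2 with an extra N-terminal
# helix), cytokinin-receptor-like (TM-flanked CHASE), phytochrome
# (PAS-GAF-PHY), dual (two HisKA), osmosensing group III (HAMP repeats), or
# a composition-labeled remainder. Truncations of the hybrid core are
# recorded independently of the primary label.

SENSING_FAMILIES <- c("GAF", "PAS", "HAMP", "CHASE", "PHY", "EBD")
CORE_FAMILIES <- c("HisKA", "HATPase_c", "REC")

HHK_LABELS <- c("ethylene-receptor-like", "cytokinin-receptor-like",
                "phytochrome-VIII-Fph", "dual-HHK", "group-III",
                "HHK-other", "not-HHK")

#' Merge domain hits and TM helices into per-protein architectures
#'
#' Same-family overlapping domain hits are reduced best-score-wins (ties to
#' the leftmost); a TM helix overlapping a retained domain hit by more than
#' half of the helix length is suppressed (domains win). The result is one
#' feature track sorted by start within each protein.
#'
#' @param hits Domain-hit tibble from [scan_profiles()].
#' @param helices TM-helix tibble from [predict_tm()].
#' @param proteins Protein record tibble, used to validate coordinates.
#' @return Tibble `protein_id`, `type` (`"domain"`/`"tm"`), `family`
#'   (`"TM"` for helices), `start`, `end`, `score`, `evalue`.
#' @export
assemble_architectures <- function(hits, helices, proteins) {
  feats <- bind_rows(
    hits |> mutate(type = "domain"),
    helices |>
      transmute(protein_id = .data$protein_id, family = "TM",
                start = .data$start, end = .data$end,
                score = .data$mean_hydropathy, evalue = NA_real_,
                type = "tm")
  )
  if (nrow(feats) == 0) {
    return(tibble(protein_id = character(), type = character(),
                  family = character(), start = integer(), end = integer(),
                  score = numeric(), evalue = numeric()))
  }
  lens <- setNames(proteins$length, proteins$id)
  bad <- is.na(lens[feats$protein_id]) | feats$start < 1 |
    feats$end > lens[feats$protein_id] | feats$start > feats$end
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("feature %s[%d,%d] lies outside protein '%s'",
                  feats$family[i], feats$start[i], feats$end[i],
                  feats$protein_id[i]),
          class = "hhk_coordinate_error")
  }
  feats |>
    group_by(.data$protein_id) |>
    group_modify(~ assemble_one(.x)) |>
    ungroup() |>
    arrange(.data$protein_id, .data$start) |>
    select("protein_id", "type", "family", "start", "end", "score", "evalue")
}

assemble_one <- function(f) {
  dom <- f[f$type == "domain", , drop = FALSE]
  if (nrow(dom) > 1) {
    kept <- dom |>
      group_by(.data$family) |>
      group_modify(~ resolve_overlaps(.x)) |>
      ungroup()
  } else {
    kept <- dom
  }
  tm <- f[f$type == "tm", , drop = FALSE]
  # domains win over TM helices, except the EBD profile: the EBD *is* a
  # helix triple, and its corroborating profile hit must not erase the
  # geometric evidence the grammar needs
  solid <- kept[kept$family != "EBD", , drop = FALSE]
  if (nrow(tm) > 0 && nrow(solid) > 0) {
    keep_tm <- vapply(seq_len(nrow(tm)), function(k) {
      ov <- pmin(tm$end[k], solid$end) - pmax(tm$start[k], solid$start) + 1
      all(ov <= 0.5 * (tm$end[k] - tm$start[k] + 1))
    }, logical(1))
    tm <- tm[keep_tm, , drop = FALSE]
  }
  bind_rows(kept, tm) |> arrange(.data$start)
}

# best-score-wins among overlapping same-family hits, ties to leftmost
resolve_overlaps <- function(h) {
  if (nrow(h) <= 1) return(h)
  ord <- order(-h$score, h$start)
  kept <- integer(0)
  for (i in ord) {
    ov <- pmin(h$end[i], h$end[kept]) - pmax(h$start[i], h$start[kept]) + 1
    if (!any(ov > 0)) kept <- c(kept, i)
  }
  h[sort(kept), , drop = FALSE]
}

#' Locate an ethylene-binding-domain helix triple
#'
#' Searches the TM helices lying entirely N-terminal to the first HisKA hit
#' for a chain of three or more helices with consecutive inter-helix gaps of
#' at most `max_gap` residues. The three C-terminal-most helices of the
#' C-terminal-most qualifying chain form the EBD; additional chain helices
#' N-terminal to the triple are recorded (they drive subfamily 2).
#'
#' @param features Assembled feature tibble for a single protein.
#' @param max_gap Maximum gap between consecutive member helices
#'   (default 40 residues).
#' @return `NULL` when no triple qualifies, else a list with `helices`
#'   (3-row tibble), `span_start`, `span_end`, and `n_extra` (chain helices
#'   N-terminal to the triple).
#' @export
call_ebd <- function(features, max_gap = 40) {
  stopifnot(length(unique(features$protein_id)) <= 1)
  hiska <- features[features$family == "HisKA", , drop = FALSE]
  if (nrow(hiska) == 0) return(NULL)
  h1 <- min(hiska$start)
  tm <- features[features$type == "tm" & features$end < h1, , drop = FALSE]
  if (nrow(tm) < 3) return(NULL)
  tm <- tm[order(tm$start), , drop = FALSE]
  gaps <- tm$start[-1] - tm$end[-nrow(tm)] - 1
  chain_id <- cumsum(c(1, gaps > max_gap))
  sizes <- table(chain_id)
  ok <- as.integer(names(sizes)[sizes >= 3])
  if (length(ok) == 0) return(NULL)
  chain <- max(ok)  # C-terminal-most qualifying chain
  members <- which(chain_id == chain)
  triple <- tail(members, 3)
  list(helices = tm[triple, , drop = FALSE],
       span_start = tm$start[triple[1]],
       span_end = tm$end[triple[3]],
       n_extra = length(members) - 3L)
}

#' Classify assembled architectures
#'
#' Applies the HHK grammar in priority order (ethylene > cytokinin >
#' phytochrome > dual > group III > other); every satisfied rule is recorded
#' in the evidence column, the first match sets the label. Truncation of the
#' hybrid core (missing REC, or missing HATPase_c and REC) is recorded
#' independently. An ethylene call additionally requires the residue
#' diagnostics of the EBD region to pass (see [diagnose()]); pass
#' `diagnostics = NULL` to classify on geometry alone.
#'
#' @param features Assembled feature tibble ([assemble_architectures()]).
#' @param proteins Protein record tibble (residues are needed for the
#'   diagnostic alignment).
#' @param diagnostics Diagnostic-set bundle from [hhk_references()], or
#'   `NULL`.
#' @param config Pipeline configuration, see [hhk_config()].
#' @return Tibble `protein_id`, `label`, `subfamily` (`"1"`, `"2"` or
#'   `"none"`), `truncation`, `composition`, `evidence`.
#' @export
classify_architectures <- function(features, proteins,
                                   diagnostics = NULL,
                                   config = hhk_config()) {
  rows <- map(seq_len(nrow(proteins)), function(i) {
    f <- features[features$protein_id == proteins$id[i], , drop = FALSE]
    cls <- classify_one(f, proteins$residues[i], diagnostics, config)
    tibble(protein_id = proteins$id[i], !!!cls)
  })
  list_rbind(rows)
}

classify_one <- function(f, residues, diagnostics, config) {
  dom <- f[f$type == "domain", , drop = FALSE]
  hiska <- dom[dom$family == "HisKA", , drop = FALSE]
  if (nrow(hiska) == 0) {
    return(list(label = "not-HHK", subfamily = "none", truncation = "none",
                composition = NA_character_, evidence = ""))
  }
  h1 <- min(hiska$start)
  evidence <- "hiska-present"
  # truncation flags from core domains downstream of the first HisKA
  has_hat <- any(dom$family == "HATPase_c" & dom$start > h1)
  has_rec <- any(dom$family == "REC" & dom$start > h1)
  truncation <- if (!has_hat) "HATPase-and-REC-missing"
                else if (!has_rec) "REC-missing" else "none"
  if (truncation != "none") {
    evidence <- c(evidence, paste0("truncation:", truncation))
  }

  sensing <- dom[dom$family %in% SENSING_FAMILIES & dom$start < h1, ,
                 drop = FALSE]
  composition <- if (nrow(sensing) == 0) "none" else
    paste(sensing$family[order(sensing$start)], collapse = "-")

  subfamily <- "none"
  # rule: ethylene-receptor-like (EBD triple + residue diagnostics)
  ethylene <- FALSE
  ebd <- call_ebd(f, max_gap = config$ebd_max_gap)
  if (!is.null(ebd)) {
    evidence <- c(evidence, "ebd-triple")
    pass <- TRUE
    if (!is.null(diagnostics)) {
      region <- substr(residues, ebd$span_start, ebd$span_end)
      rep <- tryCatch(
        diagnose(region, diagnostics$ethylene,
                 pass_threshold = config$diag_threshold,
                 score_floor = config$diag_score_floor),
        hhk_unalignable_region = function(e) NULL)
      pass <- !is.null(rep) && attr(rep, "pass")
      evidence <- c(evidence, if (pass) "ebd-diagnostics-pass"
                              else "ebd-diagnostics-fail")
    } else {
      evidence <- c(evidence, "ebd-diagnostics-skipped")
    }
    if (pass) {
      ethylene <- TRUE
      if (ebd$n_extra >= 1) {
        subfamily <- "2"
        evidence <- c(evidence, "extra-n-terminal-helix")
      } else {
        gaf_between <- any(dom$family == "GAF" & dom$start > ebd$span_end &
                             dom$start < h1)
        subfamily <- "1"
        evidence <- c(evidence,
                      if (gaf_between) "gaf-between-ebd-and-hiska"
                      else "subfamily-1-low-confidence")
      }
    }
  }

  # rule: cytokinin-receptor-like (TM-flanked CHASE N-terminal to HisKA)
  tm <- f[f$type == "tm", , drop = FALSE]
  chase <- dom[dom$family == "CHASE" & dom$start < h1, , drop = FALSE]
  cytokinin <- FALSE
  if (nrow(chase) > 0 && nrow(tm) > 0) {
    flank <- config$chase_flank
    cytokinin <- any(vapply(seq_len(nrow(chase)), function(k) {
      before <- any(tm$end >= chase$start[k] - flank &
                      tm$end < chase$start[k])
      after <- any(tm$start > chase$end[k] &
                     tm$start <= chase$end[k] + flank)
      before && after
    }, logical(1)))
    if (cytokinin) evidence <- c(evidence, "chase-tm-flanked")
  }

  # rule: phytochrome (PAS, GAF, PHY in order, N-terminal to HisKA)
  phyto <- FALSE
  pas <- dom$start[dom$family == "PAS" & dom$start < h1]
  gaf <- dom$start[dom$family == "GAF" & dom$start < h1]
  phy <- dom$start[dom$family == "PHY" & dom$start < h1]
  if (length(pas) && length(gaf) && length(phy)) {
    g_after <- gaf[gaf > min(pas)]
    phyto <- length(g_after) > 0 && any(phy > min(g_after))
    if (phyto) evidence <- c(evidence, "pas-gaf-phy-order")
  }

  # rule: dual HHK (two or more retained HisKA)
  dual <- nrow(hiska) >= 2
  if (dual) evidence <- c(evidence, sprintf("hiska-count-%d", nrow(hiska)))

  # rule: osmosensing group III (HAMP repeats ahead of HisKA)
  giii <- sum(dom$family == "HAMP" & dom$start < h1) >= 4
  if (giii) evidence <- c(evidence, "hamp-repeats>=4")

  label <- if (ethylene) "ethylene-receptor-like"
    else if (cytokinin) "cytokinin-receptor-like"
    else if (phyto) "phytochrome-VIII-Fph"
    else if (dual) "dual-HHK"
    else if (giii) "group-III"
    else "HHK-other"
  if (!ethylene) subfamily <- "none"
  list(label = label, subfamily = subfamily, truncation = truncation,
       composition = composition,
       evidence = paste(evidence, collapse = ";"))
}

#' The configured Dikarya HHK group catalog
#'
#' Sixteen group labels with matching rules against classification output:
#' `label` rules match the classifier's primary label (groups III, VIII/Fph
#' and the dual group), `composition` rules match the ordered
#' sensing-domain composition of `HHK-other` proteins. The catalog is an
#' editable configuration shipped as a plain TSV.
#'
#' @param path Catalog TSV; defaults to the packaged configuration.
#' @return Tibble `group`, `match_type`, `match`.
#' @export
dikarya_catalog <- function(path = system.file("extdata", "dikarya_groups.tsv",
                                               package = "hhkmine")) {
  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  as_tibble(tab)
}

#' Census of classified HHKs against a group catalog
#'
#' Counts proteins per primary label (per proteome when a `proteome` column
#' is present) and reports how many catalog groups have at least one member.
#'
#' @param classes Classification tibble ([classify_architectures()]),
#'   optionally with a `proteome` column.
#' @param catalog Group catalog ([dikarya_catalog()]).
#' @return An `hhk_census` object; `tidy()` gives per-label counts,
#'   `glance()` the groups-present summary.
#' @export
census_hhk <- function(classes, catalog = dikarya_catalog()) {
  if (nrow(classes) == 0) {
    out <- list(counts = tibble(proteome = character(), label = character(),
                                n = integer()),
                groups = tibble(proteome = character(), group = character(),
                                n = integer()),
                groups_present = tibble(proteome = character(),
                                        groups_present = integer()))
    return(structure(out, class = "hhk_census"))
  }
  cl <- classes
  if (!"proteome" %in% names(cl)) cl$proteome <- "proteome"
  counts <- cl |> count(.data$proteome, .data$label, name = "n")
  cl$group <- assign_group(cl$label, cl$composition, catalog)
  groups <- cl |>
    filter(!is.na(.data$group)) |>
    count(.data$proteome, .data$group, name = "n")
  gp <- cl |>
    group_by(.data$proteome) |>
    summarise(groups_present = dplyr::n_distinct(.data$group, na.rm = TRUE))
  structure(list(counts = counts, groups = groups, groups_present = gp),
            class = "hhk_census")
}

assign_group <- function(label, composition, catalog) {
  lab_rules <- catalog[catalog$match_type == "label", , drop = FALSE]
  comp_rules <- catalog[catalog$match_type == "composition", , drop = FALSE]
  g <- lab_rules$group[match(label, lab_rules$match)]
  other <- label == "HHK-other"
  g[other] <- comp_rules$group[match(composition[other], comp_rules$match)]
  g[label == "not-HHK"] <- NA_character_
  g
}

#' @export
print.hhk_census <- function(x, ...) {
  cat("<hhk_census>\n")
  print(x$counts, n = 20)
  print(x$groups_present)
  invisible(x)
}

#' @export
tidy.hhk_census <- function(x, ...) x$counts

#' @export
glance.hhk_census <- function(x, ...) x$groups_present
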