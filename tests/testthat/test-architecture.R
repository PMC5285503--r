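hit_row <- function(id, family, start, end, score = 50, evalue = 1e-6) {
  tibble::tibble(protein_id = id, family = family, start = as.integer(start),
                 end = as.integer(end), score = score, evalue = evalue)
}
tm_row <- function(id, start, end, hydro = 2.5) {
  tibble::tibble(protein_id = id, start = as.integer(start),
                 end = as.integer(end), mean_hydropathy = hydro)
}
prot1000 <- function(id = "p") protein_tbl(strrep("A", 1000), id = id)

test_that("assembly resolves overlaps, suppresses buried helices and sorts", {
  hits <- dplyr::bind_rows(
    hit_row("p", "HisKA", 10, 60, score = 40),
    hit_row("p", "HisKA", 30, 80, score = 35),
    hit_row("p", "CHASE", 90, 260, score = 80))
  helices <- dplyr::bind_rows(
    tm_row("p", 100, 120),          # buried inside the CHASE hit
    tm_row("p", 400, 425),
    tm_row("p", 300, 325))          # deliberately out of order
  f <- assemble_architectures(hits, helices, prot1000())
  expect_equal(nrow(f[f$family == "HisKA", ]), 1L)
  expect_equal(f$start[f$family == "HisKA"], 10L)      # best score wins
  expect_false(any(f$type == "tm" & f$start == 100))   # suppressed
  expect_equal(f$start, sort(f$start))                 # sorted by start
  expect_equal(sum(f$type == "tm"), 2L)
})

test_that("features outside the protein are a coordinate error", {
  expect_error(
    assemble_architectures(hit_row("p", "REC", 990, 1101), tm_row("p", 1, 1)[0, ],
                           prot1000()),
    class = "hhk_coordinate_error")
})

test_that("EBD calling finds the helix triple ahead of HisKA", {
  base <- dplyr::bind_rows(hit_row("p", "HisKA", 300, 360)) |>
    dplyr::mutate(type = "domain")
  tri <- dplyr::bind_rows(tm_row("p", 5, 25), tm_row("p", 40, 60),
                          tm_row("p", 80, 100)) |>
    dplyr::transmute(protein_id, family = "TM", start, end,
                     score = mean_hydropathy, evalue = NA_real_, type = "tm")
  ebd <- call_ebd(dplyr::bind_rows(base, tri))
  expect_equal(ebd$span_start, 5L)
  expect_equal(ebd$span_end, 100L)
  expect_equal(ebd$n_extra, 0L)

  # four chained helices: the C-terminal three form the EBD, one extra
  four <- dplyr::bind_rows(tm_row("p", 5, 25), tm_row("p", 60, 80),
                           tm_row("p", 100, 120), tm_row("p", 140, 160)) |>
    dplyr::transmute(protein_id, family = "TM", start, end,
                     score = mean_hydropathy, evalue = NA_real_, type = "tm")
  ebd4 <- call_ebd(dplyr::bind_rows(base, four))
  expect_equal(ebd4$span_start, 60L)
  expect_equal(ebd4$n_extra, 1L)

  # two helices only, or a gap beyond the limit, is no call
  expect_null(call_ebd(dplyr::bind_rows(base, tri[1:2, ])))
  spread <- tri; spread$start[3] <- 200L; spread$end[3] <- 220L
  expect_null(call_ebd(dplyr::bind_rows(base, spread)))
})

test_that("the grammar labels the canonical receptor architectures", {
  profs <- cached_profiles()
  refs <- cached_references()
  specs <- tibble::tibble(
    class = c("cytokinin", "ethylene-sf1", "ethylene-truncated",
              "phytochrome", "decoy-rec"),
    count = 1)
  syn <- synth_proteome(specs, profs, seed = 99L)
  res <- run_hhk_pipeline(syn$proteins, profiles = profs, diagnostics = refs)
  cls <- res$classes[match(syn$truth$protein_id, res$classes$protein_id), ]
  expect_equal(cls$label, syn$truth$label)
  expect_equal(cls$truncation, syn$truth$truncation)
  eth <- cls[cls$label == "ethylene-receptor-like", ]
  expect_equal(eth$subfamily, c("1", "1"))
  expect_match(eth$evidence[1], "gaf-between-ebd-and-hiska")
  expect_match(cls$evidence[cls$label == "cytokinin-receptor-like"],
               "chase-tm-flanked")
  expect_match(cls$evidence[cls$label == "phytochrome-VIII-Fph"],
               "pas-gaf-phy-order")
})

test_that("a REC-only protein is not an HHK", {
  f <- assemble_architectures(hit_row("p", "REC", 100, 211),
                              tm_row("p", 1, 1)[0, ], prot1000())
  cls <- classify_architectures(f, prot1000())
  expect_equal(cls$label, "not-HHK")
})

test_that("ethylene evidence outranks cytokinin but both are recorded", {
  # a chimeric architecture satisfying rules 3 and 4 at once
  hits <- dplyr::bind_rows(
    hit_row("p", "CHASE", 150, 339, score = 80),
    hit_row("p", "HisKA", 600, 665),
    hit_row("p", "HATPase_c", 700, 809),
    hit_row("p", "REC", 840, 951))
  helices <- dplyr::bind_rows(
    tm_row("p", 5, 25), tm_row("p", 50, 70), tm_row("p", 100, 120),
    tm_row("p", 360, 380))
  f <- assemble_architectures(hits, helices, prot1000())
  cls <- classify_architectures(f, prot1000(), diagnostics = NULL)
  expect_equal(cls$label, "ethylene-receptor-like")
  expect_match(cls$evidence, "chase-tm-flanked")
  expect_match(cls$evidence, "ebd-triple")
})

test_that("classification is a pure function of its inputs", {
  profs <- cached_profiles()
  syn <- synth_proteome(tibble::tibble(class = "group-iii", count = 2),
                        profs, seed = 5L)
  sc <- hhk_scan(syn$proteins, profs)
  f <- assemble_architectures(sc$hits, sc$helices, syn$proteins)
  a <- classify_architectures(f, syn$proteins)
  b <- classify_architectures(f, syn$proteins)
  expect_identical(a, b)
})

test_that("the census counts labels and catalog groups", {
  classes <- tibble::tibble(
    protein_id = paste0("p", 1:3),
    label = c("group-III", "group-III", "dual-HHK"),
    subfamily = "none", truncation = "none",
    composition = c("HAMP-HAMP-HAMP-HAMP", "HAMP-HAMP-HAMP-HAMP", "none"),
    evidence = "")
  cen <- census_hhk(classes)
  expect_equal(glance(cen)$groups_present, 2L)
  expect_equal(sum(tidy(cen)$n), 3L)
  empty <- census_hhk(classes[0, ])
  expect_equal(nrow(glance(empty)), 0L)
})
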