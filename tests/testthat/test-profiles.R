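make_seed <- function(rows, family = "TEST") {
  path <- withr::local_tempfile(fileext = ".afa", .local_envir = parent.frame())
  writeLines(unlist(lapply(seq_along(rows), function(i) {
    c(paste0(">r", i), rows[i])
  })), path)
  read_seed_alignment(path, family = family)
}

test_that("profile columns reward the seed consensus", {
  # two identical rows: the conserved M dominates its column
  seed <- make_seed(c("MKVLW", "MKVLW"))
  p <- build_profile(seed)
  expect_equal(p$width, 5L)
  expect_equal(hhkmine::AA_LETTERS[which.max(p$score[1, ])], "M")
  expect_true(all(is.finite(p$score)))
  # with a few more rows the whole consensus is the repeated sequence
  p4 <- build_profile(make_seed(rep("MKVLW", 4)))
  expect_equal(p4$consensus, "MKVLW")
})

test_that("an uninformative column scores flat against a uniform background", {
  # one column holding each of the 20 residues once, uniform background:
  # every residue's log-odds is identical and equals 0 bits
  rows <- paste0(hhkmine::AA_LETTERS, "MKVL")
  seed <- make_seed(rows)
  uniform <- stats::setNames(rep(1 / 20, 20), hhkmine::AA_LETTERS)
  p <- build_profile(seed, background = uniform)
  expect_lt(diff(range(p$score[1, ])), 1e-12)
  expect_equal(unname(p$score[1, 1]), 0, tolerance = 1e-12)
})

test_that("column frequencies follow the pseudocount arithmetic", {
  # two rows AA / AC inside a width-5 context; with pseudocount 0.5 the
  # first column's A-frequency is (2 + 0.5) / (2 + 20 * 0.5)
  seed <- make_seed(c("AAMKV", "ACMKV"))
  p <- build_profile(seed, pseudocount = 0.5)
  bg <- pmax(hhkmine:::AA_BACKGROUND, 1e-4)
  bg <- bg / sum(bg)
  expect_equal(unname(p$score[1, "A"]),
               log2(((2 + 0.5) / (2 + 10)) / bg[["A"]]), tolerance = 1e-12)
  expect_equal(unname(p$score[2, "C"]),
               log2(((1 + 0.5) / (2 + 10)) / bg[["C"]]), tolerance = 1e-12)
})

test_that("gap-majority columns are dropped and short profiles rejected", {
  seed <- make_seed(c("MK-VLAA", "MK-VLAA", "MKWVLAA", "MK-VLAA"))
  p <- build_profile(seed)
  expect_equal(p$width, 6L)  # the 75%-gap column is not a match column
  expect_error(build_profile(make_seed(c("MKV", "MKV"))),
               class = "hhk_profile_too_short")
})

test_that("null calibration is deterministic and matches its own quantiles", {
  a <- calibrate_null(cached_profiles()$HisKA, n_shuffles = 300,
                      length = 300, seed = 5L)
  b <- calibrate_null(cached_profiles()$HisKA, n_shuffles = 300,
                      length = 300, seed = 5L)
  expect_identical(a$null, b$null)
  expect_error(calibrate_null(cached_profiles()$HisKA, n_shuffles = 100),
               class = "hhk_calibration_error")
  # by construction of the Gumbel fit, the E-value of the null's 95th
  # percentile is close to -ln(0.95) ~ 0.05 at the calibration length
  q95 <- with(a$null, mu - beta * log(-log(0.95)))
  e <- profile_evalue(a, q95, a$null$n_windows)
  expect_equal(e, -log(0.95), tolerance = 1e-9)
})

test_that("E-values decrease strictly with score", {
  p <- cached_profiles()$REC
  s <- seq(0, 200, by = 10)
  e <- profile_evalue(p, s, 300)
  expect_true(all(diff(e) < 0))
  expect_true(all(e > 0))
})

test_that("scan recovers a planted consensus and scores it at the maximum", {
  p <- cached_profiles()$HisKA
  bg <- random_protein(300, seed = 31)
  planted <- paste0(substr(bg, 1, 40), p$consensus, substr(bg, 41, 300))
  hit <- scan_profile(protein_tbl(planted), p)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 41L)
  expect_equal(hit$end, 41L + p$width - 1L)
  expect_lt(hit$evalue, 1e-4)
  # the consensus itself scores the sum of per-column maxima
  self <- scan_profile(protein_tbl(p$consensus), p)
  expect_equal(self$score, sum(apply(p$score, 1, max)), tolerance = 1e-9)
})

test_that("scan agrees with brute-force enumeration on random proteins", {
  p <- cached_profiles()$PAS
  withr::local_seed(77)
  for (rep in 1:15) {
    prot <- paste(sample(hhkmine::AA_LETTERS, sample(80:300, 1),
                         replace = TRUE), collapse = "")
    expect_equal(max(hhkmine:::window_scores(hhkmine:::seq_to_index(prot), p$score)),
                 max(oracle_window_scores(prot, p)), tolerance = 1e-9)
  }
})

test_that("unknown residues contribute zero score", {
  p <- cached_profiles()$HisKA
  cons <- p$consensus
  with_x <- paste0(substr(cons, 1, 9), "X", substr(cons, 11, nchar(cons)))
  s_full <- scan_profile(protein_tbl(cons), p)$score
  s_x <- scan_profile(protein_tbl(with_x), p)$score
  expect_equal(s_full - s_x, max(p$score[10, ]), tolerance = 1e-9)
})

test_that("scanning requires calibration and tolerates short proteins", {
  p <- build_profile(make_seed(c("MKVLWAC", "MKVLWAC", "MKVLWAD")))
  expect_error(scan_profile(protein_tbl("MKVLWACMKVLWAC"), p),
               class = "hhk_calibration_missing")
  pc <- cached_profiles()$HisKA
  short <- suppressMessages(scan_profile(protein_tbl("MKVL"), pc))
  expect_equal(nrow(short), 0L)
})

test_that("background sequences rarely reach the retention threshold", {
  p <- cached_profiles()$GAF
  withr::local_seed(55)
  n_hit <- 0
  for (i in 1:300) {
    prot <- paste(sample(names(hhkmine:::AA_BACKGROUND), 300, replace = TRUE,
                         prob = hhkmine:::AA_BACKGROUND), collapse = "")
    n_hit <- n_hit + (nrow(scan_profile(protein_tbl(prot), p)) > 0)
  }
  expect_lte(n_hit / 300, 0.01)
})

test_that("profiles round-trip through the TSV serialization", {
  p <- cached_profiles()$CHASE
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(p, path)
  q <- read_profile_tsv(path)
  expect_equal(q$family, p$family)
  expect_equal(q$score, p$score, tolerance = 1e-12)
  expect_equal(q$background, p$background, tolerance = 1e-12)
  expect_equal(q$null$mu, p$null$mu, tolerance = 1e-12)
  expect_equal(q$consensus, p$consensus)
})
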