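test_that("center-star alignment handles identical and inserted sequences", {
  s <- random_protein(40, seed = 3)
  msa <- align_center_star(c(a = s, b = s, c = s))
  expect_equal(ncol(msa), 40L)
  expect_true(all(msa != "-"))

  ins <- paste0(substr(s, 1, 20), "W", substr(s, 21, 40))
  msa2 <- align_center_star(c(a = s, b = s, c = ins))
  expect_equal(ncol(msa2), 41L)
  expect_equal(sum(msa2["a", ] == "-"), 1L)
  expect_equal(sum(msa2["b", ] == "-"), 1L)
  expect_equal(sum(msa2["c", ] == "-"), 0L)

  # input order does not change the alignment (up to row order)
  msa3 <- align_center_star(c(c = ins, b = s, a = s))
  expect_equal(msa2[c("a", "b", "c"), ], msa3[c("a", "b", "c"), ])
  expect_error(align_center_star(c(a = s, b = s)),
               class = "hhk_too_few_taxa")
})

test_that("distances follow the Poisson-corrected closed form", {
  base <- strsplit(random_protein(100, seed = 6), "")[[1]]
  other <- base
  other[1:10] <- vapply(other[1:10], function(r) {
    setdiff(hhkmine::AA_LETTERS, r)[1]
  }, character(1))
  mat <- rbind(a = base, b = other, c = base)
  d <- hhk_distances(mat)
  expect_equal(d["a", "b"], -log(1 - 0.10), tolerance = 1e-12)
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("incomparable and saturated pairs are named errors", {
  mat <- rbind(a = c("M", "K", "-", "-"), b = c("-", "-", "V", "L"))
  err <- expect_error(hhk_distances(mat), class = "hhk_incomparable_pair")
  expect_match(conditionMessage(err), "'a'")
  sat <- rbind(a = c("M", "K"), b = c("V", "L"))
  expect_error(hhk_distances(sat), class = "hhk_incomparable_pair")
})

test_that("three taxa recover the closed-form branch lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- hhk_nj(d)
  # three-point formulas: x = (dab + dac - dbc)/2 etc.
  lens <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                   tr$tip.label)
  expect_equal(unname(lens[c("a", "b", "c")]), c(1, 2, 3))
})

test_that("NJ recovers additive trees exactly", {
  skip_if_not_installed("phangorn")
  withr::local_seed(17)
  for (rep in 1:10) {
    tr <- ape::rtree(8)
    d <- ape::cophenetic.phylo(tr)
    est <- hhk_nj(d[sort(rownames(d)), sort(rownames(d))])
    expect_equal(phangorn::RF.dist(ape::unroot(tr), est), 0)
    # additive matrices reproduce their branch lengths
    expect_equal(sum(est$edge.length), sum(ape::unroot(tr)$edge.length),
                 tolerance = 1e-9)
  }
})

mutate_frac <- function(chars, frac) {
  hit <- sample(length(chars), round(frac * length(chars)))
  chars[hit] <- vapply(chars[hit], function(r) {
    sample(setdiff(hhkmine::AA_LETTERS, r), 1)
  }, character(1))
  chars
}

test_that("bootstrap supports are deterministic and separate clear clades", {
  withr::local_seed(23)
  # four clades, each independently ~30% diverged from an unsampled
  # common ancestor (so every clade has a positive stem edge), ~50%
  # different between and far from saturation
  base <- strsplit(random_protein(120, seed = 2), "")[[1]]
  clade_seqs <- replicate(4, mutate_frac(base, 0.3), simplify = FALSE)
  # small within-clade divergence keeps every clade bipartition
  # identifiable (identical taxa create zero-length ties)
  mat <- do.call(rbind, lapply(1:4, function(k) {
    do.call(rbind, replicate(3, mutate_frac(clade_seqs[[k]], 0.02),
                             simplify = FALSE))
  }))
  rownames(mat) <- paste0(rep(letters[1:4], each = 3), 1:3)
  tree1 <- hhk_bootstrap(mat, n_reps = 50, seed = 7L)
  tree2 <- hhk_bootstrap(mat, n_reps = 50, seed = 7L)
  expect_identical(ape::write.tree(tree1), ape::write.tree(tree2))
  # every clade-defining bipartition has maximal support
  parts <- ape::prop.part(tree1)
  labs <- attr(parts, "labels")
  sup <- attr(tree1, "supports")
  for (k in 1:4) {
    want <- paste0(letters[k], 1:3)
    hit <- which(vapply(parts, function(p) {
      setequal(labs[p], want) || setequal(setdiff(labs, labs[p]), want)
    }, logical(1)))
    hit <- hit[hit > 1]   # skip the root partition
    expect_true(length(hit) >= 1)
    expect_true(all(sup[hit] >= 95, na.rm = TRUE))
  }
})

test_that("star-like data earns low supports", {
  withr::local_seed(29)
  # all taxa roughly pairwise-equidistant: independent 30% mutations of a
  # common base sequence
  base <- strsplit(random_protein(80, seed = 4), "")[[1]]
  mat <- do.call(rbind, replicate(6, mutate_frac(base, 0.3),
                                  simplify = FALSE))
  rownames(mat) <- paste0("t", 1:6)
  tr <- hhk_bootstrap(mat, n_reps = 50, seed = 11L)
  sup <- attr(tr, "supports")
  expect_true(all(sup[-1] < 70, na.rm = TRUE))
})

test_that("Newick output round-trips topology, lengths and supports", {
  skip_if_not_installed("phangorn")
  withr::local_seed(31)
  base <- strsplit(random_protein(100, seed = 5), "")[[1]]
  mat <- do.call(rbind, replicate(5, mutate_frac(base, 0.3),
                                  simplify = FALSE))
  rownames(mat) <- paste0("t", 1:5)
  tr <- hhk_bootstrap(mat, n_reps = 20, seed = 3L)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- read_newick(path)
  expect_equal(phangorn::RF.dist(tr, back), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)
  expect_setequal(back$node.label, tr$node.label)
})
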