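# Residue alphabets and per-residue constants shared across the package.

#' The 20 standard amino-acid letters
#'
#' One-letter codes in alphabetical order. `"X"` is accepted everywhere as an
#' unknown residue; it scores 0 in profile columns and 0 on the hydropathy
#' scale.
#'
#' @export
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Swiss-Prot-like background composition, used to seed synthetic sequences
# and as the fallback null composition; individual profiles recompute their
# own background from their seed alignment.
AA_BACKGROUND <- c(
  A = 0.0825, C = 0.0137, D = 0.0545, E = 0.0675, F = 0.0386,
  G = 0.0707, H = 0.0227, I = 0.0596, K = 0.0584, L = 0.0966,
  M = 0.0242, N = 0.0406, P = 0.0470, Q = 0.0393, R = 0.0553,
  S = 0.0656, T = 0.0534, V = 0.0687, W = 0.0108, Y = 0.0292
)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values; unknown residues (`X` or anything outside
#' the 20-letter alphabet) contribute 0.
#'
#' @export
KYTE_DOOLITTLE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Strongly hydrophobic residues used when emitting transmembrane blocks in
# synthetic sequences (weights favour Leu/Ile/Val as in real TM helices).
TM_ALPHABET <- c(L = 0.30, I = 0.25, V = 0.25, F = 0.10, A = 0.10)

# Disorder-promoting residues for inter-domain linkers: real linkers are
# hydrophilic, and a hydrophobic-free alphabet keeps the hydropathy TM caller
# from firing inside them.
LINKER_ALPHABET <- c(
  A = 0.08, D = 0.10, E = 0.12, G = 0.12, K = 0.10, N = 0.08,
  P = 0.10, Q = 0.08, R = 0.06, S = 0.10, T = 0.06
)

# Conservative-substitution partners used to build "allowed" sets for
# diagnostic positions (primary residue first).
AA_SIMILAR <- c(
  A = "G", C = "C", D = "E", E = "D", F = "Y", G = "A", H = "H",
  I = "L", K = "R", L = "I", M = "L", N = "Q", P = "P", Q = "N",
  R = "K", S = "T", T = "S", V = "I", W = "W", Y = "F"
)

# ---- internal encoding helpers ----

# residue character vector -> integer index into AA_LETTERS, with 21 meaning
# unknown/X (scores 0 wherever it appears)
aa_index <- function(chars) {
  idx <- match(chars, AA_LETTERS)
  idx[is.na(idx)] <- 21L
  idx
}

seq_to_index <- function(residues) {
  aa_index(strsplit(residues, "", fixed = TRUE)[[1]])
}

sample_residues <- function(n, weights = AA_BACKGROUND) {
  paste(sample(names(weights), n, replace = TRUE, prob = weights),
        collapse = "")
}
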