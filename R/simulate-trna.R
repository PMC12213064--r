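# Synthetic tRNA anticodon arms.
#
# Builds a sequence containing a canonical 7-nt anticodon loop flanked by an
# anticodon stem of exactly 4 or 5 complementary pairs (Watson-Crick), with
# a guaranteed non-pairing position immediately outside the stem.  This is
# the minimal construct needed to exercise anticodon-stem-length
# measurement; it mirrors the contrast between a 4-bp-stem tRNA-Trp(CCA)
# (associated with UGA readthrough) and the canonical 5-bp stem.

#' Simulate a tRNA anticodon arm with a prescribed stem length
#'
#' @param stem_bp Anticodon-stem length in base pairs: 4 or 5.
#' @param seed Integer seed.
#' @param anticodon Anticodon triplet placed in the loop (default `"CCA"`,
#'   the tryptophan anticodon).
#' @return List with `seq` (character), `anticodon_start` (1-based index of
#'   the anticodon's first base) and `stem_bp`.
#' @export
simulate_trna <- function(stem_bp, seed = 1, anticodon = "CCA") {
  if (!length(stem_bp) == 1 || !stem_bp %in% c(4, 5)) {
    abort("stem_bp must be 4 or 5")
  }
  if (nchar(anticodon) != 3) abort("anticodon must be a triplet")
  set.seed(as.integer(seed))
  nt <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  context5 <- paste0(sample(nt, 8, replace = TRUE), collapse = "")
  stem5 <- sample(nt, stem_bp, replace = TRUE)
  stem3 <- rev(comp[stem5])
  # the pair just outside the stem must not pair (neither WC nor G-U)
  m5 <- sample(nt, 1)
  non_pairing <- setdiff(nt, c(comp[m5], if (m5 == "G") "T", if (m5 == "T") "G"))
  m3 <- sample(non_pairing, 1)
  context3 <- paste0(sample(nt, 8, replace = TRUE), collapse = "")

  loop <- paste0(paste0(sample(nt, 2, replace = TRUE), collapse = ""),
                 anticodon,
                 paste0(sample(nt, 2, replace = TRUE), collapse = ""))
  seq <- paste0(context5, m5, paste0(stem5, collapse = ""), loop,
                paste0(stem3, collapse = ""), m3, context3)
  list(seq = seq,
       anticodon_start = 8L + 1L + as.integer(stem_bp) + 2L + 1L,
       stem_bp = as.integer(stem_bp))
}
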