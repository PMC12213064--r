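# Genetic-code tables and translation helpers.
#
# Two codes matter here: the standard bacterial code (NCBI translation
# table 11) and the Mycoplasma-like code (table 4) in which UGA encodes
# tryptophan instead of terminating translation.  Codons are always written
# as DNA triplets (TGA, not UGA) to match genome sequence.

AA_ALPHABET_20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' All 64 codons in alphabetical order
#'
#' @return Character vector of the 64 DNA codons, sorted alphabetically
#'   (AAA, AAC, ..., TTT).
#' @export
all_codons <- function() {
  nt <- c("A", "C", "G", "T")
  as.vector(outer(outer(nt, nt, paste0), nt, paste0)) %>% sort()
}

#' Codon-to-amino-acid table for a named genetic code
#'
#' @param code `"standard"` / `"11"` / `11` for the standard bacterial code,
#'   or `"uga_trp"` / `"4"` / `4` for the code in which TGA encodes
#'   tryptophan.  Stops are `"*"`.
#' @return Named character vector over the 64 codons.
#' @export
genetic_code_table <- function(code = "standard") {
  id <- normalize_code_id(code)
  gc <- Biostrings::getGeneticCode(id)
  gc[all_codons()]
}

normalize_code_id <- function(code) {
  code <- as.character(code)
  switch(code,
    standard = "11", "11" = "11",
    uga_trp = "4", "4" = "4",
    abort(sprintf("unknown genetic code '%s' (use 'standard'/11 or 'uga_trp'/4)", code))
  )
}

#' Translate DNA under a chosen genetic code
#'
#' Trailing partial codons are dropped; codons containing N (or other
#' ambiguity letters) translate to `X`; stop codons are rendered `*`.
#'
#' @param seq Single DNA string (character or [Biostrings::DNAString]).
#' @param code Genetic code, see [genetic_code_table()].
#' @return Single amino-acid string.
#' @export
translate_dna <- function(seq, code = "standard") {
  d <- as_dnastring(seq)
  len <- 3L * (length(d) %/% 3L)
  if (len == 0L) return("")
  d <- Biostrings::subseq(d, 1L, len)
  as.character(Biostrings::translate(
    d,
    genetic.code = Biostrings::getGeneticCode(normalize_code_id(code)),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
}

as_dnastring <- function(seq) {
  if (inherits(seq, "DNAString")) seq else Biostrings::DNAString(as.character(seq))
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(as_dnastring(seq)))
}

#' Synonymous codons of each amino acid under a genetic code
#'
#' @param code Genetic code, see [genetic_code_table()].
#' @return Named list: amino acid -> character vector of codons.
#' @keywords internal
synonymous_codons <- function(code = "standard") {
  tab <- genetic_code_table(code)
  split(names(tab), tab)[AA_ALPHABET_20]
}

codon_gc_count <- function(codons) {
  stringr::str_count(codons, "[GC]")
}
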