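# Highly conserved amino-acid (HCAA) positions.
#
# An alignment column is an HCAA position when at least a threshold fraction
# (default 90%) of all sequences -- gap-bearing sequences included in the
# denominator -- carry the same standard amino acid.  These columns anchor
# genetic-code inference: whatever codon the target genome uses at an HCAA
# position almost certainly encodes that conserved residue.

#' Read an aligned protein FASTA as a tidy alignment
#'
#' Residues are uppercased; selenocysteine/pyrrolysine (`U`/`O`) and any
#' ambiguity letters are mapped to `X`, which never counts towards
#' conservation.  Gaps are `-`.
#'
#' @param path FASTA file of aligned (equal-length) protein sequences.
#' @param family Family id attached to every row (default: file name
#'   without extension).
#' @return Tibble with columns `family`, `taxon`, `seq`.
#' @export
read_alignment_fasta <- function(path, family = NULL) {
  if (is.null(family)) {
    family <- tools::file_path_sans_ext(basename(path))
  }
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0) abort(sprintf("no sequences in '%s'", path))
  if (length(unique(Biostrings::width(aa))) != 1) {
    abort(sprintf("'%s' is not an alignment: sequences have unequal lengths", path))
  }
  seqs <- toupper(as.character(aa))
  seqs <- gsub(sprintf("[^%s-]", paste0(AA_ALPHABET_20, collapse = "")),
               "X", seqs)
  taxa <- names(aa)
  if (anyDuplicated(taxa)) abort(sprintf("duplicate taxon ids in '%s'", path))
  tibble(family = family, taxon = unname(taxa), seq = unname(seqs))
}

#' Write a tidy alignment to FASTA
#'
#' @param alignment Tibble with `taxon` and `seq` columns.
#' @param path Output file.
#' @export
write_alignment_fasta <- function(alignment, path) {
  x <- Biostrings::BStringSet(setNames(alignment$seq, alignment$taxon))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Identify highly conserved amino-acid (HCAA) positions
#'
#' A column qualifies iff its modal standard amino acid accounts for at
#' least `threshold` of *all* sequences (gaps and `X` stay in the
#' denominator but can never be the consensus).  The boundary is inclusive:
#' 9 identical residues out of 10 sequences qualifies at the default 0.90.
#'
#' @param alignments Tidy alignment tibble (`family`, `taxon`, `seq`), one
#'   or several families.
#' @param threshold Minimum conservation fraction, in (0, 1\].
#' @return Tibble with `family`, `column` (1-based), `consensus`,
#'   `conservation`.
#' @export
identify_hcaa <- function(alignments, threshold = 0.90) {
  if (!is.data.frame(alignments) || nrow(alignments) == 0) {
    abort("alignments must be a non-empty tibble")
  }
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  alignments %>%
    group_by(.data$family) %>%
    dplyr::group_modify(~ hcaa_one_family(.x, threshold)) %>%
    ungroup()
}

hcaa_one_family <- function(aln, threshold) {
  mat <- alignment_matrix(aln$seq)
  n <- nrow(mat)
  cols <- purrr::map_dfr(seq_len(ncol(mat)), function(j) {
    tab <- table(factor(mat[, j], levels = AA_ALPHABET_20))
    top <- max(tab)
    frac <- top / n
    if (frac < threshold) return(NULL)
    modal <- names(tab)[tab == top]
    if (length(modal) > 1) return(NULL)  # tie -> no consensus (threshold <= 0.5)
    tibble(column = j, consensus = modal, conservation = unname(frac))
  })
  if (nrow(cols) == 0) {
    tibble(column = integer(), consensus = character(),
           conservation = numeric())
  } else {
    cols
  }
}

alignment_matrix <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1) {
    abort("aligned sequences have unequal lengths")
  }
  matrix(unlist(strsplit(seqs, "")), nrow = length(seqs), byrow = TRUE)
}

#' Consensus query sequence and column map of one family
#'
#' The per-column modal character (gap included as a candidate) defines the
#' consensus; gap-majority columns are dropped from the query.  The column
#' map links each alignment column that survives to its residue index in
#' the ungapped query, which is how HCAA columns are later located inside
#' translated-search hits.
#'
#' @param alignment Tidy alignment tibble for a single family.
#' @return List with `query` (ungapped consensus string) and `map` (tibble:
#'   `column`, `qpos`).
#' @export
alignment_consensus <- function(alignment) {
  if (length(unique(alignment$family)) > 1) {
    abort("alignment_consensus expects a single family")
  }
  mat <- alignment_matrix(alignment$seq)
  chars <- apply(mat, 2, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[1]
  })
  keep <- chars %in% AA_ALPHABET_20
  list(
    query = paste0(chars[keep], collapse = ""),
    map = tibble(column = which(keep), qpos = seq_len(sum(keep)))
  )
}

#' Write an HCAA table as TSV
#'
#' @param hcaa Output of [identify_hcaa()].
#' @param path Output file.
#' @export
write_hcaa_tsv <- function(hcaa, path) {
  utils::write.table(hcaa, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
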