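# Six-frame translated homology search.
#
# A protein query is aligned locally (Smith-Waterman, BLOSUM62, affine gaps
# open 11 / extend 1) against all six translation frames of each contig.
# In-frame stop codons are rendered '*' and score a flat penalty (-4, the
# BLOSUM62 '*' column) instead of terminating the alignment, so that ORFs
# interrupted by a reassigned stop codon still align end to end -- the key
# signal for detecting UGA read-through.  Every translated residue carries
# an exact map back to its forward-strand codon.

#' Six-frame translation with coordinate maps
#'
#' @param seq One contig sequence (character or DNAString).
#' @param code Genetic code used for the search translation (default
#'   standard; stops are `*`, N-containing codons `X`).
#' @return Tibble with one row per frame: `strand` (`+`/`-`), `offset`
#'   (0-2, 5' offset on the translated strand), `aa` (translated string).
#'   Residue `i` of a frame maps to the forward-strand codon returned by
#'   [frame_codon_start()].
#' @export
six_frame_translate <- function(seq, code = "standard") {
  d <- as_dnastring(seq)
  L <- length(d)
  rc <- Biostrings::reverseComplement(d)
  purrr::map_dfr(0:2, function(off) {
    tibble(
      strand = c("+", "-"),
      offset = off,
      aa = c(
        if (L - off >= 3) translate_dna(Biostrings::subseq(d, off + 1L, L), code) else "",
        if (L - off >= 3) translate_dna(Biostrings::subseq(rc, off + 1L, L), code) else ""
      )
    )
  }) %>% arrange(desc(.data$strand), .data$offset)
}

#' Forward-strand start of a translated residue's codon
#'
#' @param i Residue index (1-based) within a translation frame.
#' @param strand `"+"` or `"-"`.
#' @param offset Frame offset 0-2 (on the translated strand).
#' @param contig_length Contig length in nt (needed for `-`).
#' @return 1-based forward-strand position of the codon's first base.
#' @export
frame_codon_start <- function(i, strand, offset, contig_length) {
  n <- max(length(i), length(strand))
  i <- rep_len(as.integer(i), n)
  strand <- rep_len(strand, n)
  offset <- rep_len(as.integer(offset), n)
  contig_length <- rep_len(as.integer(contig_length), n)
  ifelse(strand == "+",
         offset + 3L * (i - 1L) + 1L,
         contig_length - offset - 3L * i + 1L)
}

#' Search a genome for a protein query by six-frame local alignment
#'
#' @param genome Named character vector of contig sequences.
#' @param query Protein query (>= 30 residues, standard letters or X).
#' @param family Family id recorded on the hits.
#' @param score_threshold Minimum local-alignment score (BLOSUM62 units).
#' @param gap_opening,gap_extension Affine gap penalties (positive costs).
#' @param stop_penalty Score of `*` in the translated subject against any
#'   query residue (default -4).
#' @param code_for_search Genetic code used to translate the frames.
#' @param overlap_filter Keep only the best-scoring hit among hits of the
#'   same query sharing more than half of a genome span (ties: leftmost).
#' @param frames Optional precomputed frame table per contig (named list of
#'   [six_frame_translate()] outputs); avoids re-translating the genome
#'   when many queries are searched.
#' @return Tibble of hits: `family`, `contig`, `strand`, `offset` (frame
#'   offset 0-2), `start`, `end` (forward strand, 1-based inclusive,
#'   length divisible by 3), `score`, `query_start`, `query_end`,
#'   `sub_start`, `sub_end` (residue indices in query / frame), `query_aln`,
#'   `subject_aln` (gapped aligned strings), `contig_length`.
#' @export
translated_search <- function(genome, query, family = "query",
                              score_threshold = 60,
                              gap_opening = 11, gap_extension = 1,
                              stop_penalty = -4,
                              code_for_search = "standard",
                              overlap_filter = TRUE,
                              frames = NULL) {
  if (!grepl(sprintf("^[%sX]+$", paste0(AA_ALPHABET_20, collapse = "")), query)) {
    abort("query contains non-amino-acid letters")
  }
  if (nchar(query) < 30) abort("query must be at least 30 residues")
  mat <- blosum62_with_stop(stop_penalty)
  if (is.null(frames)) {
    frames <- purrr::map(genome, six_frame_translate, code = code_for_search)
  }

  hits <- purrr::imap_dfr(genome, function(seq, contig) {
    L <- nchar(seq)
    purrr::pmap_dfr(frames[[contig]], function(strand, offset, aa) {
      if (nchar(aa) < 10) return(NULL)
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(query), Biostrings::AAString(aa),
        type = "local", substitutionMatrix = mat,
        gapOpening = gap_opening, gapExtension = gap_extension
      )
      if (Biostrings::score(pa) < score_threshold) return(NULL)
      s1 <- Biostrings::start(Biostrings::subject(pa))
      s2 <- Biostrings::end(Biostrings::subject(pa))
      span <- sort(c(frame_codon_start(s1, strand, offset, L),
                     frame_codon_start(s2, strand, offset, L) + 2L))
      tibble(
        family = family, contig = contig, strand = strand, offset = offset,
        start = span[1], end = span[2], score = Biostrings::score(pa),
        query_start = Biostrings::start(Biostrings::pattern(pa)),
        query_end = Biostrings::end(Biostrings::pattern(pa)),
        sub_start = s1, sub_end = s2,
        query_aln = as.character(Biostrings::alignedPattern(pa)),
        subject_aln = as.character(Biostrings::alignedSubject(pa)),
        contig_length = L
      )
    })
  })
  if (nrow(hits) == 0) return(empty_hits())
  if (overlap_filter) hits <- filter_overlapping_hits(hits)
  hits
}

empty_hits <- function() {
  tibble(
    family = character(), contig = character(), strand = character(),
    offset = integer(), start = integer(), end = integer(), score = numeric(),
    query_start = integer(), query_end = integer(),
    sub_start = integer(), sub_end = integer(),
    query_aln = character(), subject_aln = character(),
    contig_length = integer()
  )
}

# Best hit per overlapping genome region for one query: sweep hits in
# decreasing score (ties leftmost) and drop any hit sharing > 50% of the
# shorter span with an already-kept hit on the same contig.
filter_overlapping_hits <- function(hits) {
  hits <- arrange(hits, desc(.data$score), .data$start)
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1]) {
    for (j in which(keep[seq_len(i - 1)])) {
      if (hits$contig[i] != hits$contig[j]) next
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j]) + 1
      shorter <- min(hits$end[i] - hits$start[i], hits$end[j] - hits$start[j]) + 1
      if (ov > 0.5 * shorter) {
        keep[i] <- FALSE
        break
      }
    }
  }
  hits[keep, ]
}

blosum62_with_stop <- function(stop_penalty = -4) {
  mat <- get_blosum62()
  if (stop_penalty != -4) {
    mat["*", ] <- stop_penalty
    mat[, "*"] <- stop_penalty
    mat["*", "*"] <- 1
  }
  mat
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Write translated-search hits as TSV
#'
#' @param hits Output of [translated_search()].
#' @param path Output file.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(
    select(hits, "family", "contig", "strand", "offset", "start", "end", "score"),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
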