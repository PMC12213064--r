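# Codon observations at HCAA positions and the 64 x 20 count matrix.
#
# For every translated-search hit, each HCAA alignment column whose query
# residue falls inside the hit and aligns to a subject residue (not a gap)
# contributes one observation: the genome codon under that subject residue
# (reverse-complemented to coding orientation on the minus strand) paired
# with the column's conserved amino acid.  Subject stops ('*') do emit
# observations -- a TGA codon aligned under a conserved tryptophan is
# exactly how UGA=W reassignment becomes visible.  Observations are
# accumulated into a 64-codon x 20-amino-acid count matrix.

#' Map HCAA columns of one family to genome codons within hits
#'
#' @param genome Named character vector of contig sequences.
#' @param hits Hit tibble from [translated_search()] (one family).
#' @param hcaa HCAA tibble from [identify_hcaa()] for the same family.
#' @param column_map Tibble (`column`, `qpos`) from [alignment_consensus()]
#'   linking alignment columns to query residue indices.
#' @return Observation tibble: `family`, `column`, `aa` (conserved residue),
#'   `codon` (coding orientation), `contig`, `codon_start` (forward strand),
#'   `strand`.  Duplicate observations of the same (family, column, genome
#'   codon) from overlapping hits are counted once.
#' @export
map_hcaa_to_codons <- function(genome, hits, hcaa, column_map) {
  fams_h <- unique(hits$family)
  fams_a <- unique(hcaa$family)
  if (length(fams_h) && length(fams_a) && !any(fams_h %in% fams_a)) {
    abort("hits and hcaa describe different families")
  }
  obs <- purrr::pmap_dfr(hits, function(...) {
    hit <- list(...)
    map_one_hit(genome, hit, hcaa[hcaa$family == hit$family, ], column_map)
  })
  if (nrow(obs) == 0) return(empty_observations())
  distinct(obs, .data$family, .data$column, .data$contig, .data$codon_start,
           .keep_all = TRUE)
}

map_one_hit <- function(genome, hit, hcaa, column_map) {
  if (nrow(hcaa) == 0) return(NULL)
  qc <- strsplit(hit$query_aln, "")[[1]]
  sc <- strsplit(hit$subject_aln, "")[[1]]
  # residue index (in full query / frame) at each alignment position
  q_idx <- hit$query_start - 1L + cumsum(qc != "-")
  s_idx <- hit$sub_start - 1L + cumsum(sc != "-")
  want <- hcaa %>%
    dplyr::inner_join(column_map, by = "column") %>%
    filter(.data$qpos >= hit$query_start, .data$qpos <= hit$query_end)
  if (nrow(want) == 0) return(NULL)
  # alignment position of each wanted query residue; drop gap-aligned ones
  q_positions <- which(qc != "-")
  a <- q_positions[match(want$qpos, q_idx[q_positions])]
  ok <- !is.na(a) & sc[a] != "-"
  if (!any(ok)) return(NULL)
  want <- want[ok, ]
  a <- a[ok]
  st <- frame_codon_start(s_idx[a], hit$strand, hit$offset, hit$contig_length)
  codon <- substring(genome[[hit$contig]], st, st + 2L)
  if (hit$strand == "-") {
    codon <- vapply(codon, revcomp, character(1), USE.NAMES = FALSE)
  }
  tibble(family = want$family, column = want$column, aa = want$consensus,
         codon = codon, contig = hit$contig, codon_start = st,
         strand = hit$strand)
}

empty_observations <- function() {
  tibble(family = character(), column = integer(), aa = character(),
         codon = character(), contig = character(), codon_start = integer(),
         strand = character())
}

#' Collect codon observations for a whole genome and marker set
#'
#' Convenience wrapper: per family, builds the consensus query, runs
#' [translated_search()] and maps HCAA columns to codons.
#'
#' @param genome Named character vector of contig sequences.
#' @param alignments Tidy alignment tibble (all families).
#' @param hcaa HCAA tibble (default: computed at the 0.90 threshold).
#' @param ... Passed to [translated_search()] (e.g. `score_threshold`).
#' @return Observation tibble as in [map_hcaa_to_codons()].
#' @export
codon_observations <- function(genome, alignments,
                               hcaa = identify_hcaa(alignments), ...) {
  frames <- purrr::map(genome, six_frame_translate)
  obs <- purrr::map_dfr(unique(alignments$family), function(f) {
    aln <- filter(alignments, .data$family == f)
    cons <- alignment_consensus(aln)
    hits <- translated_search(genome, cons$query, family = f,
                              frames = frames, ...)
    if (nrow(hits) == 0) return(NULL)
    map_hcaa_to_codons(genome, hits, filter(hcaa, .data$family == f), cons$map)
  })
  if (nrow(obs) == 0) empty_observations() else obs
}

#' Accumulate observations into a 64 x 20 codon-observation matrix
#'
#' @param observations Observation tibble ([map_hcaa_to_codons()] /
#'   [codon_observations()]).  Codons containing N (or anything outside
#'   ACGT) are discarded with a message.
#' @return A `codon_matrix`: tibble with one row per (codon, amino acid)
#'   pair (complete 64 x 20 grid) and count column `n`; total observation
#'   count in `attr(, "total_sites")`.
#' @export
codon_matrix <- function(observations) {
  if (is.null(observations) || nrow(observations) == 0) {
    obs <- tibble(codon = character(), aa = character())
  } else {
    ok <- grepl("^[ACGT]{3}$", observations$codon)
    if (any(!ok)) {
      inform(sprintf("discarding %d observation(s) with ambiguous codons",
                     sum(!ok)))
    }
    obs <- observations[ok, c("codon", "aa")]
  }
  grid <- tidyr::expand_grid(codon = all_codons(), aa = AA_ALPHABET_20)
  counts <- obs %>%
    count(.data$codon, .data$aa, name = "n") %>%
    dplyr::right_join(grid, by = c("codon", "aa")) %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n)) %>%
    arrange(.data$codon, .data$aa)
  structure(counts, class = c("codon_matrix", class(counts)),
            total_sites = sum(counts$n))
}

#' Total number of observations in a codon matrix
#' @param mat A `codon_matrix`.
#' @return Integer count.
#' @export
total_sites <- function(mat) {
  attr(mat, "total_sites")
}

#' Write a codon matrix as a 64-row x 20-column TSV
#'
#' Rows are codons (alphabetical), columns amino acids (alphabetical); a
#' final `total` column gives per-codon totals.
#'
#' @param mat A `codon_matrix`.
#' @param path Output file.
#' @export
write_codon_matrix_tsv <- function(mat, path) {
  wide <- tidyr::pivot_wider(as_tibble(mat), names_from = "aa",
                             values_from = "n") %>%
    mutate(total = rowSums(dplyr::across(dplyr::all_of(AA_ALPHABET_20))))
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a codon matrix written by [write_codon_matrix_tsv()]
#'
#' @param path TSV file.
#' @return A `codon_matrix`.
#' @export
read_codon_matrix_tsv <- function(path) {
  wide <- utils::read.delim(path, check.names = FALSE)
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(wide), -dplyr::any_of("total")),
    -"codon", names_to = "aa", values_to = "n"
  )
  obs <- long[rep(seq_len(nrow(long)), long$n), c("codon", "aa")]
  codon_matrix(obs)
}
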