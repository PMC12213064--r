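# Descriptive genome statistics: GC content, circular GC skew, codon usage,
# annotation feature tallies, and tRNA anticodon-stem length.

#' GC content of a sequence
#'
#' N (and any non-ACGT letter) is excluded from both numerator and
#' denominator.
#'
#' @param seq DNA string (character or DNAString).
#' @return Fraction in \[0, 1\], or `NA` for an empty / all-N sequence.
#' @export
gc_content <- function(seq) {
  s <- toupper(as.character(seq))
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) stringr::str_count(s, stringr::fixed(b)),
                   numeric(1))
  total <- sum(counts)
  if (total == 0) return(NA_real_)
  unname((counts["G"] + counts["C"]) / total)
}

#' Windowed GC skew over a circular sequence
#'
#' Computes (G - C) / (G + C) in sliding windows; by default windows wrap
#' past the end of the sequence (circular chromosome).  Windows with
#' G + C = 0 are `NA`.
#'
#' @param seq DNA string.
#' @param window Window size in nt (default 10 kb).
#' @param step Step size in nt (default 1 kb); `window >= step >= 1`.
#' @param circular Wrap windows past the origin (default TRUE).
#' @return A `skew_profile` tibble with `start`, `end` (1-based, `end` may
#'   exceed the length for wrapped windows) and `skew`; `ceiling(L / step)`
#'   windows when circular.
#' @export
gc_skew <- function(seq, window = 10000, step = 1000, circular = TRUE) {
  s <- toupper(as.character(seq))
  L <- nchar(s)
  if (step < 1 || window < step) abort("need window >= step >= 1")
  if (window > L) abort("window exceeds sequence length")
  starts <- seq(1L, if (circular) L else L - window + 1L, by = step)
  ext <- if (circular) paste0(s, substr(s, 1L, window)) else s
  skew <- vapply(starts, function(st) {
    w <- substr(ext, st, st + window - 1L)
    g <- stringr::str_count(w, stringr::fixed("G"))
    c_ <- stringr::str_count(w, stringr::fixed("C"))
    if (g + c_ == 0) NA_real_ else (g - c_) / (g + c_)
  }, numeric(1))
  structure(
    tibble(start = starts, end = starts + window - 1L, skew = skew),
    class = c("skew_profile", class(tibble())),
    window = window, step = step, circular = circular, seq_length = L
  )
}

#' Plot a GC-skew profile
#'
#' @param object A `skew_profile` from [gc_skew()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.skew_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$start, y = .data$skew)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window start (nt)", y = "(G - C) / (G + C)")
}

#' Codon usage of a set of coding sequences
#'
#' @param genes Character vector of in-frame coding sequences; genes whose
#'   length is not a multiple of 3 are skipped with a warning.
#' @param code Genetic code used to group synonymous codons.
#' @return Tibble with `codon`, `aa`, `n` (count) and `rel_freq` (frequency
#'   within the codon's synonymous family; `NA` for unused families).
#' @export
codon_usage <- function(genes, code = "standard") {
  genes <- as.character(genes)
  bad <- nchar(genes) %% 3 != 0
  if (any(bad)) {
    warn(sprintf("skipping %d gene(s) with length not divisible by 3",
                 sum(bad)))
    genes <- genes[!bad]
  }
  codons <- as.character(unlist(purrr::map(genes, function(g) {
    substring(g, seq(1, nchar(g), by = 3), seq(3, nchar(g), by = 3))
  })))
  codons <- codons[grepl("^[ACGT]{3}$", codons)]
  tab <- genetic_code_table(code)
  counts <- table(factor(codons, levels = all_codons()))
  tibble(codon = all_codons(), aa = unname(tab),
         n = as.integer(counts)) %>%
    group_by(.data$aa) %>%
    mutate(rel_freq = {
      tot <- sum(.data$n)
      if (tot > 0) .data$n / tot else rep(NA_real_, dplyr::n())
    }) %>%
    ungroup()
}

#' GC content at third codon positions
#'
#' @param genes Character vector of in-frame coding sequences.
#' @return Fraction of G/C at third positions (`NA` if no codons).
#' @export
gc3_content <- function(genes) {
  usage <- codon_usage(genes)
  third <- substr(usage$codon, 3, 3)
  tot <- sum(usage$n)
  if (tot == 0) return(NA_real_)
  sum(usage$n[third %in% c("G", "C")]) / tot
}

#' Tally features of a GFF3 annotation
#'
#' @param gff Path to a GFF3 file, or a `GRanges` already imported.
#' @return Tibble with `type` and `n`, one row per feature type.  If tRNA
#'   features carry an `anticodon` attribute, the attribute
#'   `trna_aa_coverage` reports whether the tRNA set decodes all 20 amino
#'   acids (under the code in attribute `code`, default standard).
#' @export
feature_tally <- function(gff) {
  gr <- if (is.character(gff)) rtracklayer::import(gff) else gff
  if (length(gr) == 0) {
    return(structure(tibble(type = character(), n = integer()),
                     trna_aa_coverage = NA))
  }
  tall <- count(tibble(type = as.character(gr$type)), .data$type, name = "n")
  coverage <- NA
  mc <- S4Vectors::mcols(gr)
  if ("anticodon" %in% names(mc)) {
    anti <- as.character(mc$anticodon[as.character(gr$type) == "tRNA"])
    anti <- anti[!is.na(anti)]
    if (length(anti)) {
      code <- if ("code" %in% names(mc)) {
        stats::na.omit(as.character(mc$code))[1]
      } else "standard"
      aa <- vapply(anti, function(a) translate_dna(revcomp(a), code),
                   character(1))
      coverage <- all(AA_ALPHABET_20 %in% aa)
    }
  }
  structure(tall, trna_aa_coverage = coverage)
}

# Watson-Crick or (optionally) G.U wobble pairing
nt_pairs <- function(x, y, allow_gu = TRUE) {
  wc <- (x == "A" & y == "T") | (x == "T" & y == "A") |
    (x == "G" & y == "C") | (x == "C" & y == "G")
  if (!allow_gu) return(wc)
  wc | (x == "G" & y == "T") | (x == "T" & y == "G")
}

#' Measure the anticodon-stem length of a tRNA sequence
#'
#' Assumes the canonical 7-nt anticodon loop centred on the anticodon
#' (2 nt - anticodon - 2 nt) and counts consecutive pairing positions
#' walking outward from the loop boundary, stopping at the first
#' non-pairing position; capped at 7.
#'
#' @param seq tRNA sequence (character, DNA alphabet).
#' @param anticodon_start 1-based index of the anticodon's first base.
#' @param allow_gu Count G.U wobble pairs as pairing (default TRUE).
#' @return Integer stem length in base pairs.
#' @export
anticodon_stem_length <- function(seq, anticodon_start, allow_gu = TRUE) {
  s <- strsplit(toupper(as.character(seq)), "")[[1]]
  L <- length(s)
  if (anticodon_start - 3 < 1 || anticodon_start + 5 > L) {
    abort("anticodon index out of range (need the full 7-nt loop inside the sequence)")
  }
  n <- 0L
  for (i in 0:6) {
    p5 <- anticodon_start - 3L - i
    p3 <- anticodon_start + 5L + i
    if (p5 < 1 || p3 > L) break
    if (!nt_pairs(s[p5], s[p3], allow_gu)) break
    n <- n + 1L
  }
  n
}

#' Bundle the headline statistics of an annotated genome
#'
#' @param genome Named character vector of contig sequences.
#' @param genes Optional truth/annotation tibble with `start`, `end`,
#'   `strand`, `contig` for coding genes (codon usage and counts).
#' @param window,step GC-skew window parameters.
#' @param code Genetic code for codon usage.
#' @return List with `genome_length`, `gc`, `skew` (a `skew_profile`),
#'   and, when `genes` is given, `n_genes`, `gc3`.
#' @export
genome_stats <- function(genome, genes = NULL, window = 10000, step = 1000,
                         code = "standard") {
  seqs <- paste0(genome, collapse = "")
  out <- list(
    genome_length = nchar(seqs),
    gc = gc_content(seqs),
    skew = gc_skew(genome[[1]],
                   window = min(window, nchar(genome[[1]])),
                   step = min(step, nchar(genome[[1]])))
  )
  if (!is.null(genes) && nrow(genes)) {
    cds <- extract_gene_seqs(genome, genes)
    out$n_genes <- nrow(genes)
    out$gc3 <- gc3_content(cds)
  }
  out
}

#' Extract coding sequences from a genome given gene coordinates
#'
#' @param genome Named character vector of contigs.
#' @param genes Tibble with `contig`, `start`, `end`, `strand`.
#' @return Character vector of coding-strand gene sequences.
#' @export
extract_gene_seqs <- function(genome, genes) {
  purrr::pmap_chr(
    genes[, c("contig", "start", "end", "strand")],
    function(contig, start, end, strand) {
      s <- substr(genome[[contig]], start, end)
      if (strand == "-") revcomp(s) else s
    }
  )
}
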