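# Genome FASTA and truth-GFF3 input/output.

#' Write a genome to FASTA
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of contig sequences (uppercase).
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) abort(sprintf("no sequences in '%s'", path))
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write gene-truth records as GFF3
#'
#' Coordinates are 1-based inclusive (GFF3 convention, identical to the
#' in-memory representation).  Attributes carry the source family and the
#' genetic code.
#'
#' @param genes Truth tibble from [simulate_genome()].
#' @param path Output file.
#' @param code Genetic code recorded in the attributes.
#' @export
write_truth_gff3 <- function(genes, path, code = "standard") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- genes$gene_id
  gr$family <- genes$family
  gr$code <- code
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 annotation as a tibble
#'
#' @param path GFF3 file.
#' @return Tibble with `contig`, `start`, `end`, `strand`, `type` and any
#'   attribute columns present (e.g. `family`, `code`).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as_tibble(as.data.frame(gr))
  df %>%
    rename(contig = "seqnames") %>%
    mutate(contig = as.character(.data$contig),
           strand = as.character(.data$strand),
           type = as.character(.data$type))
}
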