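# Synthetic target genome.
#
# Each marker family's consensus protein is diverged at a configurable rate
# and reverse-translated under the configured genetic code, with synonymous
# codons weighted exp(beta * GC(codon)); beta is solved numerically so that
# the expected coding GC equals the requested target.  Genes are laid on
# random strands of a single circular contig, separated by intergenic
# spacers whose base composition matches the GC target.  Ground truth (gene
# coordinates, source family, every TGA-encoded tryptophan site) is
# returned alongside the sequence.

#' Simulate a coding genome from marker families
#'
#' @param families Output of [simulate_marker_families()] (list with an
#'   `alignments` tibble), or the alignments tibble itself.
#' @param config A [sim_config()]; `genetic_code`, `gc_target`, `divergence`,
#'   `intergenic_mean` and `tga_prob` control the genome.
#' @return List with:
#'   * `genome` — named character vector of contig sequences (one contig);
#'   * `genes` — truth tibble (`gene_id`, `contig`, `start`, `end`, `strand`,
#'     `frame`, `family`, `protein`), coordinates 1-based inclusive on the
#'     forward strand;
#'   * `tga_sites` — tibble of tryptophan residues encoded by TGA
#'     (`family`, `residue`, `column`, `contig`, `codon_start`, `strand`);
#'     empty under the standard code;
#'   * `code` — the genetic code used.
#' @export
simulate_genome <- function(families, config) {
  check_sim_config(config)
  aln <- if (is.data.frame(families)) families else families$alignments
  if (is.null(aln) || nrow(aln) == 0) abort("families must be non-empty")
  set.seed(config$seed + 1L)

  fam_ids <- unique(aln$family)
  consensi <- purrr::map(fam_ids, function(f) {
    alignment_consensus(dplyr::filter(aln, .data$family == f))$query
  })
  names(consensi) <- fam_ids

  # diverge each consensus
  proteins <- purrr::map(consensi, function(p) {
    res <- strsplit(p, "")[[1]]
    hit <- runif(length(res)) < config$divergence
    if (any(hit)) {
      res[hit] <- vapply(res[hit], function(a) {
        sample(setdiff(AA_ALPHABET_20, a), 1)
      }, character(1))
    }
    paste0(res, collapse = "")
  })

  beta <- solve_gc_beta(paste0(unlist(proteins), collapse = ""), config)
  weights <- codon_weights(beta, config)

  contig <- "contig1"
  pieces <- character(0)
  pos <- 0L
  genes <- list()
  tga <- list()
  spacer <- function() {
    len <- rpois(1, config$intergenic_mean)
    if (len == 0) return("")
    paste0(sample(c("G", "C", "A", "T"), len, replace = TRUE,
                  prob = c(config$gc_target / 2, config$gc_target / 2,
                           (1 - config$gc_target) / 2,
                           (1 - config$gc_target) / 2)),
           collapse = "")
  }

  for (f in fam_ids) {
    sp <- spacer()
    pos <- pos + nchar(sp)
    pieces <- c(pieces, sp)
    res <- strsplit(proteins[[f]], "")[[1]]
    codons <- vapply(res, function(a) {
      w <- weights[[a]]
      sample(names(w), 1, prob = w)
    }, character(1))
    coding <- paste0(codons, collapse = "")
    strand <- sample(c("+", "-"), 1)
    start <- pos + 1L
    end <- pos + nchar(coding)
    gene_seq <- if (strand == "+") coding else revcomp(coding)
    pieces <- c(pieces, gene_seq)
    pos <- end
    genes[[f]] <- tibble(
      gene_id = paste0("gene_", f), contig = contig,
      start = start, end = end, strand = strand,
      frame = (start - 1L) %% 3L, family = f, protein = proteins[[f]]
    )
    is_tga <- codons == "TGA"
    if (any(is_tga)) {
      i <- which(is_tga)
      tga[[f]] <- tibble(
        family = f, residue = i, column = i, contig = contig,
        codon_start = if (strand == "+") start + 3L * (i - 1L)
                      else end - 3L * i + 1L,
        strand = strand
      )
    }
  }
  pieces <- c(pieces, spacer())

  list(
    genome = setNames(paste0(pieces, collapse = ""), contig),
    genes = bind_rows(genes),
    tga_sites = if (length(tga)) bind_rows(tga) else
      tibble(family = character(), residue = integer(), column = integer(),
             contig = character(), codon_start = integer(),
             strand = character()),
    code = config$genetic_code
  )
}

# Expected GC of a codon sampled for amino acid `a` with weights
# exp(beta * gc), and the solver that matches the pooled expectation to the
# configured target.  Tryptophan is handled separately: under uga_trp its
# codon is TGA with probability tga_prob (else TGG), a fixed choice that
# models reassignment pressure rather than GC steering.
codon_weights <- function(beta, config) {
  syn <- synonymous_codons("standard")
  w <- purrr::map(syn, function(cods) {
    gc <- codon_gc_count(cods)
    setNames(exp(beta * gc), cods)
  })
  if (config$genetic_code == "uga_trp") {
    w[["W"]] <- c(TGA = config$tga_prob, TGG = 1 - config$tga_prob)
  }
  w
}

solve_gc_beta <- function(protein, config) {
  res <- strsplit(protein, "")[[1]]
  comp <- table(factor(res, levels = AA_ALPHABET_20))
  syn_gc <- purrr::map(synonymous_codons("standard"), codon_gc_count)
  w_gc <- if (config$genetic_code == "uga_trp") {
    config$tga_prob * 1 + (1 - config$tga_prob) * 2  # TGA has 1 GC, TGG 2
  } else {
    2
  }
  expected_gc <- function(beta) {
    e <- vapply(AA_ALPHABET_20, function(a) {
      if (a == "W") return(w_gc)
      gc <- syn_gc[[a]]
      w <- exp(beta * gc)
      sum(w * gc) / sum(w)
    }, numeric(1))
    sum(comp * e) / (3 * sum(comp))
  }
  lo <- expected_gc(-30)
  hi <- expected_gc(30)
  # amino-acid composition bounds the coding GC; the intergenic spacers match
  # gc_target exactly, so a target slightly outside the coding range is still
  # reachable genome-wide.  Clamp within a small margin, error beyond it.
  margin <- 0.03
  if (config$gc_target < lo - margin || config$gc_target > hi + margin) {
    abort(sprintf(
      "gc_target %.2f is not achievable for this protein set (coding range %.2f-%.2f)",
      config$gc_target, lo, hi))
  }
  if (config$gc_target <= lo) return(-30)
  if (config$gc_target >= hi) return(30)
  uniroot(function(b) expected_gc(b) - config$gc_target,
          c(-30, 30), tol = 1e-6)$root
}
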