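# Independent brute-force oracles and small random-input generators used
# across the suite.  The oracles deliberately share no code with the
# package implementations they check.

# Column-by-column conservation scan: for each column, count each standard
# amino acid with a plain loop and report columns whose most frequent
# residue reaches the threshold over all sequences.
brute_hcaa <- function(seqs, threshold = 0.90) {
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n <- length(seqs)
  len <- nchar(seqs[1])
  out <- list()
  for (j in seq_len(len)) {
    chars <- substr(seqs, j, j)
    best_aa <- NA_character_
    best_n <- -1L
    tie <- FALSE
    for (a in aa20) {
      k <- sum(chars == a)
      if (k > best_n) {
        best_n <- k
        best_aa <- a
        tie <- FALSE
      } else if (k == best_n) {
        tie <- TRUE
      }
    }
    if (!tie && best_n / n >= threshold) {
      out[[length(out) + 1]] <- data.frame(
        column = j, consensus = best_aa, conservation = best_n / n
      )
    }
  }
  if (length(out) == 0) {
    data.frame(column = integer(), consensus = character(),
               conservation = numeric())
  } else {
    do.call(rbind, out)
  }
}

# Set comprehension over the two ancestral-proteome criteria.
brute_ancestral <- function(mat, roles) {
  basal <- names(roles)[roles == "basal"]
  sister <- names(roles)[roles == "sister"]
  ids <- character(0)
  for (i in seq_len(nrow(mat))) {
    in_basal <- any(sapply(basal, function(t) mat[[t]][i] > 0))
    in_sister <- any(sapply(sister, function(t) mat[[t]][i] > 0))
    if (in_basal && in_sister) ids <- c(ids, mat$orthogroup[i])
  }
  ids
}

random_alignment <- function(seed, n_seq = 10, len = 40, gap_prob = 0.05) {
  set.seed(seed)
  chars <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  tibble::tibble(
    family = "rand",
    taxon = sprintf("t%02d", seq_len(n_seq)),
    seq = replicate(n_seq, {
      s <- sample(chars, len, replace = TRUE)
      # push some columns towards conservation so the 90% rule fires
      cons <- sample(len, ceiling(len / 4))
      s[cons] <- ifelse(runif(length(cons)) < 0.93, "K", s[cons])
      gaps <- runif(len) < gap_prob
      s[gaps] <- "-"
      paste0(s, collapse = "")
    })
  )
}

random_og_matrix <- function(seed, n_og = 50) {
  set.seed(seed)
  taxa <- c("b1", "b2", "s1", "s2", "t1", "t2")
  mat <- tibble::tibble(orthogroup = sprintf("OG%04d", seq_len(n_og)))
  for (t in taxa) mat[[t]] <- as.integer(runif(n_og) < 0.7)
  roles <- c(b1 = "basal", b2 = "basal", s1 = "sister", s2 = "sister",
             t1 = "target", t2 = "target")
  list(matrix = mat, roles = roles)
}

# One planted gene in a spacer-padded genome; returns truth and search input.
plant_gene <- function(seed, divergence = 0.2) {
  cfg <- sim_config(seed = seed, n_families = 1, n_ref_taxa = 20,
                    family_length = 200, divergence = divergence)
  fams <- simulate_marker_families(cfg)
  gen <- simulate_genome(fams, cfg)
  cons <- alignment_consensus(fams$alignments)
  list(genome = gen$genome, truth = gen$genes, query = cons$query)
}
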