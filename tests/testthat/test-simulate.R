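small_cfg <- function(...) {
  defaults <- list(seed = 1, n_families = 2, n_ref_taxa = 12,
                   family_length = 60)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 42)
  f1 <- simulate_marker_families(cfg)
  f2 <- simulate_marker_families(cfg)
  expect_identical(f1, f2)
  expect_identical(simulate_genome(f1, cfg), simulate_genome(f2, cfg))
  expect_identical(simulate_orthogroups(n_orthogroups = 100, seed = 9),
                   simulate_orthogroups(n_orthogroups = 100, seed = 9))
  expect_identical(simulate_trna(4, seed = 3), simulate_trna(4, seed = 3))
})

test_that("config validation rejects bad parameters", {
  expect_error(sim_config(seed = 1, conserved_fraction = 1.2), "fraction")
  expect_error(sim_config(seed = 1, n_families = 0), "positive")
  expect_error(sim_config(seed = 1, conservation_level = 0.5), "0.9")
  expect_error(sim_config(seed = 1, gc_target = -0.1), "fraction")
})

test_that("conserved_fraction = 0 yields an empty truth table", {
  cfg <- small_cfg(seed = 2, conserved_fraction = 0)
  fams <- simulate_marker_families(cfg)
  expect_equal(nrow(fams$truth), 0)
})

test_that("planted conserved columns are a subset of an independent column scan", {
  cfg <- sim_config(seed = 7, n_families = 5, n_ref_taxa = 50,
                    family_length = 200, conserved_fraction = 0.2,
                    conservation_level = 0.95)
  fams <- simulate_marker_families(cfg)
  for (f in unique(fams$truth$family)) {
    seqs <- fams$alignments$seq[fams$alignments$family == f]
    oracle <- brute_hcaa(seqs, threshold = 0.90)
    truth <- fams$truth[fams$truth$family == f, ]
    # truth columns must all be found by the oracle, with the same residue
    expect_true(all(truth$column %in% oracle$column))
    m <- merge(truth, oracle, by = "column")
    expect_equal(m$consensus.x, m$consensus.y)
  }
})

test_that("divergence 0 and the standard code round-trip to the consensus", {
  cfg <- small_cfg(seed = 5, divergence = 0)
  fams <- simulate_marker_families(cfg)
  gen <- simulate_genome(fams, cfg)
  for (i in seq_len(nrow(gen$genes))) {
    g <- gen$genes[i, ]
    cds <- extract_gene_seqs(gen$genome, g)
    cons <- alignment_consensus(
      dplyr::filter(fams$alignments, family == g$family))$query
    expect_identical(translate_dna(cds, "standard"), cons)
  }
})

test_that("uga_trp genomes read through TGA exactly at recorded Trp sites", {
  cfg <- small_cfg(seed = 11, genetic_code = "uga_trp", family_length = 150)
  fams <- simulate_marker_families(cfg)
  gen <- simulate_genome(fams, cfg)
  expect_gt(nrow(gen$tga_sites), 0)
  for (i in seq_len(nrow(gen$genes))) {
    g <- gen$genes[i, ]
    cds <- extract_gene_seqs(gen$genome, g)
    aa11 <- translate_dna(cds, "standard")
    stops <- which(strsplit(aa11, "")[[1]] == "*")
    truth <- sort(gen$tga_sites$residue[gen$tga_sites$family == g$family])
    expect_identical(sort(stops), as.integer(truth))
    # and under the configured code the gene is stop-free
    expect_false(grepl("\\*", translate_dna(cds, "uga_trp")))
  }
})

test_that("realized genome GC tracks the target", {
  for (s in 1:3) {
    cfg <- sim_config(seed = s, n_families = 5, n_ref_taxa = 15,
                      family_length = 150, gc_target = 0.6)
    gen <- simulate_genome(simulate_marker_families(cfg), cfg)
    expect_lt(abs(gc_content(gen$genome) - 0.6), 0.05)
  }
})

test_that("unachievable GC targets raise a parameter error", {
  cfg <- small_cfg(seed = 1, gc_target = 0)
  fams <- simulate_marker_families(cfg)
  expect_error(simulate_genome(fams, cfg), "not achievable")
})

test_that("orthogroup loss model honours boundary rates", {
  none <- simulate_orthogroups(
    n_orthogroups = 40, seed = 1,
    loss_rates = setNames(rep(0, 9), names(symbiocode:::sc_default_loss_rates))
  )
  expect_true(all(as.matrix(none$matrix[-1]) == 1))
  expect_setequal(none$truth$root, none$matrix$orthogroup)

  rates <- setNames(rep(0, 9), names(symbiocode:::sc_default_loss_rates))
  rates["target1"] <- 1
  gone <- simulate_orthogroups(n_orthogroups = 40, seed = 1, loss_rates = rates)
  expect_true(all(gone$matrix$target1 == 0))
  expect_true(all(gone$matrix$target2 == 1))

  expect_error(
    simulate_orthogroups(taxa_groups = list(target = character(),
                                            sister = "s", basal = "b")),
    "non-empty"
  )
})

test_that("simulated tRNAs carry the requested anticodon stem", {
  for (bp in c(4L, 5L)) {
    tr <- simulate_trna(bp, seed = 8)
    expect_identical(anticodon_stem_length(tr$seq, tr$anticodon_start), bp)
  }
  expect_error(simulate_trna(6, seed = 1), "4 or 5")
})

test_that("truth GFF3 round-trips coordinates and attributes", {
  cfg <- small_cfg(seed = 13, genetic_code = "uga_trp")
  fams <- simulate_marker_families(cfg)
  gen <- simulate_genome(fams, cfg)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_truth_gff3(gen$genes, path, code = "uga_trp")
  back <- read_gff3(path)
  expect_equal(nrow(back), nrow(gen$genes))
  expect_equal(back$start, gen$genes$start)
  expect_equal(back$end, gen$genes$end)
  expect_equal(back$strand, gen$genes$strand)
  expect_equal(back$family, gen$genes$family)
  expect_true(all(back$code == "uga_trp"))
})
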