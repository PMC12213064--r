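toy_matrix <- function() {
  tibble::tibble(
    orthogroup = c("a", "b", "c", "d", "e"),
    b1 = c(1, 1, 1, 1, 0), b2 = c(0, 1, 0, 0, 0),
    s1 = c(1, 1, 1, 0, 1), s2 = c(0, 0, 1, 0, 0),
    t1 = c(1, 0, 0, 0, 0), t2 = c(1, 1, 0, 0, 0)
  )
}
toy_roles <- c(b1 = "basal", b2 = "basal", s1 = "sister", s2 = "sister",
               t1 = "target", t2 = "target")

test_that("both ancestral criteria are required", {
  anc <- infer_ancestral_proteome(toy_matrix(), toy_roles)
  # d: basal only -> excluded; e: sister only -> excluded
  expect_setequal(anc, c("a", "b", "c"))
  # target presence is irrelevant to membership
  m2 <- toy_matrix()
  m2$t1 <- 0
  m2$t2 <- 0
  expect_setequal(infer_ancestral_proteome(m2, toy_roles), c("a", "b", "c"))
})

test_that("role and matrix validation", {
  expect_error(infer_ancestral_proteome(toy_matrix(), c(b1 = "basal")),
               "no taxon with role 'sister'")
  bad <- toy_matrix()
  bad$orthogroup[2] <- "a"
  expect_error(infer_ancestral_proteome(bad, toy_roles), "duplicate")
})

test_that("ancestral inference equals brute-force set comprehension", {
  for (s in 1:20) {
    rm_ <- random_og_matrix(seed = s, n_og = 60)
    expect_setequal(infer_ancestral_proteome(rm_$matrix, rm_$roles),
                    brute_ancestral(rm_$matrix, rm_$roles))
  }
})

test_that("ancestral inference is invariant to row and column permutation", {
  rm_ <- random_og_matrix(seed = 5)
  anc <- infer_ancestral_proteome(rm_$matrix, rm_$roles)
  perm <- rm_$matrix[sample(nrow(rm_$matrix)),
                     c("orthogroup", sample(names(rm_$roles)))]
  expect_setequal(infer_ancestral_proteome(perm, rm_$roles), anc)
})

test_that("retention percentages truncate to one decimal", {
  mat <- tibble::tibble(
    orthogroup = sprintf("OG%04d", 1:2151),
    b1 = 1, s1 = 1,
    t1 = as.integer(seq_len(2151) <= 477),
    t2 = as.integer(seq_len(2151) <= 402)
  )
  roles <- c(b1 = "basal", s1 = "sister", t1 = "target", t2 = "target")
  anc <- infer_ancestral_proteome(mat, roles)
  expect_length(anc, 2151)
  ret <- compute_retention(mat, anc, c("t1", "t2"))
  expect_equal(ret$retained, c(477L, 402L))
  # 100*477/2151 = 22.175... and 100*402/2151 = 18.688...: truncation, not rounding
  expect_identical(ret$retention_pct, c(22.1, 18.6))
})

test_that("empty ancestral sets and zero retention are handled", {
  mat <- toy_matrix()
  ret0 <- compute_retention(mat, character(0), "t1")
  expect_equal(ret0$retained, 0L)
  expect_true(is.na(ret0$retention_pct))
  mat$t1 <- 0
  anc <- infer_ancestral_proteome(mat, toy_roles)
  ret <- compute_retention(mat, anc, "t1")
  expect_identical(ret$retention_pct, 0)
})

test_that("losses partition into shared and lineage-specific classes", {
  mat <- tibble::tibble(
    orthogroup = c("a", "b", "c"),
    b1 = 1, s1 = 1,
    t1 = c(1, 0, 0), t2 = c(1, 1, 0)
  )
  roles <- c(b1 = "basal", s1 = "sister", t1 = "target", t2 = "target")
  anc <- infer_ancestral_proteome(mat, roles)
  led <- partition_losses(mat, anc, c("t1", "t2"))
  expect_setequal(led$shared_loss, "c")
  expect_setequal(led$specific_loss$t1, "b")
  expect_length(led$specific_loss$t2, 0)
  # identical target columns leave no specific losses
  mat$t1 <- mat$t2
  led2 <- partition_losses(mat, anc, c("t1", "t2"))
  expect_equal(lengths(led2$specific_loss), c(t1 = 0L, t2 = 0L))
})

test_that("retained, shared and specific losses tile the ancestral set", {
  for (s in 1:10) {
    rm_ <- random_og_matrix(seed = 100 + s, n_og = 80)
    anc <- infer_ancestral_proteome(rm_$matrix, rm_$roles)
    led <- partition_losses(rm_$matrix, anc, c("t1", "t2"))
    for (t in c("t1", "t2")) {
      parts <- list(led$retained[[t]], led$shared_loss, led$specific_loss[[t]])
      expect_setequal(unlist(parts), anc)
      expect_equal(sum(lengths(parts)), length(anc))  # pairwise disjoint
    }
  }
})

test_that("adding a loss never raises retention", {
  rm_ <- random_og_matrix(seed = 55, n_og = 60)
  anc <- infer_ancestral_proteome(rm_$matrix, rm_$roles)
  base <- compute_retention(rm_$matrix, anc, "t1")$retention_pct
  pres <- which(rm_$matrix$t1 == 1 & rm_$matrix$orthogroup %in% anc)
  m2 <- rm_$matrix
  m2$t1[pres[1]] <- 0L
  expect_lte(compute_retention(m2, anc, "t1")$retention_pct, base)
})

test_that("simulated loss events reconcile with the ledger", {
  og <- simulate_orthogroups(n_orthogroups = 500, seed = 77)
  anc <- infer_ancestral_proteome(og$matrix, og$roles)
  led <- partition_losses(og$matrix, anc, c("target1", "target2"))
  ev <- og$truth$events
  lost_on <- function(branches) unique(ev$orthogroup[ev$branch %in% branches])
  absent1 <- union(lost_on("target_stem"), lost_on("target1"))
  absent2 <- union(lost_on("target_stem"), lost_on("target2"))
  expect_setequal(led$shared_loss, intersect(anc, intersect(absent1, absent2)))
  expect_setequal(led$specific_loss$target1,
                  intersect(anc, setdiff(absent1, absent2)))
})

test_that("category summaries conserve totals", {
  rm_ <- random_og_matrix(seed = 8, n_og = 60)
  anc <- infer_ancestral_proteome(rm_$matrix, rm_$roles)
  led <- partition_losses(rm_$matrix, anc, c("t1", "t2"))

  # everything in one category reproduces the ledger counts
  one <- tibble::tibble(orthogroup = anc, category = "all")
  tab <- summarize_categories(led, one)
  expect_equal(sum(tab$n), length(anc))
  expect_equal(tab$n[tab$class == "shared_loss"], length(led$shared_loss))

  # empty map -> everything uncategorized
  tab0 <- summarize_categories(led, NULL)
  expect_true(all(tab0$category == "uncategorized"))
  expect_equal(sum(tab0$n), length(anc))

  # random partial map: per-category sums across classes equal ancestral totals
  set.seed(1)
  cm <- tibble::tibble(
    orthogroup = sample(anc, ceiling(length(anc) / 2)),
    category = sample(c("transport", "regulation"),
                      ceiling(length(anc) / 2), replace = TRUE)
  )
  tab2 <- summarize_categories(led, cm)
  sums <- tapply(tab2$n, tab2$category, sum)
  expect_equal(unname(sums[["transport"]]),
               sum(cm$category == "transport"))
  expect_equal(sum(tab2$n), length(anc))
})

test_that("malformed category rows are skipped with a message", {
  rm_ <- random_og_matrix(seed = 9, n_og = 20)
  anc <- infer_ancestral_proteome(rm_$matrix, rm_$roles)
  led <- partition_losses(rm_$matrix, anc, c("t1", "t2"))
  cm <- tibble::tibble(orthogroup = c(anc[1], NA, ""),
                       category = c("x", "y", "z"))
  expect_message(tab <- summarize_categories(led, cm), "malformed")
  expect_equal(sum(tab$n[tab$category == "x"]), 1)
})

test_that("ledger accessors summarise consistently", {
  rm_ <- random_og_matrix(seed = 13, n_og = 40)
  anc <- infer_ancestral_proteome(rm_$matrix, rm_$roles)
  led <- partition_losses(rm_$matrix, anc, c("t1", "t2"))
  td <- tidy(led)
  expect_equal(td$retained + td$specific_loss + td$shared_loss,
               rep(length(anc), 2))
  expect_equal(glance(led)$ancestral_size, length(anc))
})

test_that("orthogroup TSV IO binarises and round-trips", {
  rm_ <- random_og_matrix(seed = 3, n_og = 15)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_orthogroup_tsv(rm_$matrix, path)
  back <- read_orthogroup_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(rm_$matrix))
})
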