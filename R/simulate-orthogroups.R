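# Synthetic orthogroup presence/absence matrices.
#
# Orthogroups present at the root of a fixed five-group cladogram
#   ((target1, target2), (sisterA, sisterB, sisterC), (basal1, basal2))
# are lost independently along each branch at per-branch rates.  A taxon
# carries an orthogroup iff no branch on its root-to-tip path lost it.  The
# default rates emulate a strongly reduced target pair: most losses on the
# shared target stem, target retention around 20%.

sc_default_taxa <- list(
  target = c("target1", "target2"),
  sister = c("sisterA", "sisterB", "sisterC"),
  basal = c("basal1", "basal2")
)

sc_default_loss_rates <- c(
  basal1 = 0.10, basal2 = 0.10,
  sister_stem = 0.05, sisterA = 0.10, sisterB = 0.10, sisterC = 0.10,
  target_stem = 0.65, target1 = 0.35, target2 = 0.45
)

#' Simulate an orthogroup presence/absence matrix under branch losses
#'
#' @param n_orthogroups Number of orthogroups present at the root.
#' @param loss_rates Named per-branch loss probabilities in \[0, 1\]; names
#'   must cover `basal1`, `basal2`, `sister_stem`, `sisterA`-`C`,
#'   `target_stem`, `target1`, `target2`.  Defaults emulate a severely
#'   reduced target pair.
#' @param seed Integer seed.
#' @param taxa_groups Named list with non-empty character vectors `target`,
#'   `sister`, `basal` (taxon names; the default five-genus-like layout).
#' @return List with `matrix` (tibble: `orthogroup` + one 0/1 column per
#'   taxon), `roles` (named character vector taxon -> role), and `truth`
#'   (list: `root` orthogroup ids, `events` tibble of per-branch losses).
#' @export
simulate_orthogroups <- function(n_orthogroups = 2151,
                                 loss_rates = sc_default_loss_rates,
                                 seed = 1,
                                 taxa_groups = sc_default_taxa) {
  if (!all(c("target", "sister", "basal") %in% names(taxa_groups)) ||
      any(lengths(taxa_groups[c("target", "sister", "basal")]) == 0)) {
    abort("taxa_groups must provide non-empty 'target', 'sister' and 'basal' groups")
  }
  if (n_orthogroups < 1) abort("n_orthogroups must be positive")
  if (any(loss_rates < 0 | loss_rates > 1)) abort("loss_rates must be in [0, 1]")

  targets <- taxa_groups$target
  sisters <- taxa_groups$sister
  basals <- taxa_groups$basal
  # branch set: one terminal branch per taxon, plus the sister and target stems
  branches <- c(basals, "sister_stem", sisters, "target_stem", targets)
  missing <- setdiff(branches, names(loss_rates))
  if (length(missing)) {
    abort(sprintf("loss_rates missing branches: %s", paste(missing, collapse = ", ")))
  }
  paths <- c(
    setNames(lapply(basals, identity), basals),
    setNames(lapply(sisters, function(s) c("sister_stem", s)), sisters),
    setNames(lapply(targets, function(t) c("target_stem", t)), targets)
  )

  set.seed(as.integer(seed))
  ids <- sprintf("OG%07d", seq_len(n_orthogroups))
  lost <- vapply(branches, function(b) {
    runif(n_orthogroups) < loss_rates[[b]]
  }, logical(n_orthogroups))
  lost <- matrix(lost, nrow = n_orthogroups,
                 dimnames = list(ids, branches))

  mat <- tibble(orthogroup = ids)
  for (tx in names(paths)) {
    on_path <- lost[, paths[[tx]], drop = FALSE]
    mat[[tx]] <- as.integer(rowSums(on_path) == 0)
  }

  events <- tibble(
    orthogroup = rep(ids, times = length(branches)),
    branch = rep(branches, each = n_orthogroups),
    lost = as.vector(lost)
  ) %>% filter(.data$lost) %>% select(-"lost")

  roles <- c(setNames(rep("target", length(targets)), targets),
             setNames(rep("sister", length(sisters)), sisters),
             setNames(rep("basal", length(basals)), basals))

  list(matrix = mat, roles = roles,
       truth = list(root = ids, events = events))
}
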