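# Minimal ancestral proteome and loss accounting.
#
# Working from an orthogroup presence/absence matrix over taxa tagged
# basal / sister / target, the minimal ancestral proteome is the set of
# orthogroups present in at least one basal taxon AND at least one sister
# taxon (target presence plays no part in the definition).  Retention of a
# target taxon is the ancestral orthogroups it still carries; losses are
# partitioned into shared (absent from every target, i.e. lost on the
# common-ancestor branch) and lineage-specific (absent from one target but
# present in another).  Retention percentages are truncated -- not rounded
# -- to one decimal, the convention that reproduces 477/2151 -> 22.1% and
# 402/2151 -> 18.6%.

normalize_roles <- function(roles) {
  if (is.data.frame(roles)) roles <- setNames(roles$role, roles$taxon)
  if (is.null(names(roles))) abort("roles must be named by taxon")
  roles
}

check_matrix_roles <- function(matrix, roles, need = c("basal", "sister")) {
  if (!"orthogroup" %in% names(matrix)) {
    abort("matrix must have an 'orthogroup' column")
  }
  if (anyDuplicated(matrix$orthogroup)) abort("duplicate orthogroup ids")
  missing_taxa <- setdiff(names(roles), names(matrix))
  if (length(missing_taxa)) {
    abort(sprintf("taxa in roles but not in matrix: %s",
                  paste(missing_taxa, collapse = ", ")))
  }
  for (r in need) {
    if (!any(roles == r)) abort(sprintf("no taxon with role '%s'", r))
  }
  invisible(TRUE)
}

present_in_any <- function(matrix, taxa) {
  if (length(taxa) == 1) {
    matrix[[taxa]] > 0
  } else {
    rowSums(as.matrix(matrix[taxa])) > 0
  }
}

#' Infer the minimal ancestral proteome
#'
#' An orthogroup belongs to the minimal ancestral set iff it is present in
#' at least one basal-group taxon and at least one sister-group taxon.
#'
#' @param matrix Presence/absence tibble: `orthogroup` column plus one 0/1
#'   (or logical) column per taxon.
#' @param roles Named character vector (or tibble `taxon`, `role`) tagging
#'   each taxon `basal`, `sister`, `target` or `other`.
#' @return Character vector of ancestral orthogroup ids.
#' @export
infer_ancestral_proteome <- function(matrix, roles) {
  roles <- normalize_roles(roles)
  check_matrix_roles(matrix, roles)
  basal <- names(roles)[roles == "basal"]
  sister <- names(roles)[roles == "sister"]
  keep <- present_in_any(matrix, basal) & present_in_any(matrix, sister)
  matrix$orthogroup[keep]
}

trunc1 <- function(x) floor(x * 10) / 10

#' Retention of the ancestral proteome in target taxa
#'
#' @param matrix Presence/absence tibble (see
#'   [infer_ancestral_proteome()]).
#' @param ancestral Character vector of ancestral orthogroup ids.
#' @param targets Target taxon names (columns of `matrix`).
#' @return Tibble with `taxon`, `retained` (count) and `retention_pct`
#'   (percentage of the ancestral set, truncated to one decimal; `NA` when
#'   the ancestral set is empty).
#' @export
compute_retention <- function(matrix, ancestral, targets) {
  if (!all(ancestral %in% matrix$orthogroup)) {
    abort("ancestral ids must be a subset of the matrix orthogroups")
  }
  anc <- matrix[matrix$orthogroup %in% ancestral, ]
  purrr::map_dfr(targets, function(t) {
    count <- sum(anc[[t]] > 0)
    tibble(
      taxon = t, retained = count,
      retention_pct = if (length(ancestral) == 0) NA_real_ else
        trunc1(100 * count / length(ancestral))
    )
  })
}

#' Partition ancestral-proteome losses into shared and lineage-specific
#'
#' @inheritParams compute_retention
#' @return A `loss_ledger`: list with `ancestral_size`, `targets`,
#'   `retention` (tibble from [compute_retention()]), `retained` (named list
#'   of orthogroup-id vectors per target), `shared_loss` (ids absent from
#'   all targets), `specific_loss` (named list: ids absent from that target
#'   but present in at least one other target).
#' @export
partition_losses <- function(matrix, ancestral, targets) {
  if (length(targets) < 1) abort("at least one target taxon is required")
  anc <- matrix[matrix$orthogroup %in% ancestral, ]
  pres <- purrr::map(targets, function(t) anc$orthogroup[anc[[t]] > 0])
  names(pres) <- targets
  absent_all <- anc$orthogroup[
    rowSums(as.matrix(anc[targets]) > 0) == 0
  ]
  specific <- purrr::map(targets, function(t) {
    setdiff(setdiff(anc$orthogroup, pres[[t]]), absent_all)
  })
  names(specific) <- targets
  structure(
    list(
      ancestral_size = length(ancestral), targets = targets,
      retention = compute_retention(matrix, ancestral, targets),
      retained = pres, shared_loss = absent_all, specific_loss = specific
    ),
    class = "loss_ledger"
  )
}

#' @export
print.loss_ledger <- function(x, ...) {
  cat(sprintf("Minimal ancestral proteome: %d orthogroups\n", x$ancestral_size))
  for (i in seq_len(nrow(x$retention))) {
    cat(sprintf("  %s: retained %d (%s%%), specific losses %d\n",
                x$retention$taxon[i], x$retention$retained[i],
                format(x$retention$retention_pct[i], nsmall = 1),
                length(x$specific_loss[[x$retention$taxon[i]]])))
  }
  cat(sprintf("  shared losses (all targets): %d\n", length(x$shared_loss)))
  invisible(x)
}

#' Tidy a loss ledger into per-target counts
#'
#' @param x A `loss_ledger`.
#' @param ... Unused.
#' @return Tibble with `taxon`, `retained`, `retention_pct`,
#'   `specific_loss`, `shared_loss`, `ancestral_size`.
#' @exportS3Method generics::tidy
tidy.loss_ledger <- function(x, ...) {
  x$retention %>%
    mutate(
      specific_loss = purrr::map_int(.data$taxon,
                                     ~ length(x$specific_loss[[.x]])),
      shared_loss = length(x$shared_loss),
      ancestral_size = x$ancestral_size
    )
}

#' One-row summary of a loss ledger
#'
#' @param x A `loss_ledger`.
#' @param ... Unused.
#' @return Tibble with `ancestral_size`, `shared_loss`, `n_targets`.
#' @exportS3Method generics::glance
glance.loss_ledger <- function(x, ...) {
  tibble(ancestral_size = x$ancestral_size,
         shared_loss = length(x$shared_loss),
         n_targets = length(x$targets))
}

# Single loss/retention class per ancestral orthogroup: retained_all,
# shared_loss, or specific_loss:<absent targets>.  These classes partition
# the ancestral set, so category tallies conserve totals.
ledger_classes <- function(ledger) {
  all_ids <- c(ledger$shared_loss,
               unique(unlist(ledger$retained)))
  cls <- setNames(rep("retained_all", length(all_ids)), all_ids)
  cls[ledger$shared_loss] <- "shared_loss"
  absent_some <- unique(unlist(ledger$specific_loss))
  for (id in absent_some) {
    lost_in <- ledger$targets[
      purrr::map_lgl(ledger$targets, ~ id %in% ledger$specific_loss[[.x]])
    ]
    cls[id] <- paste0("specific_loss:", paste(lost_in, collapse = ","))
  }
  tibble(orthogroup = names(cls), class = unname(cls))
}

#' Per-category loss/retention contingency table
#'
#' @param ledger A `loss_ledger`.
#' @param category_map Tibble (`orthogroup`, `category`), possibly partial;
#'   unmapped ancestral orthogroups are tallied as `"uncategorized"`.
#'   Malformed rows (missing fields) are skipped with a message.
#' @return Tibble `category` x `class` (`retained_all`, `shared_loss`,
#'   `specific_loss:<taxon>`) with count `n`.
#' @export
summarize_categories <- function(ledger, category_map = NULL) {
  cls <- ledger_classes(ledger)
  if (is.null(category_map) || nrow(category_map) == 0) {
    cm <- tibble(orthogroup = character(), category = character())
  } else {
    bad <- is.na(category_map$orthogroup) | is.na(category_map$category) |
      category_map$orthogroup == "" | category_map$category == ""
    if (any(bad)) {
      inform(sprintf("skipping %d malformed category row(s)", sum(bad)))
    }
    cm <- category_map[!bad, c("orthogroup", "category")]
    cm <- distinct(cm, .data$orthogroup, .keep_all = TRUE)
  }
  cls %>%
    left_join(cm, by = "orthogroup") %>%
    mutate(category = ifelse(is.na(.data$category), "uncategorized",
                             .data$category)) %>%
    count(.data$category, .data$class, name = "n")
}

#' Read an orthogroup presence/absence TSV
#'
#' Expects rows = orthogroups, columns = taxa, first column the orthogroup
#' id; any positive cell (e.g. gene counts from an OrthoFinder
#' `Orthogroups.GeneCount` table) counts as presence.
#'
#' @param path TSV file.
#' @return Tibble with `orthogroup` + one 0/1 integer column per taxon.
#' @export
read_orthogroup_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  names(df)[1] <- "orthogroup"
  for (j in setdiff(names(df), "orthogroup")) {
    df[[j]] <- as.integer(df[[j]] > 0)
  }
  as_tibble(df)
}

#' Write an orthogroup presence/absence TSV
#'
#' @param matrix Tibble with `orthogroup` + taxon columns.
#' @param path Output file.
#' @export
write_orthogroup_tsv <- function(matrix, path) {
  utils::write.table(matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a loss ledger as JSON
#'
#' @param ledger A `loss_ledger`.
#' @param path Output file.
#' @export
write_ledger_json <- function(ledger, path) {
  jsonlite::write_json(
    list(
      ancestral_size = ledger$ancestral_size,
      retention = ledger$retention,
      shared_loss = length(ledger$shared_loss),
      specific_loss = purrr::map_int(ledger$specific_loss, length)
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
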