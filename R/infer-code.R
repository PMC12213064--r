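# Genetic-code inference from the codon-observation matrix.
#
# Each codon is called independently: normalise its 20 counts to a
# probability vector, assign the dominant amino acid when evidence is
# sufficient (>= min_count observations and dominance >= 0.8 by default),
# and report every assigned codon whose meaning differs from the standard
# bacterial code (table 11) as a reassignment.  A stop codon assigned any
# amino acid is always a reassignment; unassigned stop codons are presumed
# to retain termination.  The reassignment set then selects an NCBI
# translation table: none -> 11, exactly {TGA: stop -> W} -> 4, anything
# else -> "custom".

#' Infer a genetic code from a codon-observation matrix
#'
#' @param mat A `codon_matrix` from [codon_matrix()].
#' @param min_count Minimum observations for a codon to be assigned (>= 1).
#' @param dominance Minimum probability of the modal amino acid.
#' @return A `genetic_code_call` with elements `codons` (per-codon tibble:
#'   `codon`, `standard`, `n`, `top_aa`, `top_p`, `assignment`), `probs`
#'   (long 64 x 20 probability tibble), `reassignments` (tibble: `codon`,
#'   `standard`, `inferred`), `selected_table` (`"11"`, `"4"` or
#'   `"custom"`), plus the thresholds and `total_sites` used.
#' @export
infer_genetic_code <- function(mat, min_count = 10, dominance = 0.8) {
  if (min_count < 1) abort("min_count must be >= 1")
  if (dominance <= 0 || dominance > 1) abort("dominance must be in (0, 1]")
  std <- genetic_code_table("standard")

  per_codon <- mat %>%
    group_by(.data$codon) %>%
    summarise(
      top_aa = .data$aa[which.max(.data$n)],
      top_p = ifelse(sum(.data$n) > 0, max(.data$n) / sum(.data$n), NA_real_),
      n = sum(.data$n),
      .groups = "drop"
    ) %>%
    mutate(
      standard = unname(std[.data$codon]),
      assignment = ifelse(
        .data$n >= min_count & !is.na(.data$top_p) & .data$top_p >= dominance,
        .data$top_aa, "unassigned"
      )
    ) %>%
    select("codon", "standard", "n", "top_aa", "top_p", "assignment")

  probs <- mat %>%
    group_by(.data$codon) %>%
    mutate(p = .data$n / pmax(sum(.data$n), 1L)) %>%
    ungroup() %>%
    select("codon", "aa", "p")

  reassignments <- per_codon %>%
    filter(.data$assignment != "unassigned",
           .data$assignment != .data$standard) %>%
    mutate(standard = ifelse(.data$standard == "*", "stop", .data$standard)) %>%
    select("codon", "standard", inferred = "assignment")

  call <- structure(
    list(codons = per_codon, probs = probs, reassignments = reassignments,
         min_count = min_count, dominance = dominance,
         total_sites = total_sites(mat)),
    class = "genetic_code_call"
  )
  call$selected_table <- select_translation_table(call)
  call
}

#' Select an NCBI translation table from a genetic-code call
#'
#' No reassignments selects the standard bacterial table 11; the single
#' reassignment TGA: stop -> W selects the Mycoplasma-like table 4; any
#' other reassignment set yields `"custom"` with a warning.
#'
#' @param call A `genetic_code_call` (or its `reassignments` tibble).
#' @return `"11"`, `"4"` or `"custom"`.
#' @export
select_translation_table <- function(call) {
  re <- if (inherits(call, "genetic_code_call")) call$reassignments else call
  if (nrow(re) == 0) return("11")
  if (nrow(re) == 1 && re$codon == "TGA" && re$standard == "stop" &&
      re$inferred == "W") {
    return("4")
  }
  warn(sprintf(
    "reassignment set {%s} matches no standard table; reporting 'custom'",
    paste(sprintf("%s:%s->%s", re$codon, re$standard, re$inferred),
          collapse = ", ")))
  "custom"
}

#' Per-codon amino-acid probability table (logo matrix)
#'
#' @param call A `genetic_code_call`.
#' @return Wide tibble: 64 codon rows x 20 amino-acid probability columns;
#'   rows of codons with zero observations are all zero.
#' @export
logo_matrix <- function(call) {
  tidyr::pivot_wider(call$probs, names_from = "aa", values_from = "p") %>%
    arrange(.data$codon)
}

#' @export
print.genetic_code_call <- function(x, ...) {
  cat(sprintf("Genetic code call (%d observations, min_count=%d, dominance=%.2f)\n",
              x$total_sites, x$min_count, x$dominance))
  cat(sprintf("Selected translation table: %s\n", x$selected_table))
  if (nrow(x$reassignments) == 0) {
    cat("No codon reassignments relative to the standard code.\n")
  } else {
    cat("Reassignments:\n")
    for (i in seq_len(nrow(x$reassignments))) {
      cat(sprintf("  %s: %s -> %s\n", x$reassignments$codon[i],
                  x$reassignments$standard[i], x$reassignments$inferred[i]))
    }
  }
  invisible(x)
}

#' Tidy a genetic-code call into its per-codon table
#'
#' @param x A `genetic_code_call`.
#' @param ... Unused.
#' @return The per-codon tibble (`codon`, `standard`, `n`, `top_aa`,
#'   `top_p`, `assignment`).
#' @exportS3Method generics::tidy
tidy.genetic_code_call <- function(x, ...) {
  x$codons
}

#' One-row summary of a genetic-code call
#'
#' @param x A `genetic_code_call`.
#' @param ... Unused.
#' @return Tibble with `total_sites`, `n_assigned`, `n_reassigned`,
#'   `selected_table`.
#' @exportS3Method generics::glance
glance.genetic_code_call <- function(x, ...) {
  tibble(
    total_sites = x$total_sites,
    n_assigned = sum(x$codons$assignment != "unassigned"),
    n_reassigned = nrow(x$reassignments),
    selected_table = x$selected_table
  )
}

#' Plot a genetic-code call as a probability heat map
#'
#' One tile per (codon, amino acid) with observed conditional probability;
#' codons with an assignment are marked, reassigned codons highlighted.
#'
#' @param object A `genetic_code_call`.
#' @param min_n Only codons with at least this many observations are shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.genetic_code_call <- function(object, min_n = 1, ...) {
  shown <- object$codons$codon[object$codons$n >= min_n]
  df <- filter(object$probs, .data$codon %in% shown)
  marks <- object$codons %>%
    filter(.data$codon %in% shown, .data$assignment != "unassigned") %>%
    mutate(reassigned = .data$codon %in% object$reassignments$codon)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$aa, y = .data$codon,
                                   fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(
      data = marks,
      ggplot2::aes(x = .data$assignment, y = .data$codon,
                   colour = .data$reassigned),
      inherit.aes = FALSE, shape = 1, size = 2
    ) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "white", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "amino acid", y = "codon", fill = "p(aa | codon)")
}

#' Stacked-letter probability logo for selected codons
#'
#' A per-codon stack of amino-acid letters, letter height equal to the
#' observed probability (the usual probability-unit logo, one stack per
#' codon).
#'
#' @param call A `genetic_code_call`.
#' @param codons Codons to plot (default: all with observations).
#' @return A ggplot object.
#' @export
plot_codon_logo <- function(call, codons = NULL) {
  if (is.null(codons)) {
    codons <- call$codons$codon[call$codons$n > 0]
  }
  df <- call$probs %>%
    filter(.data$codon %in% codons, .data$p > 0) %>%
    group_by(.data$codon) %>%
    arrange(desc(.data$p), .by_group = TRUE) %>%
    mutate(ymax = cumsum(.data$p), ymin = .data$ymax - .data$p,
           ymid = (.data$ymin + .data$ymax) / 2) %>%
    ungroup()
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = 0.6, xmax = 1.4,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$aa),
                       colour = "grey30", show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(x = 1, y = .data$ymid, label = .data$aa,
                                    size = .data$p),
                       show.legend = FALSE) +
    ggplot2::facet_wrap(~codon) +
    ggplot2::scale_size_continuous(range = c(2, 8), limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Export a genetic-code call as JSON
#'
#' @param call A `genetic_code_call`.
#' @param path Output file.
#' @export
write_code_call_json <- function(call, path) {
  jsonlite::write_json(
    list(
      selected_table = call$selected_table,
      total_sites = call$total_sites,
      min_count = call$min_count,
      dominance = call$dominance,
      reassignments = call$reassignments,
      codons = call$codons
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
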