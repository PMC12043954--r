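#' Rounded percentage
#'
#' `round(100 * numerator / denominator, decimals)` with R's round-half-even
#' convention, so printed percentages are reproducible.
#'
#' @param numerator,denominator Counts; `denominator` must be positive.
#' @param decimals Decimal places (default 1).
#' @return A number.
#' @examples
#' percent_of(19572, 63826)  # 30.7
#' @export
percent_of <- function(numerator, denominator, decimals = 1L) {
  if (any(denominator <= 0)) abort("denominator must be > 0")
  round(100 * numerator / denominator, decimals)
}

#' Dataset accounting report
#'
#' Closes the bookkeeping ledger of a pipeline run: derives the totals that a
#' survey reports (scaffolds, bins, units, lifestyles, clustered units,
#' non-singleton clusters, proteins, protein clusters, shared proteins,
#' host-assigned units) plus their percentages, and checks the arithmetic
#' identities that must hold between them. Violated identities are returned
#' as flags, not errors.
#'
#' @param counts Named list (or named numeric vector) of totals. Recognized
#'   names: `n_scaffolds_total`, `n_scaffolds_binned`, `n_bins_retained`,
#'   `n_unbinned_units`, `n_units_total`, `n_lytic`, `n_lysogenic`,
#'   `n_units_clustered`, `n_clusters_non_singleton`, `n_proteins`,
#'   `n_protein_clusters`, `n_shared_proteins`, `n_shared_annotated`,
#'   `n_host_assigned`, `n_single_host`, `n_multi_host`. Missing members of
#'   a complementary pair are derived from their total when possible
#'   (e.g. `n_units_total = n_bins_retained + n_unbinned_units`,
#'   `n_multi_host = n_host_assigned - n_single_host`).
#' @param decimals Decimal places for derived percentages.
#' @return An object of class `vv_report`: list with `totals` (tibble
#'   `metric`, `value`), `percentages` (tibble `metric`, `numerator`,
#'   `denominator`, `value`), and `flags` (character vector of violated
#'   identities, empty when consistent).
#' @export
build_report <- function(counts, decimals = 1L) {
  counts <- as.list(counts)
  get <- function(nm) if (is.null(counts[[nm]])) NA_real_ else as.numeric(counts[[nm]])

  derive <- function(total, a, b) {
    # fill any one missing member of total = a + b
    if (is.na(counts[[total]] %||% NA) && !is.na(get(a)) && !is.na(get(b))) {
      counts[[total]] <<- get(a) + get(b)
    } else if (is.na(get(a)) && !is.na(get(total)) && !is.na(get(b))) {
      counts[[a]] <<- get(total) - get(b)
    } else if (is.na(get(b)) && !is.na(get(total)) && !is.na(get(a))) {
      counts[[b]] <<- get(total) - get(a)
    }
  }
  derive("n_units_total", "n_bins_retained", "n_unbinned_units")
  derive("n_units_total", "n_lytic", "n_lysogenic")
  derive("n_scaffolds_total", "n_scaffolds_binned", "n_unbinned_units")
  derive("n_host_assigned", "n_single_host", "n_multi_host")

  flags <- character(0)
  check <- function(total, a, b) {
    if (!anyNA(c(get(total), get(a), get(b))) &&
        get(total) != get(a) + get(b)) {
      flags <<- c(flags, sprintf("%s != %s + %s (%g != %g + %g)",
                                 total, a, b, get(total), get(a), get(b)))
    }
  }
  check("n_units_total", "n_bins_retained", "n_unbinned_units")
  check("n_units_total", "n_lytic", "n_lysogenic")
  check("n_scaffolds_total", "n_scaffolds_binned", "n_unbinned_units")
  check("n_host_assigned", "n_single_host", "n_multi_host")

  pct <- function(metric, num, den) {
    if (anyNA(c(get(num), get(den))) || get(den) <= 0) return(NULL)
    tibble(metric = metric, numerator = get(num), denominator = get(den),
           value = percent_of(get(num), get(den), decimals))
  }
  percentages <- dplyr::bind_rows(
    pct("pct_scaffolds_binned", "n_scaffolds_binned", "n_scaffolds_total"),
    pct("pct_scaffolds_unbinned", "n_unbinned_units", "n_scaffolds_total"),
    pct("pct_units_lytic", "n_lytic", "n_units_total"),
    pct("pct_units_clustered", "n_units_clustered", "n_units_total"),
    pct("pct_shared_annotated", "n_shared_annotated", "n_shared_proteins"),
    pct("pct_host_assigned", "n_host_assigned", "n_units_total"),
    pct("pct_single_host", "n_single_host", "n_host_assigned"))

  known <- counts[!vapply(counts, function(x) is.na(as.numeric(x)[1]), logical(1))]
  totals <- tibble(metric = names(known),
                   value = vapply(known, as.numeric, numeric(1)))
  structure(list(totals = totals, percentages = percentages, flags = flags),
            class = "vv_report")
}

#' Collect report counts from pipeline artifacts
#'
#' Convenience bridge from pipeline outputs to [build_report()]: reads the
#' curation ledger, unit lifestyles, genome-cluster results, protein
#' clustering, and host assignments, and assembles the named count list.
#'
#' @param ledger Curation ledger tibble from [build_units()].
#' @param units Unit table with a `lifestyle` column.
#' @param genome_clusters Optional `vv_genome_clusters` object.
#' @param protein_clusters Optional [greedy_set_cover()] output.
#' @param assignments Optional host-assignment tibble (`unit_id`,
#'   `host_lineage`).
#' @return A named list suitable for [build_report()].
#' @export
gather_counts <- function(ledger = NULL, units = NULL, genome_clusters = NULL,
                          protein_clusters = NULL, assignments = NULL) {
  counts <- list()
  if (!is.null(ledger)) {
    counts$n_scaffolds_total <- ledger$n_scaffolds_total
    counts$n_scaffolds_binned <- ledger$n_scaffolds_binned
    counts$n_bins_retained <- ledger$n_bins_retained
    counts$n_unbinned_units <- ledger$n_unbinned_units
    counts$n_units_total <- ledger$n_units_total
  }
  if (!is.null(units)) {
    counts$n_lytic <- sum(units$lifestyle == "lytic")
    counts$n_lysogenic <- sum(units$lifestyle == "lysogenic")
    counts$n_units_total <- counts$n_units_total %||% nrow(units)
  }
  if (!is.null(genome_clusters)) {
    g <- glance(genome_clusters)
    counts$n_units_clustered <- g$n_units_clustered
    counts$n_clusters_non_singleton <- g$n_clusters_non_singleton
  }
  if (!is.null(protein_clusters)) {
    counts$n_proteins <- dplyr::n_distinct(protein_clusters$protein_id)
    counts$n_protein_clusters <- dplyr::n_distinct(protein_clusters$cluster_id)
  }
  if (!is.null(assignments)) {
    per_unit <- as_tibble(assignments) |>
      dplyr::count(.data$unit_id)
    counts$n_host_assigned <- nrow(per_unit)
    counts$n_single_host <- sum(per_unit$n == 1)
    counts$n_multi_host <- sum(per_unit$n > 1)
  }
  counts
}

#' @export
print.vv_report <- function(x, ...) {
  cat("Dataset accounting report\n")
  for (i in seq_len(nrow(x$totals))) {
    cat(sprintf("  %-28s %s\n", x$totals$metric[i],
                format(x$totals$value[i], big.mark = ",")))
  }
  if (nrow(x$percentages)) {
    cat("Percentages\n")
    for (i in seq_len(nrow(x$percentages))) {
      cat(sprintf("  %-28s %.1f%%\n", x$percentages$metric[i],
                  x$percentages$value[i]))
    }
  }
  if (length(x$flags)) {
    cat("Identity violations\n")
    for (f in x$flags) cat("  !", f, "\n")
  } else cat("All accounting identities hold.\n")
  invisible(x)
}

#' @method tidy vv_report
#' @export
tidy.vv_report <- function(x, ...) {
  dplyr::bind_rows(x$totals,
                   dplyr::select(x$percentages, "metric", "value"))
}

#' @method glance vv_report
#' @export
glance.vv_report <- function(x, ...) {
  tibble(n_metrics = nrow(x$totals) + nrow(x$percentages),
         n_flags = length(x$flags),
         consistent = length(x$flags) == 0)
}
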