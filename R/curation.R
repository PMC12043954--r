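#' Screen viral bins against the post-binning quality rules
#'
#' A vMAG (viral bin) is dissolved back into its individual scaffolds if any
#' of three rules fire: it carries two or more redundant proteins, it contains
#' two or more lysogenic scaffolds, or it has more than ten member scaffolds.
#' All triggered rules are reported.
#'
#' @param bins A data frame with one row per bin: `bin_id`, `n_scaffolds`,
#'   `redundant_protein_count`, `lysogenic_scaffold_count`.
#' @param max_scaffolds,max_redundant,max_lysogenic Rule thresholds: a bin is
#'   dissolved when `redundant_protein_count >= max_redundant`,
#'   `lysogenic_scaffold_count >= max_lysogenic`, or
#'   `n_scaffolds > max_scaffolds`.
#' @return The input tibble with `decision` (`"keep"`/`"dissolve"`) and
#'   `reasons` (comma-joined subset of `redundancy`, `lysogeny`, `size`).
#' @export
screen_bins <- function(bins, max_scaffolds = 10L, max_redundant = 2L,
                        max_lysogenic = 2L) {
  bins <- as_tibble(bins)
  if (nrow(bins) == 0) {
    return(dplyr::mutate(bins, decision = character(), reasons = character()))
  }
  stopifnot(all(c("bin_id", "n_scaffolds", "redundant_protein_count",
                  "lysogenic_scaffold_count") %in% names(bins)))
  if (any(bins$n_scaffolds < 1)) abort("empty bin: n_scaffolds must be >= 1")
  if (any(bins$lysogenic_scaffold_count > bins$n_scaffolds)) {
    abort("lysogenic_scaffold_count exceeds bin size")
  }
  red <- bins$redundant_protein_count >= max_redundant
  lys <- bins$lysogenic_scaffold_count >= max_lysogenic
  siz <- bins$n_scaffolds > max_scaffolds
  reasons <- mapply(function(r, l, s) {
    paste(c("redundancy", "lysogeny", "size")[c(r, l, s)], collapse = ",")
  }, red, lys, siz)
  dplyr::mutate(bins,
                decision = ifelse(red | lys | siz, "dissolve", "keep"),
                reasons = as.character(reasons))
}

#' Designate the lifestyle of a multi-scaffold unit
#'
#' A genome assembled from both lytic and lysogenic scaffolds is designated
#' lysogenic; only all-lytic member sets give a lytic unit.
#'
#' @param lifestyles Character vector of member-scaffold lifestyles
#'   (`"lytic"`/`"lysogenic"`), length >= 1.
#' @return `"lysogenic"` if any member is lysogenic, else `"lytic"`.
#' @export
assign_lifestyle <- function(lifestyles) {
  if (length(lifestyles) == 0) abort("a unit needs at least one member scaffold")
  bad <- setdiff(unique(lifestyles), c("lytic", "lysogenic"))
  if (length(bad)) abort(paste("unknown lifestyle:", paste(bad, collapse = ", ")))
  if (any(lifestyles == "lysogenic")) "lysogenic" else "lytic"
}

#' Link member scaffolds into one sequence with N spacers
#'
#' Concatenates scaffold sequences in the given order, inserting a run of
#' `spacer_length` `N`s between consecutive scaffolds (the convention used so
#' downstream tools can treat a multi-scaffold vMAG as a single genome).
#'
#' @param sequences Character vector of member scaffold sequences, length >= 1.
#' @param spacer_length Number of `N`s between consecutive scaffolds.
#' @return A single DNA string of length
#'   `sum(nchar(sequences)) + spacer_length * (length(sequences) - 1)`.
#' @export
link_scaffolds <- function(sequences, spacer_length = 1500L) {
  if (length(sequences) == 0) abort("a unit needs at least one member scaffold")
  paste(sequences, collapse = strrep("N", spacer_length))
}

#' Build the final set of viral analysis units
#'
#' Applies [screen_bins()] to the bin table, keeps surviving bins as linked
#' multi-scaffold units (lifestyle via [assign_lifestyle()], sequence via
#' [link_scaffolds()]), returns scaffolds of dissolved bins to the unbinned
#' pool with their own scaffold-level lifestyles, and emits every unbinned
#' scaffold as its own unit. Scaffold order within a bin follows `scaffold_id`
#' sort order.
#'
#' @param scaffolds Data frame: `scaffold_id`, `sample_id`, `lifestyle`,
#'   `sequence`.
#' @param bins Data frame with one row per bin member: `bin_id`,
#'   `scaffold_id`, `redundant_protein_count` (constant within a bin). May be
#'   empty or NULL.
#' @param spacer_length Passed to [link_scaffolds()].
#' @return A list with
#'   * `units`: tibble `unit_id`, `kind` (`"bin"`/`"unbinned_scaffold"`),
#'     `sample_id`, `lifestyle`, `total_length` (N spacers excluded),
#'     `n_scaffolds`, `sequence` (N-linked for bins)
#'   * `ledger`: one-row tibble of conservation counts
#'     (`n_scaffolds_total`, `n_scaffolds_binned`, `n_bins_input`,
#'     `n_bins_retained`, `n_bins_dissolved`, `n_unbinned_units`,
#'     `n_units_total`, `dissolved_redundancy`, `dissolved_lysogeny`,
#'     `dissolved_size`)
#'   * `screen`: the [screen_bins()] table.
#' @export
build_units <- function(scaffolds, bins = NULL, spacer_length = 1500L) {
  scaffolds <- as_tibble(scaffolds)
  stopifnot(all(c("scaffold_id", "sample_id", "lifestyle", "sequence") %in%
                  names(scaffolds)))
  if (anyDuplicated(scaffolds$scaffold_id)) abort("duplicated scaffold_id")
  bins <- if (is.null(bins)) {
    tibble(bin_id = character(), scaffold_id = character(),
           redundant_protein_count = integer())
  } else as_tibble(bins)

  if (nrow(bins) > 0) {
    if (anyDuplicated(bins$scaffold_id)) {
      abort("a scaffold is claimed by more than one bin")
    }
    if (!all(bins$scaffold_id %in% scaffolds$scaffold_id)) {
      abort("bin membership references unknown scaffolds")
    }
  }

  members <- bins |>
    dplyr::left_join(scaffolds, by = "scaffold_id") |>
    dplyr::arrange(.data$bin_id, .data$scaffold_id)

  bin_stats <- members |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::summarise(n_scaffolds = dplyr::n(),
                     redundant_protein_count = .data$redundant_protein_count[1],
                     lysogenic_scaffold_count = sum(.data$lifestyle == "lysogenic"),
                     .groups = "drop")
  screen <- screen_bins(bin_stats)
  kept_ids <- screen$bin_id[screen$decision == "keep"]

  kept <- if (length(kept_ids) == 0) {
    tibble(unit_id = character(), kind = character(), sample_id = character(),
           lifestyle = character(), total_length = integer(),
           n_scaffolds = integer(), sequence = character())
  } else members |>
    dplyr::filter(.data$bin_id %in% kept_ids) |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::summarise(
      kind = "bin",
      sample_id = .data$sample_id[1],
      lifestyle = assign_lifestyle(.data$lifestyle),
      total_length = sum(nchar(.data$sequence)),
      n_scaffolds = dplyr::n(),
      sequence = link_scaffolds(.data$sequence, spacer_length),
      .groups = "drop") |>
    dplyr::rename(unit_id = "bin_id")

  unbinned <- scaffolds |>
    dplyr::filter(!.data$scaffold_id %in% members$scaffold_id[members$bin_id %in% kept_ids]) |>
    dplyr::transmute(unit_id = .data$scaffold_id, kind = "unbinned_scaffold",
                     sample_id = .data$sample_id, lifestyle = .data$lifestyle,
                     total_length = nchar(.data$sequence), n_scaffolds = 1L,
                     sequence = .data$sequence)

  units <- dplyr::bind_rows(kept, unbinned) |> dplyr::arrange(.data$unit_id)

  dissolved <- screen |> dplyr::filter(.data$decision == "dissolve")
  ledger <- tibble(
    n_scaffolds_total = nrow(scaffolds),
    n_scaffolds_binned = sum(kept$n_scaffolds),
    n_bins_input = nrow(bin_stats),
    n_bins_retained = nrow(kept),
    n_bins_dissolved = nrow(dissolved),
    n_unbinned_units = nrow(unbinned),
    n_units_total = nrow(units),
    dissolved_redundancy = sum(grepl("redundancy", dissolved$reasons)),
    dissolved_lysogeny = sum(grepl("lysogeny", dissolved$reasons)),
    dissolved_size = sum(grepl("size", dissolved$reasons)))

  stopifnot(ledger$n_scaffolds_binned + ledger$n_unbinned_units ==
              ledger$n_scaffolds_total,
            ledger$n_units_total == ledger$n_bins_retained +
              ledger$n_unbinned_units)

  list(units = units, ledger = ledger, screen = screen)
}
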