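# Host-virus ecology: contamination screening, abundance aggregation by
# predicted host taxon, and clr-based proportionality.

#' Screen host scaffolds for exact viral contamination
#'
#' Flags a host scaffold when it contains an exact, full-length copy of any
#' viral unit sequence (100% identity over 100% of the viral sequence), on
#' either strand. Anything less than a perfect full-length copy is not
#' flagged.
#'
#' @param host_scaffolds Tibble `scaffold_id`, `sequence`.
#' @param viral_units Tibble `unit_id`, `sequence`.
#' @return Tibble of flagged pairs: `scaffold_id`, `unit_id`, `strand`.
#' @export
screen_contamination <- function(host_scaffolds, viral_units) {
  host_scaffolds <- as_tibble(host_scaffolds)
  viral_units <- as_tibble(viral_units)
  stopifnot(all(c("scaffold_id", "sequence") %in% names(host_scaffolds)),
            all(c("unit_id", "sequence") %in% names(viral_units)))
  out <- list()
  for (i in seq_len(nrow(viral_units))) {
    v <- viral_units$sequence[i]
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(v)))
    fwd <- stringr::str_detect(host_scaffolds$sequence, stringr::fixed(v))
    rev <- stringr::str_detect(host_scaffolds$sequence, stringr::fixed(rc))
    hit <- fwd | rev
    if (any(hit)) {
      out[[length(out) + 1L]] <- tibble(
        scaffold_id = host_scaffolds$scaffold_id[hit],
        unit_id = viral_units$unit_id[i],
        strand = ifelse(fwd[hit], "+", "-"))
    }
  }
  if (length(out) == 0) {
    return(tibble(scaffold_id = character(), unit_id = character(),
                  strand = character()))
  }
  dplyr::bind_rows(out)
}

parse_lineage_rank <- function(lineage, rank) {
  prefix <- c(domain = "d__", phylum = "p__", class = "c__", order = "o__",
              family = "f__", genus = "g__")[[rank]]
  parts <- strsplit(lineage, ";")
  vapply(parts, function(p) {
    p <- trimws(p)
    hit <- p[startsWith(p, prefix)]
    if (length(hit) == 0 || !nzchar(sub(prefix, "", hit[1]))) NA_character_
    else sub(prefix, "", hit[1])
  }, character(1))
}

#' Aggregate viral abundance by predicted host taxon
#'
#' Sums per-sample mapped read counts over all viral units whose predicted
#' host lineage matches each taxon at the requested rank. A virus with
#' several predicted hosts contributes its full count to each matching group
#' (`multi_host = "duplicate"`) or a `1/n_hosts` share to each
#' (`multi_host = "split"`). Units without an assignment at the rank are
#' skipped with a warning.
#'
#' @param abundance Tibble `unit_id`, `sample_id`, `mapped_read_count`.
#' @param assignments Host-assignment tibble: one row per predicted host,
#'   `unit_id`, `host_lineage` (GTDB-style `d__...;p__...;c__...` string).
#' @param rank Taxon rank to aggregate at (`domain`, `phylum`, `class`,
#'   `order`, `family`, `genus`).
#' @param multi_host `"duplicate"` (default) or `"split"`.
#' @return Tibble `group`, `sample_id`, `mapped_read_count`.
#' @export
aggregate_by_host <- function(abundance, assignments, rank = "class",
                              multi_host = c("duplicate", "split")) {
  multi_host <- match.arg(multi_host)
  abundance <- as_tibble(abundance)
  assignments <- as_tibble(assignments)
  stopifnot(all(c("unit_id", "host_lineage") %in% names(assignments)))
  assignments$group <- parse_lineage_rank(assignments$host_lineage, rank)
  n_missing <- sum(is.na(assignments$group))
  if (n_missing > 0) {
    warn(sprintf("%d host assignments lack rank '%s' and were skipped",
                 n_missing, rank))
  }
  assignments <- assignments |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::distinct(.data$unit_id, .data$group) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::mutate(share = if (multi_host == "split") 1 / dplyr::n() else 1) |>
    dplyr::ungroup()
  abundance |>
    dplyr::inner_join(assignments, by = "unit_id",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$group, .data$sample_id) |>
    dplyr::summarise(mapped_read_count = sum(.data$mapped_read_count *
                                               .data$share),
                     .groups = "drop")
}

#' Centered log-ratio transform
#'
#' `clr(x)_i = ln((x_i + pc) / g)` with `g` the geometric mean of `x + pc`;
#' the output always sums to zero and is invariant to multiplicative scaling
#' of the composition (for `pc = 0`).
#'
#' @param x Numeric vector (length >= 2) of non-negative components.
#' @param pseudocount Added to every component before taking logs; must make
#'   every component positive.
#' @return Numeric vector, same length as `x`, summing to zero.
#' @export
clr_transform <- function(x, pseudocount = 0.5) {
  if (!is.numeric(x) || length(x) < 2) abort("`x` must be numeric, length >= 2")
  if (any(!is.finite(x))) abort("`x` must be finite")
  y <- x + pseudocount
  if (any(y <= 0)) abort("components must be positive after the pseudocount")
  lg <- log(y)
  lg - mean(lg)
}

#' Proportionality (rho) of two groups on clr-transformed abundances
#'
#' Computes `rho_p = 1 - var(a_x - a_y) / (var(a_x) + var(a_y))`, where `a`
#' are the clr-transformed per-sample values of each group within the full
#' composition: all rows of `series` plus, optionally, a remainder component
#' (closure over everything else mapped in the sample). `rho_p` is symmetric
#' and lies in `[-1, 1]`; 1 means perfectly proportional abundances.
#'
#' @param series Tibble `group`, `sample_id`, `mapped_read_count` containing
#'   every group of the composition (e.g. [aggregate_by_host()] output bound
#'   to host MAG counts).
#' @param group_x,group_y The two group labels to compare.
#' @param samples Optional sample table with `total_reads`; when supplied, a
#'   `remainder` component (`total_reads` minus the summed group counts, floored
#'   at 0) is appended to the composition before the clr.
#' @param pseudocount Passed to [clr_transform()].
#' @return A one-row tibble: `group_x`, `group_y`, `rho`, `n_samples`,
#'   `pseudocount`, `undefined` (TRUE when both clr series have zero
#'   variance, in which case `rho` is NA).
#' @export
proportionality_rho <- function(series, group_x, group_y, samples = NULL,
                                pseudocount = 0.5) {
  series <- as_tibble(series)
  stopifnot(all(c("group", "sample_id", "mapped_read_count") %in%
                  names(series)))
  if (!all(c(group_x, group_y) %in% series$group)) {
    abort("group_x and group_y must be groups of `series`")
  }
  wide <- series |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = "mapped_read_count", values_fill = 0)
  if (!is.null(samples)) {
    samples <- as_tibble(samples)
    wide <- wide |>
      dplyr::left_join(dplyr::select(samples, "sample_id", "total_reads"),
                       by = "sample_id") |>
      dplyr::mutate(remainder = pmax(0, .data$total_reads -
                                       rowSums(dplyr::pick(dplyr::where(is.numeric),
                                                           -"total_reads")))) |>
      dplyr::select(-"total_reads")
  }
  comp <- as.matrix(wide[setdiff(names(wide), "sample_id")])
  if (nrow(comp) < 3) abort("rho needs at least 3 samples")
  a <- t(apply(comp, 1, clr_transform, pseudocount = pseudocount))
  colnames(a) <- colnames(comp)
  ax <- a[, group_x]
  ay <- a[, group_y]
  vx <- var(ax)
  vy <- var(ay)
  undefined <- (vx + vy) == 0
  tibble(group_x = group_x, group_y = group_y,
         rho = if (undefined) NA_real_ else 1 - var(ax - ay) / (vx + vy),
         n_samples = nrow(comp), pseudocount = pseudocount,
         undefined = undefined)
}

#' All-pairs proportionality matrix
#'
#' [proportionality_rho()] over every unordered pair of groups in `series`.
#'
#' @inheritParams proportionality_rho
#' @return Tibble with one row per pair.
#' @export
proportionality_matrix <- function(series, samples = NULL, pseudocount = 0.5) {
  groups <- sort(unique(series$group))
  if (length(groups) < 2) abort("need at least two groups")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    proportionality_rho(series, p[1], p[2], samples = samples,
                        pseudocount = pseudocount)
  })
}

#' Host-virus abundance congruence plot
#'
#' Per-sample relative abundances of two coupled groups (e.g. a host class
#' and the viruses infecting it), as paired bars.
#'
#' @param series Tibble `group`, `sample_id`, `mapped_read_count`.
#' @param groups Character vector of groups to show (default all).
#' @return A ggplot.
#' @export
plot_host_virus_abundance <- function(series, groups = NULL) {
  df <- as_tibble(series)
  if (!is.null(groups)) df <- dplyr::filter(df, .data$group %in% groups)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id,
                                   y = .data$mapped_read_count,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "sample", y = "mapped reads", fill = NULL,
                  title = "Host and virus-group abundance by sample") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
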