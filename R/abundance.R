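#' Per-sample normalized relative abundance
#'
#' Divides each unit's mapped read count by the total read count of the
#' sample it was detected in.
#'
#' @param abundance Tibble `unit_id`, `sample_id`, `mapped_read_count`.
#' @param samples Sample table with `sample_id`, `total_reads` (> 0).
#' @return The abundance tibble with a `relative_abundance` column in
#'   `[0, 1]`.
#' @export
relative_abundance <- function(abundance, samples) {
  abundance <- as_tibble(abundance)
  samples <- as_tibble(samples)
  stopifnot(all(c("unit_id", "sample_id", "mapped_read_count") %in%
                  names(abundance)))
  if (any(samples$total_reads <= 0)) abort("total_reads must be positive")
  unknown <- setdiff(abundance$sample_id, samples$sample_id)
  if (length(unknown)) abort(paste("unknown sample_id:",
                                   paste(unknown, collapse = ", ")))
  abundance |>
    dplyr::left_join(dplyr::select(samples, "sample_id", "total_reads"),
                     by = "sample_id") |>
    dplyr::mutate(relative_abundance = .data$mapped_read_count /
                    .data$total_reads) |>
    dplyr::select(-"total_reads")
}

#' Covered-fraction detection of viruses across samples
#'
#' A unit is detected in a sample when its genome is at least `min_length`
#' non-N bp long and the covered fraction of its genome in that sample is at
#' least `min_covered` (both thresholds inclusive). Self-detections (the
#' unit's own origin sample) are flagged, not dropped.
#'
#' @param abundance Tibble `unit_id`, `sample_id`, `covered_fraction` (and
#'   any count columns, carried through).
#' @param units Tibble with `unit_id`, `length` (non-N bp) and `sample_id`
#'   (origin sample of the unit).
#' @param min_length Genome length filter in bp.
#' @param min_covered Covered-fraction detection threshold.
#' @return Tibble of detection events: `unit_id`, `origin_sample`,
#'   `detecting_sample`, `covered_fraction`, `self_detection`.
#' @export
detect_viruses <- function(abundance, units, min_length = 3000L,
                           min_covered = 0.70) {
  abundance <- as_tibble(abundance)
  units <- as_tibble(units)
  stopifnot(all(c("unit_id", "sample_id", "covered_fraction") %in%
                  names(abundance)),
            all(c("unit_id", "length", "sample_id") %in% names(units)))
  if (any(abundance$covered_fraction < 0 | abundance$covered_fraction > 1)) {
    abort("covered_fraction must be in [0, 1]")
  }
  abundance |>
    dplyr::inner_join(dplyr::select(units, "unit_id", "length",
                                    origin_sample = "sample_id"),
                      by = "unit_id") |>
    dplyr::filter(.data$length >= min_length,
                  .data$covered_fraction >= min_covered) |>
    dplyr::transmute(unit_id = .data$unit_id,
                     origin_sample = .data$origin_sample,
                     detecting_sample = .data$sample_id,
                     covered_fraction = .data$covered_fraction,
                     self_detection = .data$origin_sample ==
                       .data$detecting_sample)
}

#' Cross-site sharing summary of detection events
#'
#' Counts non-self detection events by (origin field, detecting field) pair
#' and by habitat relation; inter-field versus intra-field events are
#' flagged, and plume-deposit crossings are counted separately.
#'
#' @param events Detection events from [detect_viruses()].
#' @param samples Sample table (`sample_id`, `vent_field`, `habitat`).
#' @return List with `field_pairs` (tibble `origin_field`,
#'   `detecting_field`, `n`, `inter_field`), `habitat_pairs` (tibble
#'   `origin_habitat`, `detecting_habitat`, `n`, `plume_deposit`), and
#'   scalar counts `n_cross_sample`, `n_inter_field`, `n_plume_deposit`,
#'   `n_units_plume_deposit`.
#' @export
sharing_summary <- function(events, samples) {
  events <- as_tibble(events)
  samples <- as_tibble(samples)
  unknown <- setdiff(union(events$origin_sample, events$detecting_sample),
                     samples$sample_id)
  if (length(unknown)) abort(paste("unknown sample_id:",
                                   paste(unknown, collapse = ", ")))
  meta <- dplyr::select(samples, "sample_id", "vent_field", "habitat")
  cross <- events |>
    dplyr::filter(!.data$self_detection) |>
    dplyr::left_join(meta, by = c(origin_sample = "sample_id")) |>
    dplyr::rename(origin_field = "vent_field", origin_habitat = "habitat") |>
    dplyr::left_join(meta, by = c(detecting_sample = "sample_id")) |>
    dplyr::rename(detecting_field = "vent_field",
                  detecting_habitat = "habitat")
  field_pairs <- cross |>
    dplyr::count(.data$origin_field, .data$detecting_field) |>
    dplyr::mutate(inter_field = .data$origin_field != .data$detecting_field)
  habitat_pairs <- cross |>
    dplyr::count(.data$origin_habitat, .data$detecting_habitat) |>
    dplyr::mutate(plume_deposit =
                    (.data$origin_habitat == "plume" &
                       .data$detecting_habitat == "deposit") |
                    (.data$origin_habitat == "deposit" &
                       .data$detecting_habitat == "plume"))
  pd <- cross |>
    dplyr::filter((.data$origin_habitat == "plume" &
                     .data$detecting_habitat == "deposit") |
                    (.data$origin_habitat == "deposit" &
                       .data$detecting_habitat == "plume"))
  list(field_pairs = field_pairs,
       habitat_pairs = habitat_pairs,
       n_cross_sample = nrow(cross),
       n_inter_field = sum(cross$origin_field != cross$detecting_field),
       n_plume_deposit = nrow(pd),
       n_units_plume_deposit = dplyr::n_distinct(pd$unit_id))
}
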