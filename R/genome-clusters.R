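#' Mean intra-cluster ANI
#'
#' For each cluster, the arithmetic mean of `ani` over all stored edges whose
#' two endpoints are members; member pairs without a stored edge do not enter
#' the mean. Clusters of two or more members with no stored edge get
#' `NA` and are flagged.
#'
#' @param members Tibble with `cluster_id`, `unit_id`.
#' @param edges Tibble with `unit_a`, `unit_b`, `ani`.
#' @return Tibble `cluster_id`, `n_members`, `n_edges`, `mean_intra_ani`,
#'   `no_intra_edges`.
#' @export
summarize_clusters <- function(members, edges) {
  members <- as_tibble(members)
  edges <- as_tibble(edges)
  unit_cluster <- setNames(members$cluster_id, members$unit_id)
  intra <- edges |>
    dplyr::mutate(ca = unname(unit_cluster[.data$unit_a]),
                  cb = unname(unit_cluster[.data$unit_b])) |>
    dplyr::filter(!is.na(.data$ca), .data$ca == .data$cb) |>
    dplyr::group_by(cluster_id = .data$ca) |>
    dplyr::summarise(n_edges = dplyr::n(), mean_intra_ani = mean(.data$ani),
                     .groups = "drop")
  members |>
    dplyr::count(.data$cluster_id, name = "n_members") |>
    dplyr::left_join(intra, by = "cluster_id") |>
    dplyr::mutate(n_edges = dplyr::coalesce(.data$n_edges, 0L),
                  no_intra_edges = .data$n_members >= 2 & .data$n_edges == 0)
}

#' Classify clusters geographically
#'
#' A cluster is `inter_field` if its members span at least two vent fields,
#' else `intra_field` if they span at least two sites within one field, else
#' `endemic_site`. `cross_habitat` is `TRUE` when members include both a
#' plume and a deposit sample.
#'
#' @param members Tibble with `cluster_id`, `unit_id`, `sample_id`.
#' @param samples Sample table with `sample_id`, `vent_field`, `site`,
#'   `habitat`.
#' @return Tibble `cluster_id`, `n_members`, `n_fields`, `n_sites`,
#'   `geo_class`, `cross_habitat`.
#' @export
classify_clusters <- function(members, samples) {
  members <- as_tibble(members)
  samples <- as_tibble(samples)
  unknown <- setdiff(members$sample_id, samples$sample_id)
  if (length(unknown)) {
    abort(paste("unknown sample_id:", paste(unknown, collapse = ", ")))
  }
  members |>
    dplyr::left_join(dplyr::select(samples, "sample_id", "vent_field", "site",
                                   "habitat"), by = "sample_id") |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      n_fields = dplyr::n_distinct(.data$vent_field),
      n_sites = dplyr::n_distinct(.data$site),
      cross_habitat = "plume" %in% .data$habitat && "deposit" %in% .data$habitat,
      .groups = "drop") |>
    dplyr::mutate(geo_class = dplyr::case_when(
      .data$n_fields >= 2 ~ "inter_field",
      .data$n_sites >= 2 ~ "intra_field",
      TRUE ~ "endemic_site")) |>
    dplyr::select("cluster_id", "n_members", "n_fields", "n_sites",
                  "geo_class", "cross_habitat")
}

#' ANI-based genome clustering pipeline
#'
#' Runs the whole nucleotide-clustering stage: all-vs-all fragment ANI
#' ([ani_edges()]), aligned-fraction normalization and screening
#' ([normalize_and_screen()]), Markov clustering ([mcl()]) on the normalized
#' scores, intra-cluster ANI summaries ([summarize_clusters()]) and
#' geographic classification ([classify_clusters()]). Units that survive no
#' screened edge enter the result as singletons (`geo_class` `endemic_site`).
#'
#' @param units Data frame with `unit_id`, `sample_id`, `sequence`.
#' @param samples Sample table (`sample_id`, `vent_field`, `site`, `habitat`).
#' @param min_length Minimum non-N genome length (bp).
#' @param min_score Normalized-score screen.
#' @param inflation MCL inflation.
#' @param ... Further arguments to [ani_edges()] or [mcl()].
#' @return An object of class `vv_genome_clusters`: list with `members`
#'   (tibble `cluster_id`, `unit_id`, `sample_id`, `singleton`), `summary`
#'   (per cluster: size, mean intra-cluster ANI, `geo_class`,
#'   `cross_habitat`), `edges` (raw), `screened_edges`, and the `vv_mcl`
#'   object. [tidy()] returns the member table joined to the summary,
#'   [glance()] counts clusters by class.
#' @export
cluster_genomes <- function(units, samples, min_length = 3000L,
                            min_score = 0.70, inflation = 2, ...) {
  units <- as_tibble(units)
  stopifnot(all(c("unit_id", "sample_id", "sequence") %in% names(units)))
  dots <- list(...)
  ani_args <- dots[intersect(names(dots),
                             c("fragment_length", "k", "min_fragment_identity"))]
  mcl_args <- dots[intersect(names(dots),
                             c("expansion", "prune_threshold", "max_iterations",
                               "convergence_tolerance", "self_loop_weight"))]
  edges <- do.call(ani_edges, c(list(units = units, min_length = min_length),
                                ani_args))
  screened <- normalize_and_screen(edges, min_score = min_score)

  eligible <- units$unit_id[vapply(units$sequence, non_n_length, integer(1),
                                   USE.NAMES = FALSE) >= min_length]
  fit <- do.call(mcl, c(list(edges = dplyr::transmute(screened,
                                                      from = .data$unit_a,
                                                      to = .data$unit_b,
                                                      weight = .data$score),
                             inflation = inflation, nodes = eligible),
                        mcl_args))

  members <- tidy(fit) |>
    dplyr::transmute(cluster_id = sprintf("cluster_%04d", .data$cluster),
                     unit_id = .data$node) |>
    dplyr::left_join(dplyr::select(units, "unit_id", "sample_id"),
                     by = "unit_id") |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::mutate(singleton = dplyr::n() == 1) |>
    dplyr::ungroup()

  summary <- summarize_clusters(dplyr::select(members, "cluster_id", "unit_id"),
                                edges) |>
    dplyr::left_join(classify_clusters(members, samples), by = "cluster_id") |>
    dplyr::select("cluster_id", n_members = "n_members.x", "n_fields",
                  "n_sites", "mean_intra_ani", "no_intra_edges", "geo_class",
                  "cross_habitat")

  structure(list(members = members, summary = summary, edges = edges,
                 screened_edges = screened, mcl = fit),
            class = "vv_genome_clusters")
}

#' @method tidy vv_genome_clusters
#' @export
tidy.vv_genome_clusters <- function(x, ...) {
  dplyr::left_join(x$members, x$summary, by = "cluster_id")
}

#' @method glance vv_genome_clusters
#' @export
glance.vv_genome_clusters <- function(x, ...) {
  s <- x$summary
  non_singleton <- s |> dplyr::filter(.data$n_members >= 2)
  tibble(n_units = nrow(x$members),
         n_clusters_non_singleton = nrow(non_singleton),
         n_units_clustered = sum(non_singleton$n_members),
         n_singletons = sum(s$n_members == 1),
         n_inter_field = sum(non_singleton$geo_class == "inter_field"),
         n_intra_field = sum(non_singleton$geo_class == "intra_field"),
         n_cross_habitat = sum(non_singleton$cross_habitat))
}

#' Cluster geography overview plot
#'
#' Bar chart of non-singleton genome clusters by geographic class.
#'
#' @param object A `vv_genome_clusters` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vv_genome_clusters
#' @export
autoplot.vv_genome_clusters <- function(object, ...) {
  df <- object$summary |>
    dplyr::filter(.data$n_members >= 2) |>
    dplyr::count(.data$geo_class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$geo_class, y = .data$n,
                                   fill = .data$geo_class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "non-singleton clusters",
                  title = "Genome clusters by geographic class") +
    ggplot2::theme_minimal()
}
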