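# Protein clustering by greedy set cover on an identity/coverage similarity
# graph, with cross-site sharing statistics and annotation resolution.

#' All-vs-all protein similarity edges
#'
#' Aligns every unordered pair of proteins (local alignment, BLOSUM62) and
#' keeps an edge when aligned-column identity and the coverage of *both*
#' partners (aligned span over sequence length, the bidirectional
#' "cov-mode 0" convention) pass their thresholds. Exact pairwise alignment is
#' quadratic in the number of proteins and meant for datasets up to a few
#' thousand sequences.
#'
#' @param proteins Data frame with `protein_id` and `sequence` (amino acids).
#' @param min_identity Minimum aligned-column identity (fraction).
#' @param min_cov Minimum coverage of query and of target (fraction).
#' @return Tibble `query`, `target`, `identity`, `cov_query`, `cov_target`.
#' @export
protein_similarity <- function(proteins, min_identity = 0.75, min_cov = 0.80) {
  proteins <- as_tibble(proteins)
  stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
  if (anyDuplicated(proteins$protein_id)) abort("duplicated protein_id")
  if (any(!nzchar(proteins$sequence))) abort("empty protein sequence")
  proteins <- dplyr::arrange(proteins, .data$protein_id)
  n <- nrow(proteins)
  if (n < 2) {
    return(tibble(query = character(), target = character(),
                  identity = numeric(), cov_query = numeric(),
                  cov_target = numeric()))
  }
  seqs <- Biostrings::AAStringSet(proteins$sequence)
  names(seqs) <- proteins$protein_id
  out <- list()
  for (i in seq_len(n - 1)) {
    subjects <- seqs[(i + 1):n]
    alns <- Biostrings::pairwiseAlignment(
      subjects, seqs[[i]], type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
    identity <- Biostrings::nmatch(alns) / Biostrings::nchar(alns)
    pat <- Biostrings::pattern(alns)   # spans on the subjects vector
    sub <- Biostrings::subject(alns)   # spans on query i
    cov_t <- (Biostrings::end(pat) - Biostrings::start(pat) + 1) /
      Biostrings::width(subjects)
    cov_q <- (Biostrings::end(sub) - Biostrings::start(sub) + 1) /
      Biostrings::width(seqs[i])
    keep <- identity >= min_identity & cov_q >= min_cov & cov_t >= min_cov
    if (any(keep)) {
      out[[length(out) + 1L]] <- tibble(
        query = proteins$protein_id[i],
        target = names(subjects)[keep],
        identity = identity[keep],
        cov_query = cov_q[keep],
        cov_target = cov_t[keep])
    }
  }
  if (length(out) == 0) {
    return(tibble(query = character(), target = character(),
                  identity = numeric(), cov_query = numeric(),
                  cov_target = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Greedy set-cover clustering of proteins
#'
#' Iteratively selects the unclustered protein with the most unclustered
#' neighbors (ties broken by lexicographically smallest `protein_id`) as a
#' cluster representative and absorbs those neighbors into its cluster, until
#' every protein is assigned. Proteins with no surviving edges become
#' singleton clusters.
#'
#' @param edges Similarity edges (`query`, `target`), e.g. from
#'   [protein_similarity()].
#' @param proteins Data frame with `protein_id` (and optionally `unit_id`,
#'   `sample_id`, carried through).
#' @return Tibble with one row per protein: `cluster_id`, `representative`,
#'   `protein_id` plus any carried metadata columns.
#' @export
greedy_set_cover <- function(edges, proteins) {
  proteins <- as_tibble(proteins)
  stopifnot("protein_id" %in% names(proteins))
  ids <- sort(proteins$protein_id)
  edges <- as_tibble(edges)
  bad <- setdiff(union(edges$query, edges$target), ids)
  if (length(bad)) abort(paste("edges reference unknown proteins:",
                               paste(head(bad, 3), collapse = ", ")))
  adj <- lapply(setNames(vector("list", length(ids)), ids), function(x) character(0))
  for (i in seq_len(nrow(edges))) {
    q <- edges$query[i]; t <- edges$target[i]
    if (q == t) next
    adj[[q]] <- c(adj[[q]], t)
    adj[[t]] <- c(adj[[t]], q)
  }
  adj <- lapply(adj, unique)
  unclustered <- setNames(rep(TRUE, length(ids)), ids)
  assignment <- character(0)
  rep_of <- character(0)
  k <- 0L
  while (any(unclustered)) {
    free <- names(unclustered)[unclustered]
    deg <- vapply(free, function(p) sum(unclustered[adj[[p]]]), numeric(1))
    rep_id <- free[order(-deg, free)][1]
    members <- c(rep_id, adj[[rep_id]][unclustered[adj[[rep_id]]]])
    k <- k + 1L
    cid <- sprintf("pc_%05d", k)
    assignment[members] <- cid
    rep_of[cid] <- rep_id
    unclustered[members] <- FALSE
  }
  tibble(protein_id = names(assignment),
         cluster_id = unname(assignment),
         representative = unname(rep_of[assignment])) |>
    dplyr::left_join(proteins, by = "protein_id") |>
    dplyr::arrange(.data$cluster_id, .data$protein_id)
}

#' Cross-site shared protein-cluster statistics
#'
#' A protein cluster is shared by a group of sites when it contains at least
#' one member from every site in the group. The percent of shared clusters
#' for a group is the shared count divided by the smallest per-site total
#' (number of clusters containing that site), times 100. Also reports, for
#' each group, whether it mixes habitats (e.g. deposit and plume sites).
#'
#' @param clusters Cluster membership tibble with `cluster_id` and
#'   `sample_id` per member (e.g. [greedy_set_cover()] output joined to
#'   protein metadata).
#' @param samples Sample table (`sample_id`, `site`, `habitat`).
#' @param groups List of character vectors of sites; default all site pairs
#'   present in the data.
#' @return Tibble `group`, `n_sites`, `shared_clusters`, `min_site_total`,
#'   `percent_shared` (NA and flagged `undefined` when a site has no
#'   clusters), `cross_habitat`.
#' @export
shared_cluster_stats <- function(clusters, samples, groups = NULL) {
  clusters <- as_tibble(clusters)
  samples <- as_tibble(samples)
  stopifnot(all(c("cluster_id", "sample_id") %in% names(clusters)))
  unknown <- setdiff(clusters$sample_id, samples$sample_id)
  if (length(unknown)) abort(paste("unknown sample_id:",
                                   paste(unknown, collapse = ", ")))
  site_of <- setNames(samples$site, samples$sample_id)
  habitat_of <- setNames(samples$habitat, samples$site)
  memb <- clusters |>
    dplyr::mutate(site = unname(site_of[.data$sample_id])) |>
    dplyr::distinct(.data$cluster_id, .data$site)
  sites_present <- sort(unique(memb$site))
  if (is.null(groups)) {
    if (length(sites_present) < 2) {
      return(tibble(group = character(), n_sites = integer(),
                    shared_clusters = integer(), min_site_total = integer(),
                    percent_shared = numeric(), undefined = logical(),
                    cross_habitat = logical()))
    }
    cmb <- utils::combn(sites_present, 2, simplify = FALSE)
    groups <- cmb
  }
  totals <- memb |> dplyr::count(.data$site, name = "total")
  total_of <- setNames(totals$total, totals$site)
  cluster_sites <- split(memb$site, memb$cluster_id)
  purrr::map_dfr(groups, function(g) {
    g <- sort(unique(g))
    bad <- setdiff(g, samples$site)
    if (length(bad)) abort(paste("unknown site:", paste(bad, collapse = ", ")))
    shared <- sum(vapply(cluster_sites, function(s) all(g %in% s), logical(1)))
    site_totals <- unname(total_of[g])
    site_totals[is.na(site_totals)] <- 0L
    undefined <- any(site_totals == 0)
    tibble(group = paste(g, collapse = "+"),
           n_sites = length(g),
           shared_clusters = as.integer(shared),
           min_site_total = as.integer(min(site_totals)),
           percent_shared = if (undefined) NA_real_ else
             100 * shared / min(site_totals),
           undefined = undefined,
           cross_habitat = dplyr::n_distinct(habitat_of[g]) > 1 &&
             all(c("plume", "deposit") %in% habitat_of[g]))
  })
}

#' Resolve the best-supported annotation per protein
#'
#' Across hits from the KEGG/VOG/Pfam databases, the best hit has the highest
#' bit score, ties broken by lowest e-value, then by highest viral score.
#' Proteins with no hits are absent from the output (counted hypothetical).
#'
#' @param hits Tibble with `protein_id`, `database`, `label`, `bit_score`,
#'   `e_value`, and optionally `viral_score`.
#' @return One row per annotated protein, the winning hit.
#' @export
resolve_best_annotation <- function(hits) {
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) return(hits)
  stopifnot(all(c("protein_id", "bit_score", "e_value") %in% names(hits)))
  if (any(hits$e_value < 0)) abort("e_value must be >= 0")
  if (!"viral_score" %in% names(hits)) hits$viral_score <- NA_real_
  hits |>
    dplyr::arrange(.data$protein_id, dplyr::desc(.data$bit_score),
                   .data$e_value,
                   dplyr::desc(dplyr::coalesce(.data$viral_score, -Inf))) |>
    dplyr::distinct(.data$protein_id, .keep_all = TRUE)
}

#' Filter and resolve PHROG-style hits
#'
#' Hits failing coverage >= `min_cov` or identity >= `min_identity` are
#' dropped; among survivors the best hit per protein has the smallest
#' e-value, ties broken by largest bit score.
#'
#' @param hits Tibble with `protein_id`, `coverage`, `identity`, `e_value`,
#'   `bit_score`.
#' @param min_cov,min_identity Fraction thresholds.
#' @return One row per protein that retains any surviving hit.
#' @export
filter_phrog_hits <- function(hits, min_cov = 0.80, min_identity = 0.75) {
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) return(hits)
  stopifnot(all(c("protein_id", "coverage", "identity", "e_value",
                  "bit_score") %in% names(hits)))
  hits |>
    dplyr::filter(.data$coverage >= min_cov, .data$identity >= min_identity) |>
    dplyr::arrange(.data$protein_id, .data$e_value,
                   dplyr::desc(.data$bit_score)) |>
    dplyr::distinct(.data$protein_id, .keep_all = TRUE)
}

#' Normalized annotation-count matrix by site
#'
#' For clustered, annotated proteins, counts proteins per (site, functional
#' category) and divides by the total number of annotated clustered proteins
#' at that site, so each site's row sums to one. Sites with zero annotated
#' clustered proteins get an all-`NA` row and are flagged.
#'
#' @param best_hits Best-annotation table (`protein_id`, `label`), e.g.
#'   [resolve_best_annotation()] output.
#' @param clusters Cluster membership (`protein_id`, `cluster_id`,
#'   `sample_id`).
#' @param samples Sample table (`sample_id`, `site`).
#' @param categories Label-to-category map (`label`, `category`); labels
#'   without a mapping fall in category `"other"`. Defaults to the table
#'   shipped in `inst/extdata/function_categories.tsv`.
#' @return Tibble `site`, `category`, `n`, `fraction`, `undefined`.
#' @export
normalize_annotation_counts <- function(best_hits, clusters, samples,
                                        categories = NULL) {
  if (is.null(categories)) {
    categories <- readr::read_tsv(
      system.file("extdata", "function_categories.tsv",
                  package = "ventviromics"),
      show_col_types = FALSE)
  }
  best_hits <- as_tibble(best_hits)
  clusters <- as_tibble(clusters)
  samples <- as_tibble(samples)
  annotated <- clusters |>
    dplyr::inner_join(dplyr::select(best_hits, "protein_id", "label"),
                      by = "protein_id") |>
    dplyr::left_join(dplyr::select(samples, "sample_id", "site"),
                     by = "sample_id") |>
    dplyr::left_join(categories, by = "label") |>
    dplyr::mutate(category = dplyr::coalesce(.data$category, "other"))
  all_sites <- sort(unique(samples$site))
  counts <- annotated |>
    dplyr::count(.data$site, .data$category) |>
    dplyr::group_by(.data$site) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n), undefined = FALSE) |>
    dplyr::ungroup()
  empty <- setdiff(all_sites, counts$site)
  if (length(empty)) {
    counts <- dplyr::bind_rows(counts,
                               tibble(site = empty, category = NA_character_,
                                      n = 0L, fraction = NA_real_,
                                      undefined = TRUE))
  }
  dplyr::arrange(counts, .data$site, .data$category)
}

#' Shared-protein heatmap-style plot
#'
#' Tile plot of percent shared protein clusters per site pair.
#'
#' @param stats Output of [shared_cluster_stats()] over site pairs.
#' @return A ggplot.
#' @export
plot_shared_clusters <- function(stats) {
  df <- stats |>
    tidyr::separate(.data$group, into = c("site_a", "site_b"), sep = "\\+",
                    extra = "merge")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site_a, y = .data$site_b,
                                   fill = .data$percent_shared)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "% shared") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Shared protein clusters between sites") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
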