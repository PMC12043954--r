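rand_aa <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I",
                                        "K", "L", "M", "N", "P", "Q", "R", "S",
                                        "T", "V", "W", "Y"), n, replace = TRUE),
                               collapse = ""))
}

mutate_aa <- function(seq, rate, seed) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  withr::with_seed(seed, {
    chars <- strsplit(seq, "")[[1]]
    hits <- which(runif(length(chars)) < rate)
    chars[hits] <- vapply(chars[hits],
                          function(c) sample(setdiff(aa, c), 1), character(1))
    paste(chars, collapse = "")
  })
}

test_that("protein similarity applies identity and bidirectional coverage", {
  p <- rand_aa(100, seed = 1)
  proteins <- tibble::tibble(
    protein_id = c("full", "twin", "frag", "mut", "far"),
    sequence = c(p, p, substring(p, 16, 85), mutate_aa(p, 0.10, seed = 2),
                 rand_aa(100, seed = 3)))
  edges <- protein_similarity(proteins)
  key <- paste(edges$query, edges$target)

  twin <- edges[key %in% c("full twin", "twin full"), ]
  expect_equal(nrow(twin), 1)
  expect_equal(twin$identity, 1)
  expect_equal(twin$cov_query, 1)
  expect_equal(twin$cov_target, 1)

  # 70-aa fragment: its own coverage is ~1 but the full protein's is 0.70
  expect_false(any(grepl("frag", key)))

  mut <- edges[key %in% c("full mut", "mut full"), ]
  expect_equal(nrow(mut), 1)
  expect_lt(abs(mut$identity - 0.90), 0.05)

  expect_false(any(grepl("far", key)))
  expect_error(protein_similarity(tibble::tibble(protein_id = "x", sequence = "")),
               "empty")
})

test_that("greedy set cover follows the max-degree absorption rule", {
  star <- tibble::tibble(query = c("ctr", "ctr", "ctr"),
                         target = c("l1", "l2", "l3"))
  prot <- tibble::tibble(protein_id = c("ctr", "l1", "l2", "l3"))
  out <- greedy_set_cover(star, prot)
  expect_equal(dplyr::n_distinct(out$cluster_id), 1)
  expect_equal(unique(out$representative), "ctr")

  path <- greedy_set_cover(tibble::tibble(query = c("a", "b"), target = c("b", "c")),
                           tibble::tibble(protein_id = c("a", "b", "c")))
  expect_equal(dplyr::n_distinct(path$cluster_id), 1)
  expect_equal(unique(path$representative), "b")

  # two triangles sharing vertex v: v has degree 4 and absorbs everything
  tri2 <- tibble::tibble(query = c("v", "v", "a", "v", "v", "c"),
                         target = c("a", "b", "b", "c", "d", "d"))
  out2 <- greedy_set_cover(tri2, tibble::tibble(protein_id = c("v", "a", "b", "c", "d")))
  expect_equal(dplyr::n_distinct(out2$cluster_id), 1)
  expect_equal(unique(out2$representative), "v")

  # isolated proteins become singletons; degree ties break lexicographically
  iso <- greedy_set_cover(tibble::tibble(query = "p1", target = "p2"),
                          tibble::tibble(protein_id = c("p1", "p2", "p3")))
  expect_equal(sort(unique(iso$cluster_id[iso$protein_id == "p3"])),
               setdiff(unique(iso$cluster_id), iso$cluster_id[iso$protein_id == "p1"]))
  expect_equal(iso$representative[iso$protein_id == "p2"], "p1")
})

test_that("greedy set cover is a deterministic partition on random graphs", {
  for (seed in 1:20) {
    g <- random_graph(n = sample(8:20, 1), p = 0.25, seed = 500 + seed,
                      prefix = "p")
    prot <- tibble::tibble(protein_id = g$nodes)
    edges <- dplyr::rename(g$edges, query = from, target = to)
    a <- greedy_set_cover(edges, prot)
    b <- greedy_set_cover(edges, prot)
    expect_identical(a, b)
    expect_setequal(a$protein_id, g$nodes)
    expect_equal(anyDuplicated(a$protein_id), 0)
    # representative is a member of its own cluster
    reps <- dplyr::distinct(a, cluster_id, representative)
    membership <- stats::setNames(a$cluster_id, a$protein_id)
    expect_true(all(membership[reps$representative] == reps$cluster_id))
  }
})

test_that("shared cluster statistics follow the smallest-total formula", {
  samples <- tibble::tibble(sample_id = c("sX", "sY", "sZ"),
                            site = c("X", "Y", "Z"),
                            habitat = c("deposit", "plume", "deposit"),
                            total_reads = 1e6L)
  clusters <- tibble::tibble(
    cluster_id = c("c1", "c1", "c2", "c3", "c4", "c4", "c5"),
    sample_id = c("sX", "sY", "sX", "sY", "sX", "sY", "sX"))
  out <- shared_cluster_stats(clusters, samples, groups = list(c("X", "Y")))
  # shared: c1 and c4; totals X = 4, Y = 3 -> 2 / 3 * 100
  expect_equal(out$shared_clusters, 2L)
  expect_equal(out$min_site_total, 3L)
  expect_equal(out$percent_shared, 200 / 3)
  expect_true(out$cross_habitat)

  # direct formula case: shared 10 of totals {100, 50} -> 20%
  big <- tibble::tibble(
    cluster_id = c(sprintf("s%02d", 1:10), sprintf("x%03d", 1:90),
                   sprintf("s%02d", 1:10), sprintf("y%02d", 1:40)),
    sample_id = c(rep("sX", 100), rep("sY", 50)))
  expect_equal(shared_cluster_stats(big, samples,
                                    groups = list(c("X", "Y")))$percent_shared, 20)

  # site with zero clusters: undefined, flagged
  none <- shared_cluster_stats(clusters, samples, groups = list(c("X", "Z")))
  expect_true(none$undefined)
  expect_true(is.na(none$percent_shared))
  expect_error(shared_cluster_stats(clusters, samples, groups = list(c("X", "Q"))),
               "unknown site")
})

test_that("planted shared protein families are recovered as shared clusters", {
  cfg <- sim_config(n_fields = 1, sites_per_field = 2, genomes_per_site = 2,
                    planted_inter_field_clusters = 0,
                    planted_intra_field_clusters = 0,
                    genome_length_range = c(3000, 3200),
                    shared_protein_family_fraction = 1,
                    n_core_protein_families = 3, seed = 61)
  comm <- simulate_community(cfg)
  edges <- protein_similarity(comm$proteins)
  clusters <- greedy_set_cover(edges, comm$proteins)
  stats <- shared_cluster_stats(clusters, comm$samples)
  # every unit carries all 3 families, so the site pair shares >= 3 clusters
  expect_gte(stats$shared_clusters[1], 3)
  # each planted family ends up in one cluster (metadata is carried through)
  fam <- dplyr::filter(clusters, !is.na(family_id))
  per_family <- fam |> dplyr::group_by(family_id) |>
    dplyr::summarise(n_clusters = dplyr::n_distinct(cluster_id))
  expect_true(all(per_family$n_clusters == 1))
})

test_that("best annotations resolve by bit score, e-value, then viral score", {
  hits <- tibble::tibble(
    protein_id = c("p1", "p1", "p2", "p2", "p3", "p3"),
    database = c("KEGG", "VOG", "KEGG", "Pfam", "VOG", "Pfam"),
    label = c("A", "B", "C", "D", "E", "F"),
    bit_score = c(100, 90, 100, 100, 80, 80),
    e_value = c(1e-20, 1e-30, 1e-10, 1e-5, 1e-8, 1e-8),
    viral_score = c(NA, NA, NA, NA, 0.2, 0.9))
  best <- resolve_best_annotation(hits)
  expect_equal(best$label[best$protein_id == "p1"], "A")   # bit score wins
  expect_equal(best$label[best$protein_id == "p2"], "C")   # e-value tiebreak
  expect_equal(best$label[best$protein_id == "p3"], "F")   # viral-score tiebreak
  expect_false("p4" %in% best$protein_id)                  # no hits -> absent
  expect_error(resolve_best_annotation(dplyr::mutate(hits, e_value = -1)),
               "e_value")
})

test_that("PHROG hits are filtered before best-hit resolution", {
  hits <- tibble::tibble(
    protein_id = c("q1", "q1", "q1", "q2"),
    coverage = c(0.9, 0.85, 0.5, 0.7),
    identity = c(0.8, 0.9, 0.99, 0.9),
    e_value = c(1e-3, 1e-8, 1e-30, 1e-10),
    bit_score = c(50, 40, 200, 60))
  out <- filter_phrog_hits(hits)
  expect_equal(nrow(out), 1)                   # q2 fails coverage entirely
  expect_equal(out$e_value, 1e-8)              # smallest e-value among survivors
  expect_equal(nrow(filter_phrog_hits(dplyr::mutate(hits, coverage = 0.1))), 0)
})

test_that("normalized annotation counts sum to one per site", {
  samples <- tibble::tibble(sample_id = c("s1", "s2"), site = c("A", "B"))
  clusters <- tibble::tibble(protein_id = sprintf("p%d", 1:5),
                             cluster_id = "pc_1",
                             sample_id = c("s1", "s1", "s1", "s1", "s2"))
  best <- tibble::tibble(protein_id = sprintf("p%d", 1:4),
                         label = c("major capsid protein", "capsid",
                                   "DNA polymerase", "DNA primase"))
  cats <- tibble::tibble(label = c("major capsid protein", "capsid",
                                   "DNA polymerase", "DNA primase"),
                         category = c("structural", "structural",
                                      "replication", "replication"))
  out <- normalize_annotation_counts(best, clusters, samples, cats)
  a <- dplyr::filter(out, site == "A")
  expect_equal(sort(a$fraction), c(0.5, 0.5))
  expect_equal(sum(a$fraction), 1, tolerance = 1e-12)
  b <- dplyr::filter(out, site == "B")            # p5 unannotated -> site empty
  expect_true(all(b$undefined))

  # the shipped default category table is usable
  out2 <- normalize_annotation_counts(best, clusters, samples)
  expect_equal(sum(dplyr::filter(out2, site == "A")$fraction), 1,
               tolerance = 1e-12)
})
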