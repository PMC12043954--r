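test_that("contamination screening flags only exact full-length copies", {
  v <- rand_dna(1000, seed = 81)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(v)))
  near <- paste0(substring(v, 1, 499), "A" , substring(v, 501, 1000))
  if (identical(near, v)) near <- paste0(substring(v, 1, 499), "C",
                                         substring(v, 501, 1000))
  hosts <- tibble::tibble(
    scaffold_id = c("clean", "contaminated", "revcomp", "almost"),
    sequence = c(rand_dna(3000, seed = 82),
                 paste0(rand_dna(500, seed = 83), v, rand_dna(500, seed = 84)),
                 paste0(rand_dna(200, seed = 85), rc),
                 paste0(rand_dna(500, seed = 86), near)))
  hosts$sequence[4] <- paste0(rand_dna(500, seed = 86),
                              sub("A", "C", v))  # one substitution, not flagged
  flagged <- screen_contamination(hosts, tibble::tibble(unit_id = "v1",
                                                        sequence = v))
  expect_setequal(flagged$scaffold_id, c("contaminated", "revcomp"))
  expect_equal(flagged$strand[flagged$scaffold_id == "revcomp"], "-")
})

test_that("host aggregation sums counts at the requested rank", {
  ab <- tibble::tibble(
    unit_id = c("v1", "v2", "v1", "v2", "v3"),
    sample_id = c("s1", "s1", "s2", "s2", "s1"),
    mapped_read_count = c(3L, 5L, 10L, 20L, 7L))
  asg <- tibble::tibble(
    unit_id = c("v1", "v2", "v3", "v3"),
    host_lineage = c("d__Bacteria;p__Campylobacterota;c__Campylobacteria",
                     "d__Bacteria;p__Campylobacterota;c__Campylobacteria",
                     "d__Bacteria;p__Pseudomonadota;c__Gammaproteobacteria",
                     "d__Bacteria;p__Pseudomonadota;c__Alphaproteobacteria"))
  out <- aggregate_by_host(ab, asg, rank = "class")
  expect_equal(out$mapped_read_count[out$group == "Campylobacteria" &
                                       out$sample_id == "s1"], 8)
  expect_equal(out$mapped_read_count[out$group == "Campylobacteria" &
                                       out$sample_id == "s2"], 30)
  # multi-host virus duplicates its full count into both classes
  expect_equal(out$mapped_read_count[out$group == "Gammaproteobacteria"], 7)
  expect_equal(out$mapped_read_count[out$group == "Alphaproteobacteria"], 7)

  split <- aggregate_by_host(ab, asg, rank = "class", multi_host = "split")
  expect_equal(split$mapped_read_count[split$group == "Gammaproteobacteria"], 3.5)

  # phylum rank collapses the two classes
  phy <- aggregate_by_host(ab, asg, rank = "phylum")
  expect_equal(phy$mapped_read_count[phy$group == "Pseudomonadota"], 7)

  expect_warning(aggregate_by_host(ab, dplyr::mutate(asg, host_lineage = "d__Bacteria"),
                                   rank = "class"),
                 "skipped")
})

test_that("clr transform has the compositional identities", {
  expect_equal(clr_transform(c(1, 1, 1, 1), pseudocount = 0), rep(0, 4))
  expect_equal(clr_transform(c(1, exp(2)), pseudocount = 0), c(-1, 1))
  withr::with_seed(91, {
    for (i in 1:10) {
      x <- rlnorm(sample(3:12, 1), 3, 1)
      a <- clr_transform(x, pseudocount = 0.5)
      expect_equal(sum(a), 0, tolerance = 1e-12)
      # scale invariance at pseudocount 0
      expect_equal(clr_transform(x, 0), clr_transform(7 * x, 0), tolerance = 1e-12)
    }
  })
  expect_error(clr_transform(c(1, NA)), "finite")
  expect_error(clr_transform(c(0, 1), pseudocount = 0), "positive")
})

test_that("rho is 1 for identical series, -1 for clr-mirrored series", {
  # a third varying component keeps the clr series of x and y non-constant
  series <- tibble::tibble(
    group = rep(c("x", "y", "z"), each = 3),
    sample_id = rep(c("s1", "s2", "s3"), 3),
    mapped_read_count = c(1, 2, 3, 1, 2, 3, 9, 1, 4))
  expect_equal(proportionality_rho(series, "x", "y", pseudocount = 0)$rho, 1)

  # in a two-component composition the clr series are exact mirrors
  anti <- tibble::tibble(
    group = rep(c("x", "y"), each = 3),
    sample_id = rep(c("s1", "s2", "s3"), 2),
    mapped_read_count = c(1, 4, 9, 9, 4, 1))
  expect_equal(proportionality_rho(anti, "x", "y", pseudocount = 0)$rho, -1)

  const <- tibble::tibble(
    group = rep(c("x", "y"), each = 3),
    sample_id = rep(c("s1", "s2", "s3"), 2),
    mapped_read_count = rep(5, 6))
  expect_true(proportionality_rho(const, "x", "y", pseudocount = 0)$undefined)

  two <- dplyr::filter(series, sample_id %in% c("s1", "s2"))
  expect_error(proportionality_rho(two, "x", "y"), "3 samples")
})

test_that("rho is symmetric, bounded, and matches a direct reference", {
  withr::with_seed(95, {
    series <- tidyr::expand_grid(group = c("g1", "g2", "g3", "g4"),
                                 sample_id = sprintf("s%02d", 1:20)) |>
      dplyr::mutate(mapped_read_count = round(rlnorm(dplyr::n(), 5, 1)))
  })
  r12 <- proportionality_rho(series, "g1", "g2", pseudocount = 0.5)
  r21 <- proportionality_rho(series, "g2", "g1", pseudocount = 0.5)
  expect_equal(r12$rho, r21$rho)
  m <- proportionality_matrix(series, pseudocount = 0.5)
  expect_true(all(m$rho >= -1 & m$rho <= 1))

  # independent reference: literal clr + variance formula on the wide matrix
  wide <- tidyr::pivot_wider(series, names_from = group,
                             values_from = mapped_read_count)
  comp <- as.matrix(wide[, c("g1", "g2", "g3", "g4")]) + 0.5
  a <- log(comp) - rowMeans(log(comp))
  ref <- 1 - var(a[, "g1"] - a[, "g2"]) / (var(a[, "g1"]) + var(a[, "g2"]))
  expect_equal(r12$rho, ref, tolerance = 1e-12)
})

test_that("estimated rho decreases as coupling noise grows", {
  cfg <- sim_config(n_fields = 3, sites_per_field = 5, genomes_per_site = 3,
                    planted_inter_field_clusters = 0,
                    planted_intra_field_clusters = 0,
                    genome_length_range = c(3000, 3500),
                    host_proportionality_pairs = list(
                      list(host_group = "low", coupling = 2, noise_sd = 0.05),
                      list(host_group = "mid", coupling = 2, noise_sd = 0.2),
                      list(host_group = "high", coupling = 2, noise_sd = 0.5)),
                    seed = 97)
  comm <- simulate_community(cfg)
  cnt <- simulate_counts(comm, seed = 98)
  asg <- comm$truth |> dplyr::filter(!is.na(host_group)) |>
    dplyr::transmute(unit_id,
                     host_lineage = paste0("d__B;p__P;c__", host_group))
  vir <- aggregate_by_host(cnt$abundance, asg, rank = "class") |>
    dplyr::mutate(group = paste0("vir_", group))
  series <- dplyr::bind_rows(vir, dplyr::rename(cnt$hosts, group = host_group))
  rhos <- vapply(c("low", "mid", "high"), function(g) {
    proportionality_rho(series, paste0("vir_", g), g,
                        samples = comm$samples)$rho
  }, numeric(1))
  expect_true(all(diff(rhos) < 0))
  expect_gt(rhos["low"], 0.9)
})
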