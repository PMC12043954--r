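test_that("screen_bins applies the redundancy, lysogeny, and size rules", {
  bins <- tibble::tibble(
    bin_id = c("b1", "b2", "b3", "b4", "b5"),
    n_scaffolds = c(3L, 2L, 11L, 4L, 5L),
    redundant_protein_count = c(0L, 0L, 0L, 2L, 3L),
    lysogenic_scaffold_count = c(0L, 2L, 0L, 0L, 2L))
  out <- screen_bins(bins)
  expect_equal(out$decision, c("keep", "dissolve", "dissolve", "dissolve",
                               "dissolve"))
  expect_equal(out$reasons[2], "lysogeny")
  expect_equal(out$reasons[3], "size")
  expect_equal(out$reasons[4], "redundancy")
  expect_equal(out$reasons[5], "redundancy,lysogeny")
  expect_error(screen_bins(tibble::tibble(bin_id = "b", n_scaffolds = 0L,
                                          redundant_protein_count = 0L,
                                          lysogenic_scaffold_count = 0L)),
               "empty bin")
})

test_that("screen_bins is monotone in lysogenic scaffolds", {
  withr::with_seed(11, {
    for (i in 1:50) {
      n <- sample(2:12, 1)
      bin <- tibble::tibble(bin_id = "b", n_scaffolds = n,
                            redundant_protein_count = sample(0:3, 1),
                            lysogenic_scaffold_count = sample(0:(n - 1), 1))
      more <- dplyr::mutate(bin,
                            lysogenic_scaffold_count = lysogenic_scaffold_count + 1L)
      if (screen_bins(bin)$decision == "dissolve") {
        expect_equal(screen_bins(more)$decision, "dissolve")
      }
    }
  })
})

test_that("assign_lifestyle designates mixed bins as lysogenic", {
  expect_equal(assign_lifestyle(c("lytic", "lytic")), "lytic")
  expect_equal(assign_lifestyle(c("lytic", "lysogenic")), "lysogenic")
  expect_equal(assign_lifestyle("lysogenic"), "lysogenic")
  expect_error(assign_lifestyle(character(0)), "at least one")
  expect_error(assign_lifestyle("temperate"), "unknown lifestyle")
})

test_that("link_scaffolds inserts N spacers between scaffolds only", {
  one <- strrep("A", 4000)
  expect_equal(nchar(link_scaffolds(one)), 4000)
  expect_false(grepl("N", link_scaffolds(one)))

  two <- link_scaffolds(c(strrep("A", 100), strrep("C", 200)))
  expect_equal(nchar(two), 1800)
  expect_equal(stringr::str_count(two, "N"), 1500)

  three <- link_scaffolds(rep(strrep("G", 1000), 3))
  expect_equal(nchar(three), 6000)
})

test_that("build_units conserves scaffolds and closes the ledger", {
  scaffolds <- tibble::tibble(
    scaffold_id = sprintf("sc%02d", 1:10),
    sample_id = "s1",
    lifestyle = c("lysogenic", rep("lytic", 9)),
    sequence = vapply(1:10, function(i) rand_dna(500, seed = i), character(1)))
  bins <- tibble::tibble(bin_id = "bin1", scaffold_id = c("sc02", "sc03", "sc04"),
                         redundant_protein_count = 0L)
  res <- build_units(scaffolds, bins)
  expect_equal(nrow(res$units), 8)
  expect_equal(sum(res$units$kind == "bin"), 1)
  led <- res$ledger
  expect_equal(unname(unlist(led[c("n_scaffolds_total", "n_scaffolds_binned",
                                   "n_bins_retained", "n_unbinned_units",
                                   "n_units_total")])),
               c(10, 3, 1, 7, 8))
  bin_unit <- dplyr::filter(res$units, kind == "bin")
  expect_equal(bin_unit$total_length, 1500)        # member bases, spacers excluded
  expect_equal(nchar(bin_unit$sequence), 1500 + 2 * 1500)

  # no bins: every scaffold is its own unit
  res0 <- build_units(scaffolds)
  expect_equal(res0$ledger$n_units_total, res0$ledger$n_scaffolds_total)

  expect_error(build_units(scaffolds,
                           tibble::tibble(bin_id = c("a", "b"),
                                          scaffold_id = c("sc01", "sc01"),
                                          redundant_protein_count = 0L)),
               "more than one bin")
})

test_that("dissolved bins return scaffolds with their own lifestyles", {
  scaffolds <- tibble::tibble(
    scaffold_id = c("x1", "x2", "x3"),
    sample_id = "s1",
    lifestyle = c("lytic", "lysogenic", "lysogenic"),
    sequence = vapply(1:3, function(i) rand_dna(300, seed = 40 + i), character(1)))
  bins <- tibble::tibble(bin_id = "badbin", scaffold_id = c("x1", "x2", "x3"),
                         redundant_protein_count = 0L)  # 2 lysogenic -> dissolve
  res <- build_units(scaffolds, bins)
  expect_equal(res$ledger$n_bins_retained, 0)
  expect_equal(res$ledger$dissolved_lysogeny, 1)
  expect_equal(sort(res$units$unit_id), c("x1", "x2", "x3"))
  expect_equal(res$units$lifestyle[res$units$unit_id == "x1"], "lytic")
})

test_that("ledger identities hold on random inputs", {
  withr::with_seed(99, {
    for (rep in 1:10) {
      n <- sample(5:30, 1)
      scaffolds <- tibble::tibble(
        scaffold_id = sprintf("r%03d", seq_len(n)),
        sample_id = sample(c("sA", "sB"), n, replace = TRUE),
        lifestyle = sample(c("lytic", "lysogenic"), n, replace = TRUE,
                           prob = c(0.8, 0.2)),
        sequence = strrep("ACGT", 100))
      n_bins <- sample(0:3, 1)
      binned_ids <- sample(scaffolds$scaffold_id,
                           min(n, sum(sample(2:4, max(n_bins, 1), replace = TRUE))))
      bins <- if (n_bins == 0 || length(binned_ids) < 2) NULL else
        tibble::tibble(bin_id = sprintf("bin%d",
                                        rep_len(seq_len(n_bins), length(binned_ids))),
                       scaffold_id = binned_ids,
                       redundant_protein_count = sample(0:2, length(binned_ids),
                                                        replace = TRUE)) |>
        dplyr::group_by(bin_id) |>
        dplyr::mutate(redundant_protein_count = redundant_protein_count[1]) |>
        dplyr::ungroup() |>
        dplyr::group_by(bin_id) |> dplyr::filter(dplyr::n() >= 2) |> dplyr::ungroup()
      res <- build_units(scaffolds, bins)
      led <- res$ledger
      expect_equal(led$n_scaffolds_binned + led$n_unbinned_units,
                   led$n_scaffolds_total)
      expect_equal(led$n_units_total, led$n_bins_retained + led$n_unbinned_units)
      # scaffold conservation: every scaffold in exactly one unit
      expect_equal(sum(res$units$n_scaffolds), n)
    }
  })
})
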