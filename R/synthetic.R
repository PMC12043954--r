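#' Configure a synthetic hydrothermal vent viral community
#'
#' Builds and validates the configuration for [simulate_community()]. The
#' generator emulates the structure of a multi-field hydrothermal vent survey:
#' several vent fields, each with several sites (one metagenome per site),
#' mixed plume/deposit/diffuse habitats, viral genomes with planted ANI-cluster
#' structure (inter-field, intra-field, and endemic singletons), lytic /
#' lysogenic lifestyles, shared core protein families across sites, and
#' host-coupled virus abundances.
#'
#' @param n_fields Number of vent fields.
#' @param sites_per_field Number of sites (= samples) per field.
#' @param genomes_per_site Number of viral genomes originating from each site.
#' @param genome_length_range Length range (bp) genomes are drawn from,
#'   uniformly. The default 3--50 kb keeps every genome above the 3 kb
#'   clustering floor.
#' @param planted_inter_field_clusters Number of planted clusters whose two
#'   members come from sites in different vent fields.
#' @param planted_intra_field_clusters Number of planted clusters whose two
#'   members come from different sites of the same vent field.
#' @param divergence_within_cluster Expected pairwise nucleotide divergence
#'   between the two members of a planted cluster (each member is mutated from
#'   a common ancestor at half this rate). Must be at most 0.30 so planted
#'   pairs stay above the 70% ANI screen.
#' @param lysogenic_fraction Bernoulli probability that a unit is lysogenic.
#' @param shared_protein_family_fraction Probability that a unit carries a copy
#'   of each shared core protein family.
#' @param n_core_protein_families Number of shared core protein families.
#' @param host_proportionality_pairs List of host-coupling specifications,
#'   each a list/vector with elements `host_group` (label), `coupling`
#'   (multiplicative constant), and `noise_sd` (sd of the lognormal
#'   multiplicative noise). Each group is serviced by `units_per_host_group`
#'   endemic viral units.
#' @param units_per_host_group Number of viral units attached to each host
#'   group.
#' @param habitat_probs Sampling probabilities for site habitats, in the order
#'   plume, deposit, diffuse. The default mirrors a survey dominated by
#'   deposits with a minority of plumes and rare diffuse-flow samples.
#' @param total_reads_range Range of per-sample sequencing depth (read counts).
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return A named list of class `vv_sim_config`.
#' @seealso [simulate_community()], [simulate_counts()]
#' @export
sim_config <- function(n_fields = 2,
                       sites_per_field = 2,
                       genomes_per_site = 20,
                       genome_length_range = c(3000, 50000),
                       planted_inter_field_clusters = 3,
                       planted_intra_field_clusters = 3,
                       divergence_within_cluster = 0.05,
                       lysogenic_fraction = 0.05,
                       shared_protein_family_fraction = 0.2,
                       n_core_protein_families = 5,
                       host_proportionality_pairs = list(),
                       units_per_host_group = 3,
                       habitat_probs = c(plume = 0.2, deposit = 0.75, diffuse = 0.05),
                       total_reads_range = c(2e6, 8e6),
                       seed = 1L) {
  assert_scalar_count(n_fields, "n_fields")
  assert_scalar_count(sites_per_field, "sites_per_field")
  assert_scalar_count(genomes_per_site, "genomes_per_site")
  assert_fraction(divergence_within_cluster, "divergence_within_cluster", max = 0.30)
  assert_fraction(lysogenic_fraction, "lysogenic_fraction")
  assert_fraction(shared_protein_family_fraction, "shared_protein_family_fraction")
  stopifnot(length(genome_length_range) == 2, genome_length_range[1] >= 100,
            diff(genome_length_range) >= 0, length(total_reads_range) == 2)
  if (planted_inter_field_clusters > 0 && n_fields < 2) {
    abort("inter-field clusters need at least 2 vent fields")
  }
  if (planted_intra_field_clusters > 0 && sites_per_field < 2) {
    abort("intra-field clusters need at least 2 sites per field")
  }
  for (p in host_proportionality_pairs) {
    if (is.null(p$host_group) || is.null(p$coupling) || is.null(p$noise_sd)) {
      abort("each host_proportionality_pairs entry needs host_group, coupling, noise_sd")
    }
  }
  structure(
    list(n_fields = as.integer(n_fields),
         sites_per_field = as.integer(sites_per_field),
         genomes_per_site = as.integer(genomes_per_site),
         genome_length_range = as.integer(genome_length_range),
         planted_inter_field_clusters = as.integer(planted_inter_field_clusters),
         planted_intra_field_clusters = as.integer(planted_intra_field_clusters),
         divergence_within_cluster = divergence_within_cluster,
         lysogenic_fraction = lysogenic_fraction,
         shared_protein_family_fraction = shared_protein_family_fraction,
         n_core_protein_families = as.integer(n_core_protein_families),
         host_proportionality_pairs = host_proportionality_pairs,
         units_per_host_group = as.integer(units_per_host_group),
         habitat_probs = habitat_probs,
         total_reads_range = total_reads_range,
         seed = as.integer(seed)),
    class = "vv_sim_config")
}

#' Mutate a genome by random substitutions
#'
#' Applies independent per-site substitutions at rate `subst_rate`; a
#' substituted base is always different from the original, and no indels are
#' introduced, so the expected Hamming divergence of the output from the input
#' is exactly `subst_rate`. This makes the true ANI of simulated genome pairs
#' analytically known.
#'
#' @param sequence A non-empty DNA string over A/C/G/T.
#' @param subst_rate Per-site substitution probability in `[0, 1)`.
#' @param seed Integer seed; output is deterministic given `(sequence,
#'   subst_rate, seed)`.
#' @return The mutated DNA string, same length as the input.
#' @examples
#' mutate_genome("ACGTACGT", 0.5, seed = 1)
#' @export
mutate_genome <- function(sequence, subst_rate, seed) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    abort("`sequence` must be a single non-empty DNA string")
  }
  if (grepl("[^ACGT]", sequence)) {
    abort("`sequence` contains characters other than A, C, G, T")
  }
  if (!is.numeric(subst_rate) || subst_rate < 0 || subst_rate >= 1) {
    abort("`subst_rate` must be in [0, 1)")
  }
  withr::with_seed(as.integer(seed), mutate_string(sequence, subst_rate, DNA_BASES))
}

# Allocate one origin site for a planted-cluster member. Sites are picked by
# most remaining capacity (lexicographic tie-break) so feasibility depends only
# on total capacity, not on allocation luck.
pick_site <- function(free, eligible) {
  cand <- eligible[free[eligible] > 0]
  if (length(cand) == 0) return(NA_character_)
  cand[order(-free[cand], cand)][1]
}

#' Simulate a multi-site viral community with planted structure
#'
#' Generates viral genomes for every site of every vent field, plants
#' inter-field and intra-field ANI clusters (pairs of genomes mutated from a
#' common ancestor so their expected pairwise divergence equals
#' `divergence_within_cluster`), leaves the remaining genomes as endemic
#' singletons, assigns lytic/lysogenic lifestyles, emits per-unit protein
#' complements including shared core families copied across sites, and
#' records all of it in a truth table.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `vv_community`: a list with tibbles
#'   * `genomes`: `unit_id`, `sample_id`, `length`, `sequence`
#'   * `samples`: `sample_id`, `vent_field`, `site`, `habitat`, `total_reads`
#'   * `truth`: `unit_id`, `sample_id`, `planted_cluster_id` (NA for endemic
#'     singletons), `cluster_kind`, `lifestyle`, `host_group`
#'   * `detection_truth`: expected `(unit_id, sample_id)` detections (a unit is
#'     expected in its origin sample and in the origin samples of its planted
#'     cluster co-members)
#'   * `proteins`: `protein_id`, `unit_id`, `sample_id`, `family_id` (NA for
#'     unit-private proteins), `sequence`
#'   plus the `config` used.
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "vv_sim_config"))
  withr::with_seed(config$seed, simulate_community_impl(config))
}

simulate_community_impl <- function(config) {
  fields <- sprintf("F%d", seq_len(config$n_fields))
  sites <- tibble(
    vent_field = rep(fields, each = config$sites_per_field),
    site = as.vector(vapply(fields, function(f)
      sprintf("%sS%d", f, seq_len(config$sites_per_field)), character(config$sites_per_field)))
  )
  samples <- sites |>
    dplyr::mutate(
      sample_id = paste0("sample_", .data$site),
      habitat = sample(names(config$habitat_probs), dplyr::n(),
                       replace = TRUE, prob = config$habitat_probs),
      total_reads = as.integer(round(runif(dplyr::n(),
                                           config$total_reads_range[1],
                                           config$total_reads_range[2])))) |>
    dplyr::select("sample_id", "vent_field", "site", "habitat", "total_reads")

  free <- setNames(rep(config$genomes_per_site, nrow(samples)), samples$site)
  site_field <- setNames(samples$vent_field, samples$site)

  # Plan planted clusters: each is a pair of slots in distinct fields
  # (inter) or distinct sites of one field (intra).
  plan <- list()
  for (i in seq_len(config$planted_inter_field_clusters)) {
    s1 <- pick_site(free, names(free))
    if (is.na(s1)) {
      abort("genomes_per_site too small to plant the requested inter-field clusters")
    }
    free[s1] <- free[s1] - 1L
    s2 <- pick_site(free, names(free)[site_field != site_field[[s1]]])
    if (is.na(s2)) {
      abort("genomes_per_site too small to plant the requested inter-field clusters")
    }
    free[s2] <- free[s2] - 1L
    plan[[length(plan) + 1L]] <- list(id = sprintf("inter_%02d", i),
                                      kind = "inter_field", sites = c(s1, s2))
  }
  for (i in seq_len(config$planted_intra_field_clusters)) {
    s1 <- pick_site(free, names(free))
    if (is.na(s1)) {
      abort("genomes_per_site too small to plant the requested intra-field clusters")
    }
    free[s1] <- free[s1] - 1L
    s2 <- pick_site(free, names(free)[site_field == site_field[[s1]] &
                                        names(free) != s1])
    if (is.na(s2)) {
      abort("genomes_per_site too small to plant the requested intra-field clusters")
    }
    free[s2] <- free[s2] - 1L
    plan[[length(plan) + 1L]] <- list(id = sprintf("intra_%02d", i),
                                      kind = "intra_field", sites = c(s1, s2))
  }

  counter <- setNames(rep(0L, nrow(samples)), samples$site)
  new_unit <- function(site) {
    counter[site] <<- counter[site] + 1L
    sprintf("vir_%s_%03d", site, counter[site])
  }
  rows <- list()
  per_member_rate <- config$divergence_within_cluster / 2

  for (p in plan) {
    len <- as.integer(round(runif(1, config$genome_length_range[1],
                                  config$genome_length_range[2])))
    ancestor <- random_dna(len)
    for (s in p$sites) {
      seq_mut <- mutate_string(ancestor, per_member_rate, DNA_BASES)
      rows[[length(rows) + 1L]] <- tibble(
        unit_id = new_unit(s), site = s,
        planted_cluster_id = p$id, cluster_kind = p$kind,
        length = len, sequence = seq_mut)
    }
  }
  for (s in samples$site) {
    for (i in seq_len(free[s])) {
      len <- as.integer(round(runif(1, config$genome_length_range[1],
                                    config$genome_length_range[2])))
      rows[[length(rows) + 1L]] <- tibble(
        unit_id = new_unit(s), site = s,
        planted_cluster_id = NA_character_, cluster_kind = "endemic",
        length = len, sequence = random_dna(len))
    }
  }
  units <- dplyr::bind_rows(rows) |>
    dplyr::left_join(dplyr::select(samples, "sample_id", "site"), by = "site") |>
    dplyr::arrange(.data$unit_id)

  # Lifestyles and host-group attachment (endemic units only, so host-coupled
  # counts never collide with planted cross-sample detection truth).
  units$lifestyle <- ifelse(runif(nrow(units)) < config$lysogenic_fraction,
                            "lysogenic", "lytic")
  units$host_group <- NA_character_
  endemic_pool <- units$unit_id[units$cluster_kind == "endemic"]
  for (p in config$host_proportionality_pairs) {
    take <- min(config$units_per_host_group, length(endemic_pool))
    if (take == 0) abort("not enough endemic units to attach host groups")
    chosen <- endemic_pool[seq_len(take)]
    endemic_pool <- setdiff(endemic_pool, chosen)
    units$host_group[units$unit_id %in% chosen] <- p$host_group
  }

  truth <- dplyr::select(units, "unit_id", "sample_id", "planted_cluster_id",
                         "cluster_kind", "lifestyle", "host_group")

  detection_truth <- truth |>
    dplyr::filter(!is.na(.data$planted_cluster_id)) |>
    dplyr::select("planted_cluster_id", det_unit = "unit_id") |>
    dplyr::inner_join(truth |>
                        dplyr::filter(!is.na(.data$planted_cluster_id)) |>
                        dplyr::select("planted_cluster_id", "sample_id"),
                      by = "planted_cluster_id",
                      relationship = "many-to-many") |>
    dplyr::select(unit_id = "det_unit", "sample_id") |>
    dplyr::bind_rows(dplyr::select(truth, "unit_id", "sample_id")) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$unit_id, .data$sample_id)

  proteins <- simulate_proteins(units, config)

  structure(list(genomes = dplyr::select(units, "unit_id", "sample_id",
                                         "length", "sequence"),
                 samples = samples,
                 truth = truth,
                 detection_truth = detection_truth,
                 proteins = proteins,
                 config = config),
            class = "vv_community")
}

# Per-unit protein complements: a few private proteins per unit plus copies of
# shared core families (2% amino-acid divergence between copies).
simulate_proteins <- function(units, config) {
  core <- lapply(seq_len(config$n_core_protein_families), function(i) {
    list(family_id = sprintf("fam_%02d", i),
         sequence = random_protein(sample(100:300, 1)))
  })
  rows <- list()
  for (i in seq_len(nrow(units))) {
    uid <- units$unit_id[i]
    sid <- units$sample_id[i]
    n_private <- sample(3:6, 1)
    for (j in seq_len(n_private)) {
      rows[[length(rows) + 1L]] <- tibble(
        protein_id = sprintf("%s_p%02d", uid, j), unit_id = uid, sample_id = sid,
        family_id = NA_character_, sequence = random_protein(sample(100:300, 1)))
    }
    for (fam in core) {
      if (runif(1) < config$shared_protein_family_fraction) {
        rows[[length(rows) + 1L]] <- tibble(
          protein_id = sprintf("%s_%s", uid, fam$family_id),
          unit_id = uid, sample_id = sid, family_id = fam$family_id,
          sequence = mutate_string(fam$sequence, 0.02, AA_ALPHABET))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate mapped-read counts and covered fractions
#'
#' Produces the per-unit, per-sample abundance matrix for a simulated
#' community. Every unit receives a high covered fraction (0.9--1) and a
#' lognormal read count in its origin sample; members of planted clusters are
#' additionally "detected" (covered fraction 0.8--1) in their co-members'
#' origin samples; all other cells get covered fractions below 0.3 and mostly
#' zero counts. For each host-coupling specification in the config, per-sample
#' host-group counts are drawn lognormally and the attached viral units'
#' counts are set to `coupling * host_count * exp(N(0, noise_sd))`, split
#' across the group's units, so downstream clr proportionality has a known
#' signal. A coupling of 0 marks an uncoupled control: the group's virus
#' counts are drawn independently of its host counts. Per-sample totals are capped at the sample's `total_reads`.
#'
#' @param community A `vv_community` from [simulate_community()].
#' @param seed Integer seed.
#' @return A list with tibbles `abundance` (`unit_id`, `sample_id`,
#'   `mapped_read_count`, `covered_fraction`) and `hosts` (`host_group`,
#'   `sample_id`, `mapped_read_count`).
#' @export
simulate_counts <- function(community, seed = community$config$seed + 1L) {
  stopifnot(inherits(community, "vv_community"))
  withr::with_seed(as.integer(seed), simulate_counts_impl(community))
}

simulate_counts_impl <- function(community) {
  truth <- community$truth
  samples <- community$samples
  cfg <- community$config

  grid <- tidyr::expand_grid(unit_id = truth$unit_id, sample_id = samples$sample_id) |>
    dplyr::left_join(dplyr::select(truth, "unit_id", origin = "sample_id",
                                   "host_group"), by = "unit_id") |>
    dplyr::left_join(dplyr::mutate(community$detection_truth, expected = TRUE),
                     by = c("unit_id", "sample_id")) |>
    dplyr::mutate(expected = !is.na(.data$expected))

  n <- nrow(grid)
  is_origin <- grid$sample_id == grid$origin
  count <- integer(n)
  count[is_origin] <- as.integer(round(rlnorm(sum(is_origin), log(500), 1)))
  co <- grid$expected & !is_origin
  count[co] <- as.integer(round(rlnorm(sum(co), log(200), 1)))
  bg <- !grid$expected
  has_bg <- bg & rbinom(n, 1, 0.1) == 1
  count[has_bg] <- as.integer(sample(1:20, sum(has_bg), replace = TRUE))

  covered <- runif(n, 0, 0.3)
  covered[co] <- runif(sum(co), 0.8, 1)
  covered[is_origin] <- runif(sum(is_origin), 0.9, 1)

  # Host-coupled groups overwrite the counts of their attached units; a
  # coupling of 0 marks an uncoupled control pair whose virus counts are
  # drawn independently of the host counts.
  host_rows <- list()
  for (p in cfg$host_proportionality_pairs) {
    host_counts <- as.integer(round(rlnorm(nrow(samples), log(2000), 1)))
    noise <- exp(rnorm(nrow(samples), 0, p$noise_sd))
    virus_totals <- if (p$coupling == 0) {
      as.integer(round(rlnorm(nrow(samples), log(2000), 1)))
    } else {
      as.integer(round(p$coupling * host_counts * noise))
    }
    host_rows[[length(host_rows) + 1L]] <- tibble(
      host_group = p$host_group, sample_id = samples$sample_id,
      mapped_read_count = host_counts)
    members <- truth$unit_id[!is.na(truth$host_group) &
                               truth$host_group == p$host_group]
    for (si in seq_along(samples$sample_id)) {
      split <- as.integer(rmultinom(1, virus_totals[si],
                                    rep(1, length(members))))
      idx <- match(paste(members, samples$sample_id[si]),
                   paste(grid$unit_id, grid$sample_id))
      count[idx] <- split
    }
  }

  abundance <- tibble(unit_id = grid$unit_id, sample_id = grid$sample_id,
                      mapped_read_count = count,
                      covered_fraction = covered)

  # Marginal cap: simulated mapped reads never exceed the sample's depth.
  abundance <- abundance |>
    dplyr::left_join(dplyr::select(samples, "sample_id", "total_reads"),
                     by = "sample_id") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(mapped_read_count = if (sum(.data$mapped_read_count) >
                                          .data$total_reads[1]) {
      as.integer(floor(.data$mapped_read_count * .data$total_reads[1] /
                         sum(.data$mapped_read_count)))
    } else .data$mapped_read_count) |>
    dplyr::ungroup() |>
    dplyr::select(-"total_reads")

  list(abundance = abundance,
       hosts = if (length(host_rows)) dplyr::bind_rows(host_rows) else
         tibble(host_group = character(), sample_id = character(),
                mapped_read_count = integer()))
}

#' Write a simulated community to disk
#'
#' Writes the genomes as FASTA (headers `unitID|scaffold1|sampleID`) and the
#' sample, truth, detection-truth, and protein tables as TSV.
#'
#' @param community A `vv_community`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  stopifnot(inherits(community, "vv_community"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(community$genomes$sequence)
  names(seqs) <- sprintf("%s|scaffold1|%s", community$genomes$unit_id,
                         community$genomes$sample_id)
  Biostrings::writeXStringSet(seqs, file.path(dir, "genomes.fasta"), width = 80)
  readr::write_tsv(community$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(community$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(community$detection_truth, file.path(dir, "detection_truth.tsv"))
  prot <- Biostrings::AAStringSet(community$proteins$sequence)
  names(prot) <- sprintf("%s|%s|%s", community$proteins$protein_id,
                         community$proteins$unit_id, community$proteins$sample_id)
  Biostrings::writeXStringSet(prot, file.path(dir, "proteins.fasta"), width = 80)
  invisible(dir)
}
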