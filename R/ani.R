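# Fragment-mapping ANI estimation.
#
# The shorter genome of a pair is cut into fixed-length fragments (N spacers of
# linked vMAGs are excluded), each fragment is anchored on the longer genome by
# exact k-mer seeds (modal diagonal), and the anchored window is aligned with a
# global-local alignment. ANI is the mean percent identity of the fragments
# that align above the per-fragment identity screen; each genome's aligned
# fraction (AF) is its aligned bases over its non-N length.

non_n_length <- function(seq) nchar(seq) - stringr::str_count(seq, "N")

# Cut a genome into alignment fragments, skipping N spacers. Tail pieces
# shorter than `min_fragment` are dropped.
genome_fragments <- function(seq, fragment_length, min_fragment = 300L) {
  segments <- strsplit(seq, "N+")[[1]]
  segments <- segments[nchar(segments) > 0]
  frags <- character(0)
  for (seg in segments) {
    starts <- seq(1L, nchar(seg), by = fragment_length)
    pieces <- substring(seg, starts, pmin(starts + fragment_length - 1L, nchar(seg)))
    frags <- c(frags, pieces[nchar(pieces) >= min_fragment])
  }
  frags
}

target_kmer_index <- function(seq, k) {
  if (nchar(seq) < k) return(character(0))
  km <- kmers_at(seq, k, seq_len(nchar(seq) - k + 1L))
  km[grepl("N", km, fixed = TRUE)] <- NA_character_
  km
}

nuc_submat <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      mat <<- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                       baseOnly = TRUE)
    }
    mat
  }
})

align_fragment <- function(frag, target, target_index, k, pad = 100L) {
  starts <- seq(1L, nchar(frag) - k + 1L, by = 25L)
  hits <- match(kmers_at(frag, k, starts), target_index)
  ok <- !is.na(hits)
  if (sum(ok) < 2L) return(NULL)
  diags <- hits[ok] - starts[ok]
  diag_tab <- table(diags)
  if (max(diag_tab) < 2L) return(NULL)
  d <- as.integer(names(diag_tab)[which.max(diag_tab)])
  w_start <- max(1L, d + 1L - pad)
  w_end <- min(nchar(target), d + nchar(frag) + pad)
  window <- substring(target, w_start, w_end)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(frag), Biostrings::DNAString(gsub("N", "A", window)),
    type = "global-local", substitutionMatrix = nuc_submat(),
    gapOpening = 6, gapExtension = 1)
  subj <- Biostrings::subject(aln)
  list(identity = 100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln),
       target_span = Biostrings::end(subj) - Biostrings::start(subj) + 1L)
}

#' Estimate ANI and aligned fractions for a genome pair
#'
#' Fragment-mapping estimator of average nucleotide identity: the shorter
#' genome is cut into `fragment_length` bp fragments (N spacers excluded),
#' each fragment is seeded on the longer genome by exact `k`-mer matches and
#' extended with a global-local alignment, and fragments with identity at or
#' above `min_fragment_identity` count as aligned. ANI is the mean identity of
#' the aligned fragments; each partner's aligned fraction is its aligned bases
#' divided by its non-N length, in percent.
#'
#' @param seq_a,seq_b DNA strings (possibly N-linked vMAGs), each with at
#'   least `min_length` non-N bases.
#' @param fragment_length Fragment size in bp.
#' @param k Seed k-mer size.
#' @param min_fragment_identity Per-fragment percent-identity screen; pairs
#'   with no fragment at or above it return `NULL`.
#' @param min_length Minimum non-N genome length; shorter inputs are an error
#'   (they are excluded upstream by the length filter).
#' @return A one-row tibble `ani`, `af_a`, `af_b`, `n_fragments`,
#'   `n_aligned_fragments`, or `NULL` when no fragment aligns.
#' @export
estimate_ani <- function(seq_a, seq_b, fragment_length = 1000L, k = 15L,
                         min_fragment_identity = 70, min_length = 3000L) {
  len_a <- non_n_length(seq_a)
  len_b <- non_n_length(seq_b)
  if (len_a < min_length || len_b < min_length) {
    abort(sprintf("both genomes must have >= %d non-N bp", min_length))
  }
  a_is_short <- len_a <= len_b
  short <- if (a_is_short) seq_a else seq_b
  long <- if (a_is_short) seq_b else seq_a
  idx <- target_kmer_index(long, k)

  frags <- genome_fragments(short, fragment_length)
  idents <- numeric(0)
  short_aligned <- 0L
  long_aligned <- 0L
  for (frag in frags) {
    res <- align_fragment(frag, long, idx, k)
    if (!is.null(res) && res$identity >= min_fragment_identity) {
      idents <- c(idents, res$identity)
      short_aligned <- short_aligned + nchar(frag)
      long_aligned <- long_aligned + res$target_span
    }
  }
  if (length(idents) == 0) return(NULL)
  af_short <- min(100, 100 * short_aligned / min(len_a, len_b))
  af_long <- min(100, 100 * long_aligned / max(len_a, len_b))
  tibble(ani = mean(idents),
         af_a = if (a_is_short) af_short else af_long,
         af_b = if (a_is_short) af_long else af_short,
         n_fragments = length(frags),
         n_aligned_fragments = length(idents))
}

#' All-vs-all ANI edges for a set of viral units
#'
#' Runs [estimate_ani()] over every unordered pair of units with at least
#' `min_length` non-N bases. Pairs sharing fewer than three sampled seed
#' k-mers are skipped without alignment (unrelated genomes essentially never
#' share exact 15-mers).
#'
#' @param units Data frame with `unit_id` and `sequence`.
#' @param min_length Minimum non-N genome length (bp); shorter units are
#'   dropped before pairing.
#' @inheritParams estimate_ani
#' @return Tibble of edges: `unit_a`, `unit_b` (lexicographically ordered),
#'   `ani`, `af_a`, `af_b`.
#' @export
ani_edges <- function(units, min_length = 3000L, fragment_length = 1000L,
                      k = 15L, min_fragment_identity = 70) {
  units <- as_tibble(units)
  stopifnot(all(c("unit_id", "sequence") %in% names(units)))
  units <- units |>
    dplyr::mutate(.len = vapply(.data$sequence, non_n_length, integer(1),
                                USE.NAMES = FALSE)) |>
    dplyr::filter(.data$.len >= min_length) |>
    dplyr::arrange(.data$unit_id)
  n <- nrow(units)
  if (n < 2) {
    return(tibble(unit_a = character(), unit_b = character(), ani = numeric(),
                  af_a = numeric(), af_b = numeric()))
  }
  indexes <- lapply(units$sequence, target_kmer_index, k = k)
  probes <- lapply(units$sequence, function(s) {
    km <- kmers_at(s, k, seq(1L, max(1L, nchar(s) - k + 1L), by = 11L))
    km[!grepl("N", km, fixed = TRUE)]
  })
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- sum(!is.na(match(probes[[i]], indexes[[j]])))
      if (shared < 3L) next
      hit <- estimate_ani(units$sequence[i], units$sequence[j],
                          fragment_length = fragment_length, k = k,
                          min_fragment_identity = min_fragment_identity,
                          min_length = min_length)
      if (!is.null(hit)) {
        out[[length(out) + 1L]] <- dplyr::bind_cols(
          tibble(unit_a = units$unit_id[i], unit_b = units$unit_id[j]),
          hit[c("ani", "af_a", "af_b")])
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(unit_a = character(), unit_b = character(), ani = numeric(),
                  af_a = numeric(), af_b = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Normalize ANI edges by aligned fraction and screen
#'
#' The clustering edge weight is ANI corrected by the lowest of the two
#' aligned fractions, `score = ani * min(af_a, af_b) / 100^2`, on the
#' `[0, 1]` scale; edges scoring below `min_score` are removed.
#'
#' @param edges Tibble with `ani`, `af_a`, `af_b` (percent scales).
#' @param min_score Screen on the normalized score, default 0.70.
#' @return The surviving edges with a `score` column.
#' @export
normalize_and_screen <- function(edges, min_score = 0.70) {
  edges <- as_tibble(edges)
  stopifnot(all(c("ani", "af_a", "af_b") %in% names(edges)))
  if (nrow(edges) == 0) return(dplyr::mutate(edges, score = numeric()))
  if (any(edges$af_a < 0 | edges$af_a > 100 | edges$af_b < 0 | edges$af_b > 100)) {
    abort("aligned fractions must be in [0, 100]")
  }
  if (any(edges$ani < 0 | edges$ani > 100)) abort("ani must be in [0, 100]")
  edges |>
    dplyr::mutate(score = .data$ani * pmin(.data$af_a, .data$af_b) / 1e4) |>
    dplyr::filter(.data$score >= min_score)
}
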