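# Shared fixtures and independent oracles. Everything is generated in code;
# oracles never reuse the code path they are checking.

rand_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

# Independent ANI oracle: identity of one global pairwise alignment of the
# whole genomes (no fragmenting, no k-mer seeding).
oracle_global_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE),
    gapOpening = 6, gapExtension = 1)
  100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Erdos-Renyi edge list on named nodes.
random_graph <- function(n, p, seed, prefix = "n") {
  withr::with_seed(seed, {
    nodes <- sprintf("%s%03d", prefix, seq_len(n))
    pairs <- utils::combn(nodes, 2)
    keep <- runif(ncol(pairs)) < p
    list(nodes = nodes,
         edges = tibble::tibble(from = pairs[1, keep], to = pairs[2, keep]))
  })
}

# Planted-partition graph: `blocks` blocks of `size` nodes.
planted_graph <- function(blocks, size, p_in, p_out, seed) {
  withr::with_seed(seed, {
    n <- blocks * size
    nodes <- sprintf("v%03d", seq_len(n))
    block_of <- rep(seq_len(blocks), each = size)
    from <- character(0); to <- character(0)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        p <- if (block_of[i] == block_of[j]) p_in else p_out
        if (runif(1) < p) { from <- c(from, nodes[i]); to <- c(to, nodes[j]) }
      }
    }
    list(nodes = nodes, block_of = block_of,
         edges = tibble::tibble(from = from, to = to),
         partition = unname(split(nodes, block_of)))
  })
}

# Connected components by BFS over an edge list (oracle for MCL tests).
graph_components <- function(nodes, edges) {
  adj <- lapply(stats::setNames(vector("list", length(nodes)), nodes),
                function(x) character(0))
  for (i in seq_len(nrow(edges))) {
    adj[[edges$from[i]]] <- c(adj[[edges$from[i]]], edges$to[i])
    adj[[edges$to[i]]] <- c(adj[[edges$to[i]]], edges$from[i])
  }
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  k <- 0L
  for (s in nodes) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, adj[[v]][is.na(comp[adj[[v]]])])
    }
  }
  comp
}

same_partition <- function(a, b) {
  setequal(lapply(a, sort), lapply(b, sort))
}

tiny_samples <- function() {
  tibble::tibble(
    sample_id = c("s_ABE", "s_Mariner", "s_NWCA", "s_Plume1"),
    vent_field = c("Lau", "Lau", "Brothers", "Lau"),
    site = c("ABE", "Mariner", "NWC-A", "KiloMoana"),
    habitat = c("deposit", "deposit", "deposit", "plume"),
    total_reads = c(1e6L, 2e6L, 1e6L, 5e5L))
}
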