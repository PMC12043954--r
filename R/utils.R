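# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

# Substitution-only point mutation over an arbitrary alphabet; the replacement
# base is drawn uniformly from the other letters so a hit always changes state.
mutate_string <- function(x, rate, alphabet) {
  if (rate == 0) return(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  hits <- which(runif(length(chars)) < rate)
  if (length(hits) > 0) {
    idx <- match(chars[hits], alphabet)
    shift <- sample.int(length(alphabet) - 1L, length(hits), replace = TRUE)
    chars[hits] <- alphabet[(idx - 1L + shift) %% length(alphabet) + 1L]
  }
  paste(chars, collapse = "")
}

# All k-mers of a sequence starting at `starts` (1-based).
kmers_at <- function(seq, k, starts) {
  substring(seq, starts, starts + k - 1L)
}

assert_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    abort(sprintf("`%s` must be a single positive integer, got %s",
                  name, paste(format(x), collapse = ", ")))
  }
}

assert_fraction <- function(x, name, max = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > max) {
    abort(sprintf("`%s` must be a fraction in [0, %s]", name, format(max)))
  }
}
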