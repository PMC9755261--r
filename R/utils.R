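# Shared internal helpers.

BASES <- c("A", "C", "G", "T")

# Reverse complement of a plain character string (IUPAC ACGTN only).
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# all package randomness flows through this, never the global stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Deterministic child seed from (seed, k); keeps results below 2^31 so
# they remain valid R integers.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807 + 12345) %%
               2147483647)
}

# Split a string into single characters.
chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Random DNA string of length n using the current RNG state.
random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(BASES, n, replace = TRUE, prob = prob), collapse = "")
}
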