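# Small constructed fixtures shared across test files. Everything is built
# in code; nothing binary on disk.

# homopolymer sequence of one base
homopoly <- function(base, L = 60L) paste(rep(base, L), collapse = "")

# panel of K homopolymers (mutually 0% identical, maximally separable)
homopoly_panel <- function(bases = c("A", "C"), L = 60L) {
  reference_panel(paste0("homo_", bases),
                  vapply(bases, homopoly, character(1), L = L))
}

# deterministic pseudo-random sequence (independent of the package RNG use)
fixed_seq <- function(L, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), L,
                                      replace = TRUE), collapse = ""))
}

# small random panel for round-trip tests
small_panel <- function(K = 3L, L = 60L, seed = 11L) {
  make_reference_panel(K, L = L, min_divergence = 0.2, seed = seed)
}

# mixture spectra with known proportions, one list of spectrum_matrix
render_set <- function(panel, prop_matrix, scales = NULL, noise_sd = 0,
                       seed = NULL, prefix = "s") {
  if (is.null(scales)) scales <- rep(1, nrow(prop_matrix))
  if (!is.null(seed)) withr::local_seed(seed)
  lapply(seq_len(nrow(prop_matrix)), function(i) {
    render_spectrum(panel, prop_matrix[i, ], scale = scales[i],
                    noise_sd = noise_sd,
                    sample_id = sprintf("%s%02d", prefix, i))
  })
}

# independent Hamming identity (oracle for pairwise_identity / taxonomy)
hamming_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}
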