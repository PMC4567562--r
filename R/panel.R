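#' Reference panels of aligned 16S amplicon sequences
#'
#' A reference panel holds named, equal-length, gap-free DNA sequences over
#' `{A,C,G,T}` on a common position frame. Panels serve two roles: they are
#' the ground truth from which mixed chromatogram spectra are simulated, and
#' the lookup set against which base-called components are matched for
#' taxonomy assignment.
#'
#' @param names Character vector of taxon labels (unique).
#' @param sequences Character vector of DNA strings, all the same length
#'   (at least 50) and restricted to the alphabet `ACGT`.
#' @return An object of class `reference_panel`: a list with elements
#'   `names`, `sequences` and `L` (the common sequence length).
#' @examples
#' reference_panel(c("a", "b"), c("ACGTACGTACGT...", "TGCATGCATGCA..."))
#' @export
reference_panel <- function(names, sequences) {
  names <- as.character(names)
  sequences <- toupper(as.character(sequences))
  if (length(names) != length(sequences)) {
    stop("'names' and 'sequences' must have the same length")
  }
  if (anyDuplicated(names)) stop("panel names must be unique")
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("all panel sequences must have the same length")
  if (L < 50L) stop("panel sequences must be at least 50 bases long")
  if (any(grepl("[^ACGT]", sequences))) {
    stop("panel sequences must use the alphabet A, C, G, T only")
  }
  if (length(sequences) > 1L) {
    id <- pairwise_identity(sequences)
    if (any(id[upper.tri(id)] >= 1)) {
      stop("panel contains identical sequences; components must be distinguishable")
    }
  }
  structure(list(names = names, sequences = sequences, L = L),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d sequences of length %d\n",
              length(x$names), x$L))
  cat(paste0("  ", x$names, collapse = "\n"), "\n")
  invisible(x)
}

#' Pairwise sequence identity matrix
#'
#' Fraction of positions at which two equal-length sequences carry the same
#' base (Hamming identity). Used both to validate panels and as the
#' nearest-reference taxonomy score.
#'
#' @param sequences Character vector of equal-length DNA strings.
#' @return Symmetric matrix of identities in `[0, 1]`, unit diagonal.
#' @export
pairwise_identity <- function(sequences) {
  n <- length(sequences)
  chars <- lapply(sequences, function(s) strsplit(s, "")[[1]])
  out <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        out[i, j] <- out[j, i] <- mean(chars[[i]] == chars[[j]])
      }
    }
  }
  dimnames(out) <- list(names(sequences), names(sequences))
  out
}

#' Generate a random reference panel with a divergence guarantee
#'
#' Draws `K` i.i.d. random sequences of length `L` and rejects draws until
#' every pair is at most `1 - min_divergence` identical, so simulated
#' components are guaranteed distinguishable. Random sequences of length
#' ~450 have expected pairwise identity 0.25, so the default constraint is
#' reached on the first attempt almost always.
#'
#' @param K Number of components, `2 <= K <= 10` (K = 1 is allowed and
#'   trivially satisfies the constraint).
#' @param L Sequence length, default 450 (the length of the 16S fragment
#'   this analysis targets).
#' @param min_divergence Required minimum pairwise divergence in `(0, 1)`.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param max_tries Attempts before giving up.
#' @param names Optional taxon labels; defaults to `component_1..K`.
#' @return A [reference_panel].
#' @export
make_reference_panel <- function(K, L = 450L, min_divergence = 0.1,
                                 seed = 1L, max_tries = 100L, names = NULL) {
  stopifnot(K >= 1, K <= 10, L >= 50)
  if (min_divergence <= 0 || min_divergence >= 1) {
    stop("'min_divergence' must be in (0, 1)")
  }
  if (is.null(names)) names <- sprintf("component_%d", seq_len(K))
  rng <- local_rng(seed)
  bases <- c("A", "C", "G", "T")
  for (try in seq_len(max_tries)) {
    seqs <- vapply(seq_len(K), function(k) {
      paste(sample(bases, L, replace = TRUE), collapse = "")
    }, character(1))
    if (K == 1L) return(reference_panel(names, seqs))
    id <- pairwise_identity(seqs)
    if (max(id[upper.tri(id)]) <= 1 - min_divergence) {
      return(reference_panel(names, seqs))
    }
  }
  stop(sprintf(
    "could not draw %d sequences with pairwise identity <= %.3f in %d tries",
    K, 1 - min_divergence, max_tries))
}

#' Write a reference panel (or any named sequences) to FASTA
#' @param panel A [reference_panel] or named character vector of sequences.
#' @param path Output file path.
#' @export
write_panel_fasta <- function(panel, path) {
  if (inherits(panel, "reference_panel")) {
    seqs <- stats::setNames(panel$sequences, panel$names)
  } else {
    seqs <- panel
  }
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = 70L)
  invisible(path)
}

#' Read a reference panel from FASTA
#' @param path FASTA file of equal-length, gap-free sequences.
#' @return A [reference_panel].
#' @export
read_panel_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  reference_panel(names(ss), as.character(ss))
}

# Seed the RNG for the lifetime of the calling function, restoring the
# caller's state afterwards. All stochastic entry points use this so that
# seeding is explicit and never leaks.
local_rng <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(NULL)
}
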