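CHANNELS <- c("A", "C", "G", "T")

#' Chromatogram spectrum of one sample
#'
#' A mixed-template Sanger chromatogram reduced to a per-position,
#' four-channel intensity matrix: row `i` holds the A, C, G, T signal at
#' aligned position `i`. Intensities are non-negative and carry the
#' (arbitrary) units of the sequencer; every operation downstream is either
#' scale-invariant or normalizes explicitly. Channel order is fixed as
#' A, C, G, T everywhere in the package.
#'
#' @param intensities Numeric `L x 4` matrix of non-negative values.
#' @param sample_id Sample identifier string.
#' @return Object of class `spectrum_matrix`: a list with `sample_id` and
#'   `intensities` (with channel column names).
#' @export
spectrum_matrix <- function(intensities, sample_id = "sample") {
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != 4L) stop("spectrum must have exactly 4 channels")
  if (nrow(intensities) < 1L) stop("spectrum must have at least one position")
  if (!all(is.finite(intensities))) stop("spectrum intensities must be finite")
  if (any(intensities < 0)) stop("spectrum intensities must be non-negative")
  colnames(intensities) <- CHANNELS
  rownames(intensities) <- NULL
  structure(list(sample_id = as.character(sample_id),
                 intensities = intensities),
            class = "spectrum_matrix")
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat(sprintf("<spectrum_matrix> '%s': %d positions x 4 channels (A,C,G,T)\n",
              x$sample_id, nrow(x$intensities)))
  invisible(x)
}

#' Dominant-base call of a spectrum
#'
#' Per position, the channel with the highest intensity; `N` where the top
#' two channels are within a relative tie tolerance of each other or the
#' position carries no signal at all. The tie rule makes base-calling
#' deterministic: an ambiguous position never resolves by floating-point
#' accident.
#'
#' @param s A [spectrum_matrix] or a plain `L x 4` intensity matrix.
#' @param tie_tol Relative tolerance below which the top two channels are
#'   considered tied (default `1e-9`).
#' @return A DNA string of length `L` over `{A,C,G,T,N}`.
#' @export
dominant_basecall <- function(s, tie_tol = 1e-9) {
  X <- if (inherits(s, "spectrum_matrix")) s$intensities else as.matrix(s)
  calls <- apply(X, 1L, function(row) {
    if (all(row <= 0)) return("N")
    ord <- order(row, decreasing = TRUE)
    top <- row[ord[1L]]
    if (top - row[ord[2L]] <= tie_tol * top) return("N")
    CHANNELS[ord[1L]]
  })
  paste(calls, collapse = "")
}

#' Align a set of spectra onto a common position frame
#'
#' All downstream analysis (the bilinear factorization, the mixing-based
#' alpha-diversity) assumes every sample's position `i` refers to the same
#' template position. Amplicons primed at a fixed site differ only by small
#' integer shifts, so alignment is by integer offset: the sample of median
#' length anchors the frame, every sample is shifted by the lag that
#' maximizes the cross-correlation between its four-channel intensity
#' profile and the consensus (per-position mean) profile of all samples,
#' and all frames are cropped to the common overlap.
#'
#' Two details matter for mixed chromatograms. The correlation must be
#' channel-resolved: the per-position total is nearly flat (every position
#' sums to about the same overall signal), so totals alone carry almost no
#' positional information. And the reference must be the consensus rather
#' than any single sample: two samples dominated by different community
#' members share channel structure only at the minority of positions where
#' their sequences coincide, whereas the consensus contains every
#' component and correlates sharply with each sample at the true lag.
#'
#' The reported `offsets` follow the convention that common-frame position
#' `j` reads sample position `j - offset`; a sample whose content starts
#' three positions later than the anchor therefore gets offset `-3`. Ties in
#' the correlation score resolve to the smallest absolute lag (then the
#' negative one), keeping alignment idempotent.
#'
#' @param samples List of [spectrum_matrix] objects.
#' @param max_shift Search window for the lag, default `25` positions.
#' @return Object of class `aligned_set`: list with `spectra` (cropped,
#'   same length `L*`), `offsets` (named integer vector, anchor = 0),
#'   `anchor` (sample id), `L` (common frame length) and `gap` (logical
#'   vector, `TRUE` at positions excluded from fitting; all `FALSE` after
#'   cropping, kept for interface stability).
#' @export
align_spectra <- function(samples, max_shift = 25L) {
  if (length(samples) == 0L) stop("no spectra to align")
  stopifnot(all(vapply(samples, inherits, logical(1), "spectrum_matrix")))
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  lens <- vapply(samples, function(s) nrow(s$intensities), integer(1))
  if (length(samples) == 1L) {
    return(structure(list(spectra = samples,
                          offsets = stats::setNames(0L, ids),
                          anchor = ids[1L], L = lens[1L],
                          gap = rep(FALSE, lens[1L])),
                     class = "aligned_set"))
  }
  anchor_idx <- which.min(abs(lens - stats::median(lens)))
  Lc <- min(lens)
  consensus <- Reduce(`+`, lapply(samples, function(s) {
    s$intensities[seq_len(Lc), , drop = FALSE]
  })) / length(samples)

  offsets <- vapply(seq_along(samples), function(n) {
    best_lag(consensus, samples[[n]]$intensities, max_shift)
  }, integer(1))
  # the frame is pinned to the median-length anchor sample
  offsets <- offsets - offsets[anchor_idx]

  # common frame position j maps to sample position j - offset (1-based
  # internally; the CSV interface is 0-based)
  lo <- max(1L + offsets)
  hi <- min(lens + offsets)
  if (hi < lo) stop("no common overlap between spectra after shifting")
  cropped <- lapply(seq_along(samples), function(n) {
    idx <- (lo:hi) - offsets[n]
    spectrum_matrix(samples[[n]]$intensities[idx, , drop = FALSE], ids[n])
  })
  structure(list(spectra = cropped,
                 offsets = stats::setNames(offsets, ids),
                 anchor = ids[anchor_idx],
                 L = hi - lo + 1L,
                 gap = rep(FALSE, hi - lo + 1L)),
            class = "aligned_set")
}

# Lag maximizing sum over positions j and channels b of
# anchor[j, b] * sample[j - lag, b] over the valid overlap; ties go to
# the smallest |lag|, then to the negative lag.
best_lag <- function(anchor, prof, max_shift) {
  lags <- seq.int(-max_shift, max_shift)
  scores <- vapply(lags, function(lag) {
    j <- seq_len(nrow(anchor))
    i <- j - lag
    ok <- i >= 1L & i <= nrow(prof)
    if (!any(ok)) return(-Inf)
    sum(anchor[j[ok], ] * prof[i[ok], ])
  }, numeric(1))
  best <- scores >= max(scores) - 1e-12 * abs(max(scores))
  cand <- lags[best]
  cand[order(abs(cand), cand)][1L]
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("<aligned_set> %d spectra on a common frame of %d positions (anchor '%s')\n",
              length(x$spectra), x$L, x$anchor))
  invisible(x)
}

# Subset an aligned set without re-aligning: the common frame is already
# established, so dropping samples must not change it.
subset_aligned <- function(aligned, idx) {
  stopifnot(inherits(aligned, "aligned_set"))
  structure(list(spectra = aligned$spectra[idx],
                 offsets = aligned$offsets[idx],
                 anchor = aligned$anchor, L = aligned$L,
                 gap = aligned$gap),
            class = "aligned_set")
}

#' Stack an aligned set into a samples x features matrix
#'
#' Feature order is position-major with channels contiguous: columns
#' `1..4` are position 1 (A,C,G,T), columns `5..8` position 2, and so on.
#' This is the layout the factorization operates on.
#'
#' @param aligned An [align_spectra] result.
#' @return Numeric `N x (4 L)` matrix with sample ids as row names.
#' @export
stack_spectra <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_set"))
  X <- t(vapply(aligned$spectra,
                function(s) as.vector(t(s$intensities)),
                numeric(4L * aligned$L)))
  rownames(X) <- vapply(aligned$spectra, function(s) s$sample_id, character(1))
  X
}

# Inverse of stack_spectra for one row.
unstack_row <- function(row) {
  matrix(row, ncol = 4L, byrow = TRUE, dimnames = list(NULL, CHANNELS))
}

#' Write / read spectra as per-sample CSV files
#'
#' One CSV per sample, header `pos,A,C,G,T`, positions 0-based. The file
#' name is `<sample_id>.csv` under `dir`.
#'
#' @param samples List of [spectrum_matrix] objects.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths.
#' @export
write_spectra_csv <- function(samples, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(samples, function(s) {
    df <- data.frame(pos = seq_len(nrow(s$intensities)) - 1L, s$intensities)
    path <- file.path(dir, paste0(s$sample_id, ".csv"))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
  }, character(1))
  invisible(paths)
}

#' @rdname write_spectra_csv
#' @param paths CSV files to read (each one sample).
#' @export
read_spectra_csv <- function(paths) {
  lapply(paths, function(path) {
    df <- utils::read.csv(path)
    need <- c("pos", CHANNELS)
    if (!all(need %in% names(df))) {
      stop("spectral CSV must have columns pos,A,C,G,T: ", path)
    }
    df <- df[order(df$pos), , drop = FALSE]
    spectrum_matrix(as.matrix(df[, CHANNELS]),
                    sample_id = sub("\\.csv$", "", basename(path)))
  })
}
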