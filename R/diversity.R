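#' Nucleotide-mixing alpha-diversity of one spectrum
#'
#' A Simpson-type diversity computed directly from the raw aligned
#' chromatogram, without any decomposition: at each position the four
#' channel intensities are turned into proportions `p_b`, the position's
#' mixing index is the Gini-Simpson value `1 - sum(p_b^2)`, and the
#' sample's alpha is the mean over positions carrying usable signal. A
#' pure single-template chromatogram scores 0; the theoretical maximum
#' with four channels is `1 - 4 (1/4)^2 = 0.75`. Positions whose total
#' signal falls below the floor are excluded so that empty, noise-only
#' positions cannot inflate the index.
#'
#' The index is internal to the mixed-sequencing approach: its scale
#' depends on how templates differ across positions, so values are
#' comparable between samples profiled the same way but not with
#' OTU-based diversity measures.
#'
#' @param s A [spectrum_matrix].
#' @param min_total_signal Absolute signal floor per position; by default
#'   5% of the sample's own mean per-position total intensity.
#' @return List (class `diversity_result`) with `sample_id`, `alpha` in
#'   `[0, 0.75]` and `n_positions` used.
#' @export
alpha_diversity <- function(s, min_total_signal = NULL) {
  stopifnot(inherits(s, "spectrum_matrix"))
  X <- s$intensities
  totals <- rowSums(X)
  if (is.null(min_total_signal)) min_total_signal <- 0.05 * mean(totals)
  use <- totals >= min_total_signal & totals > 0
  if (!any(use)) stop("no positions above the signal floor in sample '",
                      s$sample_id, "'")
  P <- X[use, , drop = FALSE] / totals[use]
  d <- 1 - rowSums(P^2)
  structure(list(sample_id = s$sample_id, alpha = mean(d),
                 n_positions = sum(use)),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("<diversity_result> '%s': alpha = %.4f over %d positions\n",
              x$sample_id, x$alpha, x$n_positions))
  invisible(x)
}

#' Alpha-diversity table for a set of samples
#'
#' @param samples List of [spectrum_matrix] (typically the `spectra` slot
#'   of an [align_spectra()] result).
#' @param min_total_signal Passed to [alpha_diversity()].
#' @return data.frame `sample_id, alpha, n_positions`.
#' @export
alpha_diversity_table <- function(samples, min_total_signal = NULL) {
  rows <- lapply(samples, function(s) {
    r <- alpha_diversity(s, min_total_signal)
    data.frame(sample_id = r$sample_id, alpha = r$alpha,
               n_positions = r$n_positions)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-group (monthly) alpha-diversity summary
#'
#' Group mean, sample SD and SEM of per-sample alpha values, in the order
#' the grouping factor defines. Groups of size one report SD and SEM as 0
#' and are flagged.
#'
#' @param alpha_table An [alpha_diversity_table()] result (or any
#'   data.frame with `sample_id` and `alpha`).
#' @param meta data.frame with `sample_id` and `month`.
#' @return data.frame `month, n, mean, sd, sem, singleton`.
#' @export
group_alpha <- function(alpha_table, meta) {
  merged <- merge(alpha_table, meta[, c("sample_id", "month")],
                  by = "sample_id")
  if (nrow(merged) == 0L) stop("no samples shared between table and metadata")
  g <- grouped_series(split(merged$alpha, merged$month, drop = TRUE))
  s <- summarize_groups(g)
  names(s)[names(s) == "group"] <- "month"
  s
}
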