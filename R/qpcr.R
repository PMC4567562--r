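#' qPCR record constructor and CSV reader
#'
#' One record is one reaction: a sample, a target (`bee` for the host
#' vitellogenin assay, `bacteria` for the universal 16S assay, or a
#' species name in the competition experiment), its cycle-threshold CT and
#' its per-cycle amplification efficiency. Efficiencies are inputs,
#' estimated upstream from the raw fluorescence curves (e.g. by the
#' window-of-linearity method); 2.0 means perfect doubling.
#'
#' @param sample_id Sample identifier.
#' @param target Target label.
#' @param ct Cycle threshold, finite and positive.
#' @param efficiency Amplification factor in `(1, 2]`.
#' @return A one-row data.frame `sample_id, target, ct, efficiency`.
#' @export
qpcr_record <- function(sample_id, target, ct, efficiency) {
  validate_qpcr(ct, efficiency)
  data.frame(sample_id = as.character(sample_id),
             target = as.character(target),
             ct = as.numeric(ct), efficiency = as.numeric(efficiency))
}

validate_qpcr <- function(ct, efficiency) {
  if (any(!is.finite(ct)) || any(ct <= 0)) {
    stop("CT values must be finite and positive")
  }
  if (any(efficiency <= 1) || any(efficiency > 2)) {
    stop("amplification efficiencies must lie in (1, 2]")
  }
  invisible(TRUE)
}

#' @rdname qpcr_record
#' @param path CSV with columns `sample_id, target, ct, efficiency`.
#' @export
read_qpcr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "target", "ct", "efficiency")
  if (!all(need %in% names(df))) {
    stop("qPCR CSV must have columns sample_id,target,ct,efficiency")
  }
  validate_qpcr(df$ct, df$efficiency)
  df[, need]
}

#' Log relative bacteria/bee DNA ratio from a paired qPCR
#'
#' The efficiency-weighted delta-CT: for a starting quantity `Q` amplified
#' with efficiency `E`, `Q` is proportional to `E^(-CT)`, so the log10
#' ratio of bacterial to host DNA is
#' `log10(E_bee) * CT_bee - log10(E_bact) * CT_bact`. Logs are base 10
#' throughout (the qPCR convention); with both efficiencies at 2.0 one
#' cycle of CT difference is `log10(2) ~ 0.301` units of log ratio. Lower
#' bacterial CT (more bacterial template) gives a larger ratio.
#'
#' @param bee Host (vitellogenin) reaction: one-row data.frame as from
#'   [qpcr_record()].
#' @param bact Bacterial (16S) reaction for the same sample.
#' @return List (class `load_result`) with `sample_id` and `log_ratio`.
#' @export
relative_load <- function(bee, bact) {
  stopifnot(nrow(bee) == 1L, nrow(bact) == 1L)
  if (bee$sample_id != bact$sample_id) {
    stop("records belong to different samples: '", bee$sample_id,
         "' vs '", bact$sample_id, "'")
  }
  validate_qpcr(c(bee$ct, bact$ct), c(bee$efficiency, bact$efficiency))
  lr <- log10(bee$efficiency) * bee$ct - log10(bact$efficiency) * bact$ct
  structure(list(sample_id = bee$sample_id, log_ratio = lr),
            class = "load_result")
}

#' @export
print.load_result <- function(x, ...) {
  cat(sprintf("<load_result> '%s': log10 bacteria/bee ratio = %.4f\n",
              x$sample_id, x$log_ratio))
  invisible(x)
}

#' Relative-load table for a whole qPCR run
#'
#' Pairs each sample's `bee` and `bacteria` reactions and applies
#' [relative_load()]. Samples missing either reaction are dropped with a
#' warning.
#'
#' @param records data.frame as read by [read_qpcr_csv()].
#' @return data.frame `sample_id, log_ratio`.
#' @export
relative_load_table <- function(records) {
  ids <- unique(records$sample_id)
  rows <- lapply(ids, function(id) {
    bee <- records[records$sample_id == id & records$target == "bee", ]
    bact <- records[records$sample_id == id & records$target == "bacteria", ]
    if (nrow(bee) != 1L || nrow(bact) != 1L) return(NULL)
    r <- relative_load(bee, bact)
    data.frame(sample_id = r$sample_id, log_ratio = r$log_ratio)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L) {
    warning(dropped, " sample(s) without a complete bee/bacteria pair dropped")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Growth-suppression ratio from the competition experiment
#'
#' For one bacterium grown alone and together with a competitor, the ratio
#' of efficiency-corrected quantities
#' `E^(-CT_alone) / E^(-CT_together) = 10^(log10(E) * (CT_together - CT_alone))`.
#' A ratio above 1 means the bacterium grew worse in co-culture
#' (suppression); 1 means no effect.
#'
#' @param alone Reaction of the bacterium cultured alone.
#' @param together Reaction of the same bacterium in co-culture; must
#'   share the target label and efficiency.
#' @return Positive numeric ratio.
#' @export
competition_ratio <- function(alone, together) {
  stopifnot(nrow(alone) == 1L, nrow(together) == 1L)
  if (alone$target != together$target) {
    stop("competition ratio compares the same bacterium: '", alone$target,
         "' vs '", together$target, "'")
  }
  if (alone$efficiency != together$efficiency) {
    stop("alone/together records must share the efficiency model")
  }
  validate_qpcr(c(alone$ct, together$ct),
                c(alone$efficiency, together$efficiency))
  10^(log10(alone$efficiency) * (together$ct - alone$ct))
}

#' Summarize competition replicates
#'
#' Per-replicate alone:together ratios plus mean, SD, SEM, and a two-sided
#' one-sample t-test of the log10 ratios against 0 (i.e. ratio 1, no
#' suppression).
#'
#' @param alone,together data.frames of replicate reactions (same target),
#'   matched by row order.
#' @return List with `ratios`, `mean`, `sd`, `sem`, `t`, `df`, `p`.
#' @export
competition_summary <- function(alone, together) {
  if (nrow(alone) != nrow(together)) {
    stop("'alone' and 'together' must have the same number of replicates")
  }
  ratios <- vapply(seq_len(nrow(alone)), function(i) {
    competition_ratio(alone[i, , drop = FALSE], together[i, , drop = FALSE])
  }, numeric(1))
  n <- length(ratios)
  lg <- log10(ratios)
  res <- list(ratios = ratios, mean = mean(ratios),
              sd = if (n > 1L) stats::sd(ratios) else 0,
              sem = if (n > 1L) stats::sd(ratios) / sqrt(n) else 0,
              t = NA_real_, df = NA_real_, p = NA_real_)
  if (n > 1L && stats::sd(lg) > 0) {
    tt <- stats::t.test(lg, mu = 0)
    res$t <- unname(tt$statistic)
    res$df <- unname(tt$parameter)
    res$p <- tt$p.value
  }
  res
}

#' Write a relative-load table to TSV
#' @param load_table A [relative_load_table()] result.
#' @param path Output path.
#' @export
write_load_tsv <- function(load_table, path) {
  utils::write.table(load_table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
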