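#' Mixing design for simulated seasonal datasets
#'
#' Describes the sampling design the generator emulates: an ordered set of
#' time points (months), a mean mixing-proportion vector per month for each
#' latent bacterial component, a fixed number of bees per month, and the
#' nuisance structure of real chromatograms — between-bee variation around
#' the monthly mean, per-sample total-signal variation (no closure: the
#' proportions need not sum to one and the overall signal level differs
#' between bees), additive channel noise, and a fraction of low-quality
#' samples rendered with inflated noise.
#'
#' @param months Ordered character vector of time-point labels.
#' @param proportions Numeric matrix, `length(months)` rows x K components,
#'   non-negative; row sums may be below 1 (the deficit is residual signal
#'   the factor model is not asked to explain).
#' @param bees_per_month Samples per time point (default 30: ten bees from
#'   each of three colonies).
#' @param dispersion Concentration of the Dirichlet perturbation applied to
#'   the monthly mean to get per-bee proportions; larger is tighter.
#'   `Inf` disables the perturbation. Default 100 gives a within-month SD
#'   of roughly 0.05 on a component near 0.3.
#' @param sample_scale_sd Log-normal SD of the per-sample total-signal
#'   factor (default 0.1).
#' @param noise_sd Channel noise SD in units of the pure-signal amplitude
#'   (default 0.1, i.e. 10% of a pure single-template peak).
#' @param lowquality_fraction Fraction of samples rendered with inflated
#'   noise (default 0.15, the attrition level typical of mixed-template
#'   Sanger runs).
#' @param noise_inflation Noise multiplier for low-quality samples
#'   (default 10).
#' @param n_colonies Colonies bees are cycled over for the metadata
#'   (default 3).
#' @param dataset Dataset label recorded in the metadata.
#' @param seed Integer seed.
#' @return Object of class `mixing_design`.
#' @export
mixing_design <- function(months, proportions, bees_per_month = 30L,
                          dispersion = 100, sample_scale_sd = 0.1,
                          noise_sd = 0.1, lowquality_fraction = 0.15,
                          noise_inflation = 10, n_colonies = 3L,
                          dataset = "seasonal", seed = 1L) {
  proportions <- as.matrix(proportions)
  if (nrow(proportions) != length(months)) {
    stop("'proportions' must have one row per month")
  }
  if (any(proportions < 0)) stop("mixing proportions must be non-negative")
  stopifnot(bees_per_month >= 1, dispersion > 0, sample_scale_sd >= 0,
            noise_sd >= 0, noise_inflation >= 1)
  if (lowquality_fraction < 0 || lowquality_fraction > 1) {
    stop("'lowquality_fraction' must be in [0, 1]")
  }
  rownames(proportions) <- months
  structure(list(months = as.character(months), proportions = proportions,
                 bees_per_month = as.integer(bees_per_month),
                 dispersion = dispersion, sample_scale_sd = sample_scale_sd,
                 noise_sd = noise_sd,
                 lowquality_fraction = lowquality_fraction,
                 noise_inflation = noise_inflation,
                 n_colonies = as.integer(n_colonies),
                 dataset = dataset, seed = as.integer(seed)),
            class = "mixing_design")
}

#' Built-in design presets
#'
#' `seasonal_design()` is a six-month foraging-season trajectory for four
#' components: a dominant component declining through the season, one
#' peaking in late summer, one peaking in early autumn, and one that stays
#' rare before rising roughly eight-fold into the final month. Row sums stay
#' below 1 — the score axis is open, not compositional.
#' `stable_design()` is a two-time-point winter dataset (24 and 30 bees)
#' with five components at constant proportions, for testing that a stable
#' community yields no significant differences.
#'
#' @param ... Overrides passed to [mixing_design()].
#' @return A `mixing_design`.
#' @export
seasonal_design <- function(...) {
  p <- rbind(
    May = c(0.80, 0.05, 0.04, 0.05),
    Jun = c(0.70, 0.08, 0.06, 0.05),
    Jul = c(0.55, 0.12, 0.10, 0.04),
    Aug = c(0.35, 0.30, 0.15, 0.02),
    Sep = c(0.20, 0.15, 0.35, 0.05),
    Oct = c(0.10, 0.08, 0.12, 0.40))
  colnames(p) <- c("Gilliamella_apicola", "Frischella_perrara",
                   "Enterobacteriaceae", "Snodgrassella_alvi")
  defaults <- list(months = rownames(p), proportions = p,
                   dataset = "seasonal")
  do.call(mixing_design, utils::modifyList(defaults, list(...)))
}

#' @rdname seasonal_design
#' @export
stable_design <- function(...) {
  p <- rbind(Nov = c(0.35, 0.20, 0.15, 0.10, 0.08),
             Feb = c(0.35, 0.20, 0.15, 0.10, 0.08))
  colnames(p) <- sprintf("component_%d", 1:5)
  defaults <- list(months = rownames(p), proportions = p,
                   bees_per_month = 30L, dataset = "stable")
  design <- do.call(mixing_design, utils::modifyList(defaults, list(...)))
  # November has 24 bees, February 30, unless overridden
  if (!("bees_per_month" %in% names(list(...)))) {
    design$bees_per_month <- c(Nov = 24L, Feb = 30L)
  }
  design
}

#' Render one mixed chromatogram spectrum
#'
#' The generative model the decomposition inverts: at each position the
#' expected signal in channel `b` is `scale` times the summed proportion of
#' the panel sequences carrying base `b` there, plus Gaussian channel noise
#' truncated below at zero (intensities are physically non-negative).
#'
#' @param panel A [reference_panel].
#' @param proportions Non-negative vector, one entry per panel sequence.
#' @param scale Positive total-signal factor.
#' @param noise_sd Channel noise SD (0 for a noiseless render).
#' @param seed Optional seed; omit to draw from the current RNG stream.
#' @param sample_id Sample identifier.
#' @return A [spectrum_matrix].
#' @export
render_spectrum <- function(panel, proportions, scale = 1, noise_sd = 0,
                            seed = NULL, sample_id = "sample") {
  stopifnot(inherits(panel, "reference_panel"), scale > 0, noise_sd >= 0)
  K <- length(panel$sequences)
  if (length(proportions) != K) {
    stop("'proportions' must have one entry per panel sequence")
  }
  if (any(proportions < 0)) stop("proportions must be non-negative")
  local_rng(seed)
  v <- as.vector(panel_signal(panel) %*% proportions) * scale
  X <- matrix(v, ncol = 4L, byrow = TRUE)
  if (noise_sd > 0) {
    X <- X + matrix(stats::rnorm(length(X), 0, noise_sd), nrow = nrow(X))
    X[X < 0] <- 0
  }
  spectrum_matrix(X, sample_id)
}

# (4L) x K indicator matrix: entry [(i-1)*4 + b, k] = 1 iff sequence k has
# base b at position i. Cached per panel content.
panel_signal <- function(panel) {
  K <- length(panel$sequences)
  M <- matrix(0, nrow = 4L * panel$L, ncol = K)
  for (k in seq_len(K)) {
    b <- match(strsplit(panel$sequences[k], "")[[1]], CHANNELS)
    M[(seq_len(panel$L) - 1L) * 4L + b, k] <- 1
  }
  M
}

# Per-bee proportions for one month: Dirichlet perturbation around the
# monthly mean with an extra residual category absorbing the closure
# deficit, so draws keep E[p] = mean and need not sum to one.
draw_proportions <- function(mean_p, dispersion, n) {
  K <- length(mean_p)
  if (is.infinite(dispersion)) {
    return(matrix(rep(mean_p, each = n), nrow = n))
  }
  resid <- max(1 - sum(mean_p), 1e-6)
  alpha <- dispersion * c(mean_p, resid)
  draws <- matrix(stats::rgamma(n * (K + 1L), shape = rep(alpha, each = n)),
                  nrow = n)
  draws <- draws / rowSums(draws)
  p <- draws[, seq_len(K), drop = FALSE] * sum(c(mean_p, resid))
  p[p < 0] <- 0
  p
}

#' Simulate a full seasonal dataset of chromatogram spectra
#'
#' For every month, draws per-bee mixing proportions around the design's
#' monthly mean, a per-bee log-normal total-signal factor, flags a fixed
#' fraction of bees as low quality, and renders each bee's spectrum with
#' [render_spectrum()] (low-quality bees get `noise_sd` multiplied by the
#' design's inflation factor). Deterministic under the design seed.
#'
#' @param panel A [reference_panel] with as many sequences as the design
#'   has components.
#' @param design A [mixing_design].
#' @return List with `spectra` (list of [spectrum_matrix]), `meta`
#'   (data.frame `sample_id, month, colony, dataset`) and `truth`
#'   (data.frame with the true proportion vector, scale and quality flag
#'   per sample; proportion columns named `p_<component>`).
#' @export
simulate_dataset <- function(panel, design) {
  stopifnot(inherits(panel, "reference_panel"),
            inherits(design, "mixing_design"))
  K <- ncol(design$proportions)
  if (length(panel$sequences) != K) {
    stop("panel size does not match the number of design components")
  }
  local_rng(design$seed)
  bees <- design$bees_per_month
  if (length(bees) == 1L) {
    bees <- stats::setNames(rep(bees, length(design$months)), design$months)
  }
  n_total <- sum(bees)
  n_lq <- round(design$lowquality_fraction * n_total)
  lq_global <- rep(FALSE, n_total)
  lq_global[sample.int(n_total, n_lq)] <- TRUE

  spectra <- vector("list", n_total)
  meta <- vector("list", length(design$months))
  truth <- vector("list", length(design$months))
  at <- 0L
  for (m in seq_along(design$months)) {
    n <- bees[[m]]
    month <- design$months[m]
    ids <- sprintf("%s_%s_bee%02d", design$dataset, month, seq_len(n))
    p <- draw_proportions(design$proportions[m, ], design$dispersion, n)
    scl <- stats::rlnorm(n, meanlog = 0, sdlog = design$sample_scale_sd)
    lq <- lq_global[at + seq_len(n)]
    sd_i <- ifelse(lq, design$noise_sd * design$noise_inflation,
                   design$noise_sd)
    for (i in seq_len(n)) {
      spectra[[at + i]] <- render_spectrum(panel, p[i, ], scale = scl[i],
                                           noise_sd = sd_i[i],
                                           sample_id = ids[i])
    }
    meta[[m]] <- data.frame(sample_id = ids, month = month,
                            colony = ((seq_len(n) - 1L) %% design$n_colonies) + 1L,
                            dataset = design$dataset)
    tr <- data.frame(sample_id = ids, scale = scl, low_quality = lq)
    colnames(p) <- paste0("p_", colnames(design$proportions))
    truth[[m]] <- cbind(tr, p)
    at <- at + n
  }
  meta <- do.call(rbind, meta)
  truth <- do.call(rbind, truth)
  rownames(meta) <- rownames(truth) <- NULL
  meta$month <- factor(meta$month, levels = design$months)
  list(spectra = spectra, meta = meta, truth = truth)
}

#' Draw design-level per-bee mixing proportions only
#'
#' The truth layer of [simulate_dataset()] without any chromatogram
#' rendering: per-bee proportion vectors around each month's mean under
#' the design's dispersion. Useful for studying the statistical power of
#' the sampling design itself, where the measurement model is not the
#' question.
#'
#' @param design A [mixing_design].
#' @param seed Seed; defaults to the design's.
#' @return data.frame with `month` (factor in design order) and one
#'   `p_<component>` column per component.
#' @export
simulate_proportions <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "mixing_design"))
  local_rng(seed)
  bees <- design$bees_per_month
  if (length(bees) == 1L) {
    bees <- stats::setNames(rep(bees, length(design$months)), design$months)
  }
  out <- do.call(rbind, lapply(seq_along(design$months), function(m) {
    p <- draw_proportions(design$proportions[m, ], design$dispersion,
                          bees[[m]])
    colnames(p) <- paste0("p_", colnames(design$proportions))
    data.frame(month = design$months[m], p, check.names = FALSE)
  }))
  out$month <- factor(out$month, levels = design$months)
  out
}

#' Simulate paired 16S/vitellogenin qPCR records
#'
#' The generative inverse of [relative_load()]: for each sample a bacterial
#' CT is drawn around a baseline and the host (bee) CT is set so that the
#' noiseless pair reproduces `log10(true_load_ratio)` exactly under the
#' stated efficiencies; optional Gaussian CT noise is then added to both
#' reactions.
#'
#' @param true_load_ratio Positive vector of true bacteria/bee ratios
#'   (one per sample); the noiseless round trip returns their `log10`.
#' @param efficiencies Length-2 vector `c(bee, bacteria)` of per-cycle
#'   amplification factors in `(1, 2]`.
#' @param ct_noise_sd SD of CT noise in cycles (default 0).
#' @param base_ct Baseline bacterial CT (default 25).
#' @param seed Integer seed.
#' @param sample_ids Optional ids, default `qpcr_1..n`.
#' @return data.frame `sample_id, target, ct, efficiency` with one `bee`
#'   and one `bacteria` row per sample (the package's qPCR CSV layout).
#' @export
simulate_qpcr <- function(true_load_ratio, efficiencies = c(2, 2),
                          ct_noise_sd = 0, base_ct = 25, seed = 1L,
                          sample_ids = NULL) {
  if (any(true_load_ratio <= 0)) stop("'true_load_ratio' must be positive")
  if (any(efficiencies <= 1) || any(efficiencies > 2)) {
    stop("amplification efficiencies must lie in (1, 2]")
  }
  stopifnot(ct_noise_sd >= 0)
  local_rng(seed)
  n <- length(true_load_ratio)
  if (is.null(sample_ids)) sample_ids <- sprintf("qpcr_%d", seq_len(n))
  e_bee <- efficiencies[1]; e_bact <- efficiencies[2]
  ct_bact <- rep(base_ct, n)
  ct_bee <- (log10(true_load_ratio) + log10(e_bact) * ct_bact) / log10(e_bee)
  if (ct_noise_sd > 0) {
    ct_bact <- ct_bact + stats::rnorm(n, 0, ct_noise_sd)
    ct_bee <- ct_bee + stats::rnorm(n, 0, ct_noise_sd)
  }
  data.frame(sample_id = rep(sample_ids, each = 2L),
             target = rep(c("bee", "bacteria"), times = n),
             ct = as.vector(rbind(ct_bee, ct_bact)),
             efficiency = rep(c(e_bee, e_bact), times = n))
}

#' Write the simulation metadata / truth files
#'
#' Metadata goes to TSV (`sample_id, month, colony, dataset`), the truth
#' records to JSON. Companions to [write_spectra_csv()].
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  spectra_dir <- file.path(dir, "spectra")
  write_spectra_csv(sim$spectra, spectra_dir)
  meta_path <- file.path(dir, "meta.tsv")
  utils::write.table(sim$meta, meta_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, truth_path, digits = NA, dataframe = "rows")
  invisible(c(meta = meta_path, truth = truth_path, spectra = spectra_dir))
}
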