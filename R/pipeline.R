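#' Configuration of a full pipeline run
#'
#' One declarative object drives the whole analysis. In `simulate` mode
#' the run generates its own data from a design and panel; in `load` mode
#' it reads spectra CSVs, a metadata TSV, a panel FASTA and (optionally)
#' a qPCR CSV written earlier.
#'
#' @param mode `"simulate"` or `"load"`.
#' @param design A [mixing_design] (simulate mode).
#' @param panel A [reference_panel] (simulate mode; in load mode read
#'   from `panel_fasta`).
#' @param paths Named list for load mode: `spectra_dir`, `meta_tsv`,
#'   `panel_fasta`, optional `qpcr_csv`.
#' @param K Number of components, or `"auto"` to use [estimate_k()].
#' @param variance_threshold Threshold for `K = "auto"` (default 0.95).
#' @param max_iter,tol ALS controls (defaults 500, 1e-8).
#' @param quality_threshold Residual-fraction cut of [quality_filter()]
#'   (default 0.30).
#' @param refit_after_filter Refit the model on the kept samples
#'   (default TRUE).
#' @param min_identity Taxonomy assignment floor in percent (default 80).
#' @param alpha Significance level before Bonferroni division
#'   (default 0.05).
#' @param simulate_qpcr_load In simulate mode, also generate qPCR records
#'   with a per-sample true load tied to total signal (default TRUE).
#' @param seed Integer master seed for the run.
#' @param out_dir Output directory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "load"), design = NULL,
                       panel = NULL, paths = list(), K = "auto",
                       variance_threshold = 0.95, max_iter = 500L,
                       tol = 1e-8, quality_threshold = 0.30,
                       refit_after_filter = TRUE, min_identity = 80,
                       alpha = 0.05, simulate_qpcr_load = TRUE,
                       seed = 1L, out_dir = tempfile("sangermix_run_")) {
  mode <- match.arg(mode)
  if (mode == "simulate") {
    if (is.null(design)) design <- seasonal_design()
    stopifnot(inherits(design, "mixing_design"))
  } else {
    need <- c("spectra_dir", "meta_tsv", "panel_fasta")
    missing <- setdiff(need, names(paths))
    if (length(missing)) {
      stop("load mode needs paths: ", paste(missing, collapse = ", "))
    }
    for (p in unlist(paths)) {
      if (!file.exists(p)) stop("input path does not exist: ", p)
    }
  }
  structure(list(mode = mode, design = design, panel = panel, paths = paths,
                 K = K, variance_threshold = variance_threshold,
                 max_iter = as.integer(max_iter), tol = tol,
                 quality_threshold = quality_threshold,
                 refit_after_filter = refit_after_filter,
                 min_identity = min_identity, alpha = alpha,
                 simulate_qpcr_load = simulate_qpcr_load,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full mixed-sequencing analysis
#'
#' Stages, in order: simulate or load -> align -> (estimate K) -> MCR-ALS
#' fit -> residual quality filter (optional refit on kept samples) ->
#' component base-calling and taxonomy matching -> per-sample
#' alpha-diversity -> qPCR relative load -> seasonal statistics for every
#' component score, alpha and load. Every figure-equivalent table is
#' written under `config$out_dir` and a manifest records the config, the
#' per-month sample attrition and the checksums of all outputs. The run
#' is deterministic under `config$seed`.
#'
#' @param config A [run_config].
#' @return Invisibly, a list with `manifest`, `model`, `taxonomy`,
#'   `scores` (long data.frame), `alpha` table, `load` table, `stats`
#'   (per-quantity test batteries) and `kept`/`removed` ids.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message(sprintf(...))

  # --- stage: inputs ------------------------------------------------------
  if (config$mode == "simulate") {
    design <- config$design
    panel <- config$panel
    if (is.null(panel)) {
      panel <- make_reference_panel(K = ncol(design$proportions),
                                    L = 450L, min_divergence = 0.1,
                                    seed = config$seed,
                                    names = colnames(design$proportions))
    }
    design$seed <- config$seed
    sim <- simulate_dataset(panel, design)
    spectra <- sim$spectra
    meta <- sim$meta
    write_simulation(sim, config$out_dir)
    write_panel_fasta(panel, file.path(config$out_dir, "panel.fasta"))
    qpcr <- NULL
    if (config$simulate_qpcr_load) {
      # true bacterial load proportional to the bee's total mixing mass
      totals <- rowSums(sim$truth[, startsWith(names(sim$truth), "p_"),
                                  drop = FALSE]) * sim$truth$scale
      qpcr <- simulate_qpcr(pmax(totals, 1e-6), efficiencies = c(1.95, 1.9),
                            ct_noise_sd = 0.15, seed = config$seed + 1L,
                            sample_ids = sim$truth$sample_id)
      utils::write.csv(qpcr, file.path(config$out_dir, "qpcr.csv"),
                       row.names = FALSE, quote = FALSE)
    }
  } else {
    panel <- read_panel_fasta(config$paths$panel_fasta)
    files <- sort(list.files(config$paths$spectra_dir, pattern = "\\.csv$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("no spectra CSVs in ", config$paths$spectra_dir)
    spectra <- read_spectra_csv(files)
    meta <- utils::read.delim(config$paths$meta_tsv, stringsAsFactors = FALSE)
    meta$month <- factor(meta$month, levels = unique(meta$month))
    ids <- vapply(spectra, function(s) s$sample_id, character(1))
    ord <- match(ids, meta$sample_id)
    if (anyNA(ord)) stop("spectra present that are missing from the metadata")
    meta <- meta[ord, , drop = FALSE]
    qpcr <- if (!is.null(config$paths$qpcr_csv)) {
      read_qpcr_csv(config$paths$qpcr_csv)
    } else NULL
  }
  log_stage("inputs: %d spectra, %d months", length(spectra),
            length(unique(meta$month)))

  # --- stage: align -------------------------------------------------------
  aligned <- align_spectra(spectra)

  # --- stage: fit ---------------------------------------------------------
  K <- if (identical(config$K, "auto")) {
    estimate_k(aligned, config$variance_threshold)
  } else as.integer(config$K)
  if (config$refit_after_filter) {
    ff <- mcr_fit_filtered(aligned, K,
                           max_residual_fraction = config$quality_threshold,
                           max_iter = config$max_iter, tol = config$tol,
                           seed = config$seed)
    model <- ff$model
    qf <- list(kept = ff$kept, removed = ff$removed)
  } else {
    model <- mcr_als(aligned, K, max_iter = config$max_iter,
                     tol = config$tol, seed = config$seed)
    qf <- quality_filter(model, config$quality_threshold)
  }
  log_stage("fit: K=%d, %d iterations, converged=%s", K, model$iterations,
            model$converged)

  # --- stage: quality filter ---------------------------------------------
  attrition <- per_month_attrition(meta, qf$kept)
  for (m in seq_len(nrow(attrition))) {
    log_stage("quality filter %s: %d/%d kept (%.0f%%)",
              attrition$month[m], attrition$kept[m], attrition$total[m],
              100 * attrition$pass_rate[m])
  }

  # --- stage: base-call + taxonomy ---------------------------------------
  calls <- basecall_components(model)
  taxonomy <- match_taxonomy(calls, panel, config$min_identity)
  comp_names <- make.unique(taxonomy$best_match)
  write_panel_fasta(stats::setNames(calls, comp_names),
                    file.path(config$out_dir, "components.fasta"))
  write_model_json(model, file.path(config$out_dir, "model.json"))
  write_scores_tsv(model, file.path(config$out_dir, "scores.tsv"),
                   component_names = comp_names)

  # --- stage: diversity ---------------------------------------------------
  alpha_tab <- alpha_diversity_table(aligned$spectra)
  utils::write.table(alpha_tab, file.path(config$out_dir, "alpha.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # --- stage: qPCR load ---------------------------------------------------
  load_tab <- NULL
  if (!is.null(qpcr)) {
    load_tab <- relative_load_table(qpcr)
    write_load_tsv(load_tab, file.path(config$out_dir, "load.tsv"))
  }

  # --- stage: statistics --------------------------------------------------
  meta_kept <- meta[meta$sample_id %in% model$sample_ids, , drop = FALSE]
  stats_out <- list()
  scores_long <- data.frame(
    sample_id = rep(model$sample_ids, times = model$K),
    component = rep(comp_names, each = length(model$sample_ids)),
    score = as.vector(model$C))
  multi_month <- length(unique(meta_kept$month)) >= 2L
  if (multi_month) {
    for (k in seq_len(model$K)) {
      df <- data.frame(sample_id = model$sample_ids, value = model$C[, k])
      df <- merge(df, meta_kept[, c("sample_id", "month")], by = "sample_id")
      stats_out[[comp_names[k]]] <-
        seasonal_tests(group_by_month(df, "value"), comp_names[k])
    }
    adf <- merge(alpha_tab, meta_kept[, c("sample_id", "month")],
                 by = "sample_id")
    stats_out[["alpha_diversity"]] <-
      seasonal_tests(group_by_month(adf, "alpha"), "alpha_diversity")
    if (!is.null(load_tab)) {
      ldf <- merge(load_tab, meta_kept[, c("sample_id", "month")],
                   by = "sample_id")
      stats_out[["relative_load"]] <-
        seasonal_tests(group_by_month(ldf, "log_ratio"), "relative_load")
    }
  }
  jsonlite::write_json(stats_out, file.path(config$out_dir, "stats.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "rows",
                       na = "null")

  # --- manifest -----------------------------------------------------------
  outputs <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    seed = config$seed, mode = config$mode, K = K,
    n_samples = length(spectra),
    kept = length(qf$kept), removed = length(qf$removed),
    attrition = attrition,
    converged = model$converged, iterations = model$iterations,
    checksums = as.list(tools::md5sum(sort(outputs))))
  names(manifest$checksums) <- basename(sort(outputs))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "rows")

  invisible(list(manifest = manifest, model = model, taxonomy = taxonomy,
                 scores = scores_long, alpha = alpha_tab, load = load_tab,
                 stats = stats_out, kept = qf$kept, removed = qf$removed,
                 meta = meta, panel = panel))
}

per_month_attrition <- function(meta, kept_ids) {
  months <- if (is.factor(meta$month)) levels(meta$month) else unique(meta$month)
  rows <- lapply(months, function(m) {
    ids <- meta$sample_id[meta$month == m]
    data.frame(month = m, total = length(ids),
               kept = sum(ids %in% kept_ids))
  })
  out <- do.call(rbind, rows)
  out$pass_rate <- ifelse(out$total > 0, out$kept / out$total, NA_real_)
  out
}

#' Technical-replicate (plate) variation report
#'
#' Emulates running one fixed community repeatedly: a single true
#' composition is rendered twice per simulated plate under plate-specific
#' noise seeds, each render is scored against the component spectra of a
#' reference fit of the surrounding dataset, and the report gives the
#' per-component score of every replicate, the per-component maximal
#' difference between plate means, and the qPCR load mean and SD across
#' plates.
#'
#' @param config A [run_config] in simulate mode.
#' @param n_plates Number of plates (each contributing 2 replicates),
#'   at least 2.
#' @param proportions True composition of the replicated sample; default
#'   the design's first-month mean.
#' @param noise_sd Channel noise for the replicate renders; default the
#'   design's.
#' @return List with `scores` (data.frame plate, replicate, component,
#'   score), `max_mean_diff` per component, and `load` (mean, sd).
#' @export
technical_replicates <- function(config, n_plates = 3L, proportions = NULL,
                                 noise_sd = NULL) {
  stopifnot(inherits(config, "run_config"), n_plates >= 2L)
  design <- if (is.null(config$design)) seasonal_design() else config$design
  if (is.null(proportions)) proportions <- design$proportions[1L, ]
  if (is.null(noise_sd)) noise_sd <- design$noise_sd
  panel <- config$panel
  if (is.null(panel)) {
    panel <- make_reference_panel(K = ncol(design$proportions), L = 450L,
                                  min_divergence = 0.1, seed = config$seed,
                                  names = colnames(design$proportions))
  }

  # reference components: noiseless pure renders define S; replicate scores
  # are the NNLS projection of each render onto them
  S <- t(vapply(seq_along(panel$sequences), function(k) {
    p <- rep(0, length(panel$sequences)); p[k] <- 1
    as.vector(t(render_spectrum(panel, p)$intensities))
  }, numeric(4L * panel$L)))

  rows <- list()
  loads <- numeric(0)
  for (plate in seq_len(n_plates)) {
    for (rep_i in 1:2) {
      seed_i <- config$seed + 1000L * plate + rep_i
      sp <- render_spectrum(panel, proportions, scale = 1,
                            noise_sd = noise_sd, seed = seed_i,
                            sample_id = sprintf("plate%d_rep%d", plate, rep_i))
      x <- as.vector(t(sp$intensities))
      scores <- pracma::lsqnonneg(t(S), x)$x
      rows[[length(rows) + 1L]] <- data.frame(
        plate = plate, replicate = rep_i,
        component = panel$names, score = scores)
      q <- simulate_qpcr(max(sum(proportions), 1e-6),
                         efficiencies = c(1.95, 1.9),
                         ct_noise_sd = if (noise_sd > 0) 0.15 else 0,
                         seed = seed_i,
                         sample_ids = sp$sample_id)
      loads <- c(loads, relative_load_table(q)$log_ratio)
    }
  }
  scores <- do.call(rbind, rows)
  plate_means <- stats::aggregate(score ~ component + plate, scores, mean)
  max_diff <- vapply(split(plate_means$score, plate_means$component),
                     function(v) max(v) - min(v), numeric(1))
  list(scores = scores,
       max_mean_diff = max_diff[panel$names],
       load = list(mean = mean(loads),
                   sd = if (length(loads) > 1L) stats::sd(loads) else 0))
}
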