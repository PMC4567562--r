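#' Choose the number of components by explained variance
#'
#' Takes the singular value decomposition of the stacked (uncentred)
#' samples x features matrix and returns the smallest `K` whose top-K
#' singular values explain at least `variance_threshold` of the total sum
#' of squares. A rank-K noiseless mixture gives exactly `K` at any
#' threshold below 1; with noise the threshold trades parsimony against
#' fit and is deliberately exposed.
#'
#' @param aligned An [align_spectra()] result (at least 2 samples).
#' @param variance_threshold Fraction of total variance to reach
#'   (default 0.95).
#' @return Integer `K >= 1`.
#' @export
estimate_k <- function(aligned, variance_threshold = 0.95) {
  X <- stack_spectra(aligned)
  if (nrow(X) < 2L) stop("need at least 2 samples to estimate K")
  total <- sum(X^2)
  if (total == 0) stop("all-zero input: K is undefined")
  d2 <- svd(X, nu = 0, nv = 0)$d^2
  cum <- cumsum(d2) / total
  as.integer(which(cum >= variance_threshold - 1e-12)[1L])
}

#' Purest-sample initialization for the factorization
#'
#' Seeds the component spectra with actual sample rows: the first pick is
#' the largest-norm sample, each further pick the sample least similar (in
#' maximal cosine similarity) to all picks so far. On data containing
#' near-pure samples this starts the alternating fit close to the true
#' components; it is deterministic given the input order.
#'
#' @param aligned An [align_spectra()] result.
#' @param K Number of components (`1 <= K <=` sample count).
#' @param seed Unused by the deterministic rule; reserved for random
#'   restarts.
#' @return List with `S` (`K x 4L` initial spectra) and `picked`
#'   (indices of the selected samples).
#' @export
initialize_components <- function(aligned, K, seed = NULL) {
  X <- stack_spectra(aligned)
  N <- nrow(X)
  if (K < 1L || K > N) stop("'K' must be between 1 and the sample count")
  norms <- sqrt(rowSums(X^2))
  if (all(norms == 0)) stop("all-zero input")
  unit <- X / pmax(norms, .Machine$double.eps)
  picked <- as.integer(which.max(norms))
  while (length(picked) < K) {
    cossim <- unit %*% t(unit[picked, , drop = FALSE])
    maxsim <- apply(cossim, 1L, max)
    maxsim[picked] <- Inf
    picked <- c(picked, as.integer(which.min(maxsim)))
  }
  list(S = X[picked, , drop = FALSE], picked = picked)
}

# Exact non-negative least squares solve of min ||A %*% B - Y||_F over
# B >= 0, columnwise.
#
# For small K (the factorization never uses more than a handful of
# components) the exact solution is found by support enumeration: for
# each candidate support F the equality-constrained solution is computed
# for all columns of Y at once, and a column accepts F when it satisfies
# the NNLS KKT conditions (feasible on F, non-negative gradient off F).
# Larger supports are tried first because on real data most columns are
# interior. Columns no enumerated support accepts (singular subsystems,
# razor-edge ties) fall back to the Lawson-Hanson active-set solver
# (pracma::lsqnonneg), which is also the solver used outright when K is
# too large to enumerate.
nnls_columns <- function(A, Y, enum_max_k = 8L) {
  K <- ncol(A)
  m <- ncol(Y)
  AtA <- crossprod(A)
  AtY <- crossprod(A, Y)
  B <- matrix(0, K, m)
  tol <- 1e-10 * (1 + max(abs(AtY)))

  if (K <= enum_max_k) {
    # zero solution is optimal where the gradient at 0 is already >= 0
    solved <- .colSums(AtY > tol, K, m) == 0L
    supports <- lapply(seq_len(2^K - 1L), function(code) {
      which(bitwAnd(code, bitwShiftL(1L, seq_len(K) - 1L)) > 0L)
    })
    supports <- supports[order(-lengths(supports))]
    for (F in supports) {
      idx <- which(!solved)
      if (length(idx) == 0L) break
      sol <- tryCatch(solve(AtA[F, F, drop = FALSE],
                            AtY[F, idx, drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(sol)) next
      ok <- .colSums(sol < -tol, length(F), length(idx)) == 0L
      comp <- setdiff(seq_len(K), F)
      if (length(comp) > 0L && any(ok)) {
        grad <- AtA[comp, F, drop = FALSE] %*% sol -
          AtY[comp, idx, drop = FALSE]
        ok <- ok & .colSums(grad < -tol, length(comp), length(idx)) == 0L
      }
      cols <- idx[ok]
      if (length(cols) > 0L) {
        B[F, cols] <- pmax(sol[, ok, drop = FALSE], 0)
        solved[cols] <- TRUE
      }
    }
    leftover <- which(!solved)
  } else {
    # unconstrained shortcut, exact where already feasible
    Bu <- tryCatch(solve(AtA, AtY), error = function(e) NULL)
    if (!is.null(Bu)) {
      okcols <- .colSums(Bu < 0, K, m) == 0L
      B[, okcols] <- Bu[, okcols]
      leftover <- which(!okcols)
    } else {
      leftover <- seq_len(m)
    }
  }
  for (j in leftover) {
    B[, j] <- pracma::lsqnonneg(A, Y[, j])$x
  }
  B
}

#' Fit the MCR-ALS factor model
#'
#' Factors the stacked spectra `X` (`N` samples x `4 L` channel features)
#' as `X ~ C S` with `C >= 0` (`N x K` scores) and `S >= 0` (`K x 4L`
#' component spectra) by alternating exact non-negative least squares:
#' scores given spectra, then spectra given scores. There is no closure
#' constraint — rows of `C` are free to sum to anything, so residual noise
#' lowers a sample's scores rather than being redistributed across
#' components.
#'
#' Scale conventions: the stacked data are divided by one global factor
#' (the grand mean per-position total intensity over all samples) before
#' fitting, and after convergence each component spectrum is rescaled to
#' unit mean per-position total intensity with the inverse factor absorbed
#' into its score column. Scores are therefore dimensionless and
#' comparable across samples and runs; a sample consisting purely of
#' component `k` at the dataset's typical signal level gets `C[n, k]`
#' close to 1.
#'
#' @param aligned An [align_spectra()] result.
#' @param K Number of components.
#' @param max_iter Maximum alternating iterations (default 500).
#' @param tol Relative decrease of the squared residual at which to stop
#'   (default 1e-8).
#' @param seed Passed to [initialize_components()].
#' @param init Optional `K x 4L` non-negative matrix overriding the
#'   purest-sample initialization.
#' @return Object of class `mcr_model`: list with `C`, `S`, `K`,
#'   `residual_fraction` (per sample, `||x_n - c_n S||^2 / ||x_n||^2`),
#'   `objective` (squared-residual trace over iterations), `iterations`,
#'   `converged`, `L`, `sample_ids`.
#' @export
mcr_als <- function(aligned, K, max_iter = 500L, tol = 1e-8, seed = NULL,
                    init = NULL) {
  X <- stack_spectra(aligned)
  N <- nrow(X)
  if (K < 1L || K > N) stop("'K' must be between 1 and the sample count")
  if (!all(is.finite(X))) stop("non-finite intensities in input")
  L <- aligned$L

  # global pre-scaling: grand mean per-position total intensity
  g <- mean(rowSums(X)) / L
  if (g <= 0) stop("all-zero input")
  Xs <- X / g

  S <- if (is.null(init)) {
    initialize_components(aligned, K, seed)$S / g
  } else {
    stopifnot(nrow(init) == K, ncol(init) == ncol(X), all(init >= 0))
    init / g
  }

  total <- sum(Xs^2)
  objective <- numeric(0)
  prev <- Inf
  converged <- FALSE
  C <- NULL
  C_acc <- NULL
  S_acc <- NULL
  beta <- 1
  for (it in seq_len(max_iter)) {
    # C-step: rows of C solve min ||x_n - c_n S||, c_n >= 0
    C <- t(nnls_columns(t(S), t(Xs)))
    # S-step: columns of S solve min ||X_j - C s_j||, s_j >= 0
    S <- nnls_columns(C, Xs)
    obj <- sum((Xs - C %*% S)^2)
    # monotone extrapolation: plain ALS converges linearly and can crawl
    # once the support pattern is settled; an extrapolated candidate along
    # the last accepted step is taken only when it strictly lowers the
    # objective, so the descent guarantee of the exact NNLS sweeps is kept
    if (!is.null(C_acc)) {
      Ce <- pmax(C + beta * (C - C_acc), 0)
      Se <- pmax(S + beta * (S - S_acc), 0)
      obje <- sum((Xs - Ce %*% Se)^2)
      if (obje < obj) {
        C <- Ce
        S <- Se
        obj <- obje
        beta <- min(beta * 2, 32)
      } else {
        beta <- max(beta / 2, 1)
      }
    }
    C_acc <- C
    S_acc <- S
    objective <- c(objective, obj)
    if (obj <= 1e-24 * total ||
        (is.finite(prev) &&
         (prev - obj) <= tol * max(prev, .Machine$double.eps))) {
      converged <- TRUE
      break
    }
    prev <- obj
  }

  # resolve the scale indeterminacy of C S: unit mean per-position total
  # intensity per component
  f <- rowSums(S) / L
  f[f <= 0] <- 1  # dead component: leave as is
  S <- S / f
  C <- C * rep(f, each = N)

  resid <- rowSums((Xs - C %*% S)^2)
  denom <- rowSums(Xs^2)
  residual_fraction <- ifelse(denom > 0, pmin(resid / denom, 1), 0)

  structure(list(C = structure(C, dimnames = list(rownames(X), NULL)),
                 S = S, K = as.integer(K), L = L,
                 residual_fraction = stats::setNames(residual_fraction,
                                                     rownames(X)),
                 objective = objective,
                 iterations = length(objective),
                 converged = converged,
                 total_ss = total,
                 sample_ids = rownames(X)),
            class = "mcr_model")
}

#' @export
print.mcr_model <- function(x, ...) {
  cat(sprintf(paste0("<mcr_model> K=%d components, %d samples, %d positions; ",
                     "%d iterations (%sconverged)\n"),
              x$K, nrow(x$C), x$L, x$iterations,
              if (x$converged) "" else "not "))
  cat(sprintf("  median residual fraction: %.4g\n",
              stats::median(x$residual_fraction)))
  invisible(x)
}

#' Component spectrum as an L x 4 matrix
#' @param model An [mcr_als()] fit.
#' @param k Component index.
#' @export
component_spectrum <- function(model, k) {
  stopifnot(inherits(model, "mcr_model"), k >= 1, k <= model$K)
  unstack_row(model$S[k, ])
}

#' Score arbitrary samples against fixed component spectra
#'
#' Non-negative least-squares projection of each sample onto the fitted
#' component spectra `S`, without touching `S`: per sample the score
#' vector minimizing the residual, plus the resulting residual fraction.
#' Used to score samples that were excluded from (or arrived after) the
#' fit, and to re-assess quality against a refit model.
#'
#' @param model An [mcr_als()] fit.
#' @param aligned An [align_spectra()] result on the same position frame
#'   (same `L`).
#' @return List with `C` (`N x K` scores) and `residual_fraction`
#'   (named per sample).
#' @export
project_scores <- function(model, aligned) {
  stopifnot(inherits(model, "mcr_model"), inherits(aligned, "aligned_set"))
  X <- stack_spectra(aligned)
  if (ncol(X) != ncol(model$S)) {
    stop("aligned frame length does not match the fitted model")
  }
  g <- mean(rowSums(X)) / aligned$L
  if (g <= 0) stop("all-zero input")
  Xs <- X / g
  C <- t(nnls_columns(t(model$S), t(Xs)))
  resid <- rowSums((Xs - C %*% model$S)^2)
  denom <- rowSums(Xs^2)
  rf <- ifelse(denom > 0, pmin(resid / denom, 1), 0)
  list(C = structure(C, dimnames = list(rownames(X), NULL)),
       residual_fraction = stats::setNames(rf, rownames(X)))
}

#' Fit with iterative residual filtering
#'
#' The robust workflow for mixed-chromatogram data: fit all samples, drop
#' the ones the model cannot explain (residual fraction above the
#' threshold), refit on the kept samples, re-score every sample against
#' the refit spectra and re-partition; repeat until the kept set is
#' stable. Low-quality chromatograms distort a joint fit in two ways, and
#' both are handled: their unstructured signal inflates their own
#' residual (caught by the threshold), and a single high-energy noise
#' sample can capture a whole component for itself, which makes its
#' residual deceptively small. The second failure mode is detected as a
#' *private component*: when one sample carries more than
#' `private_fraction` of a component's total score mass, that sample is
#' marked low quality outright, since a real community component is
#' expressed across many samples.
#'
#' @param aligned An [align_spectra()] result.
#' @param K Number of components.
#' @param max_residual_fraction Quality threshold (default 0.30).
#' @param private_fraction Score-mass share above which a component
#'   counts as private to its top sample (default 0.5).
#' @param max_rounds Maximum filter/refit rounds (default 6).
#' @param svd_triage Pre-screen samples by their residual from the
#'   rank-K truncated-SVD subspace before the first ALS fit
#'   (default TRUE). Shared community structure concentrates in the top
#'   singular directions while each bad chromatogram's noise is its own
#'   direction, so the subspace residual flags bad samples without
#'   letting them distort the factorization first.
#' @param ... Passed to [mcr_als()].
#' @return List with `model` (fit on the final kept set), `kept`,
#'   `removed`, `residual_fraction` (all samples, scored against the
#'   final model) and `rounds`.
#' @export
mcr_fit_filtered <- function(aligned, K, max_residual_fraction = 0.30,
                             private_fraction = 0.5, max_rounds = 6L,
                             svd_triage = TRUE, ...) {
  ids <- vapply(aligned$spectra, function(s) s$sample_id, character(1))
  blacklist <- character(0)
  kept <- ids
  if (svd_triage && length(ids) > K) {
    X <- stack_spectra(aligned)
    sv <- svd(X, nu = K, nv = 0)
    rf0 <- rowSums((X - sv$u %*% (t(sv$u) %*% X))^2) / rowSums(X^2)
    if (sum(rf0 <= max_residual_fraction) > K) {
      kept <- ids[rf0 <= max_residual_fraction]
    }
  }
  rounds <- 0L
  model <- NULL
  repeat {
    rounds <- rounds + 1L
    sub <- if (length(kept) == length(ids)) aligned else {
      subset_aligned(aligned, match(kept, ids))
    }
    model <- mcr_als(sub, K, ...)
    mass <- colSums(model$C)
    frac <- ifelse(mass > 0, apply(model$C, 2L, max) / mass, 0)
    owners <- model$sample_ids[apply(model$C, 2L, which.max)]
    blacklist <- union(blacklist, owners[frac > private_fraction])
    rf <- if (length(kept) == length(ids)) model$residual_fraction else {
      project_scores(model, aligned)$residual_fraction
    }
    new_kept <- setdiff(ids[rf <= max_residual_fraction], blacklist)
    if (length(new_kept) <= K) break
    if (setequal(new_kept, kept) || rounds >= max_rounds) {
      kept <- new_kept
      break
    }
    kept <- new_kept
  }
  if (!setequal(model$sample_ids, kept) && length(kept) > K) {
    model <- mcr_als(subset_aligned(aligned, match(kept, ids)), K, ...)
    rf <- project_scores(model, aligned)$residual_fraction
    kept <- setdiff(ids[rf <= max_residual_fraction], blacklist)
  }
  list(model = model, kept = kept, removed = setdiff(ids, kept),
       residual_fraction = rf, rounds = rounds)
}

#' Residual-based quality filter
#'
#' Low-quality chromatograms are those the factor model cannot explain:
#' their residual fraction (share of the sample's signal energy left in
#' the residual) exceeds the threshold. Returns both partitions; whether
#' to refit on the kept samples is the caller's choice.
#'
#' @param model An [mcr_als()] fit.
#' @param max_residual_fraction Threshold (default 0.30).
#' @return List with `kept` and `removed` character vectors of sample ids.
#' @export
quality_filter <- function(model, max_residual_fraction = 0.30) {
  stopifnot(inherits(model, "mcr_model"))
  bad <- model$residual_fraction > max_residual_fraction
  list(kept = model$sample_ids[!bad], removed = model$sample_ids[bad])
}

#' Base-call the fitted component spectra
#'
#' Applies the dominant-base rule of [dominant_basecall()] to each
#' component's `L x 4` spectrum: the co-occurring nucleotides that load on
#' one component form that component's sequence.
#'
#' @param model An [mcr_als()] fit.
#' @param tie_tol Tie tolerance passed through.
#' @return Character vector of `K` sequences over `{A,C,G,T,N}`.
#' @export
basecall_components <- function(model, tie_tol = 1e-9) {
  stopifnot(inherits(model, "mcr_model"))
  vapply(seq_len(model$K),
         function(k) dominant_basecall(component_spectrum(model, k), tie_tol),
         character(1))
}

#' Match base-called components to a reference panel
#'
#' Nearest-reference taxonomy: percent identity of each call against every
#' panel sequence over the positions where the call is informative
#' (`N` positions are excluded from the denominator). Calls whose best hit
#' falls below `min_identity` are labelled `"unassigned"`.
#'
#' @param calls Character vector of component sequences (from
#'   [basecall_components()]).
#' @param panel A [reference_panel] on the same position frame as the
#'   calls.
#' @param min_identity Assignment floor in percent (default 80).
#' @return data.frame `component, sequence, best_match, identity` with
#'   identity in percent.
#' @export
match_taxonomy <- function(calls, panel, min_identity = 80) {
  stopifnot(inherits(panel, "reference_panel"))
  if (length(panel$sequences) == 0L) stop("empty reference panel")
  res <- lapply(seq_along(calls), function(i) {
    call_chars <- strsplit(calls[i], "")[[1]]
    usable <- call_chars != "N"
    ident <- vapply(panel$sequences, function(ref) {
      ref_chars <- strsplit(ref, "")[[1]]
      n <- min(length(call_chars), length(ref_chars))
      ok <- usable[seq_len(n)]
      if (!any(ok)) return(NA_real_)
      100 * mean(call_chars[seq_len(n)][ok] == ref_chars[seq_len(n)][ok])
    }, numeric(1))
    if (all(is.na(ident))) {
      return(data.frame(component = i, sequence = calls[i],
                        best_match = "unassigned", identity = NA_real_))
    }
    best <- which.max(ident)
    data.frame(component = i, sequence = calls[i],
               best_match = if (ident[best] >= min_identity)
                 panel$names[best] else "unassigned",
               identity = ident[best])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Serialize / restore a fitted model
#'
#' JSON round trip of the score matrix, component spectra, residuals and
#' fit diagnostics; companion TSV writer for the long score table
#' (`sample_id, component, score`).
#'
#' @param model An [mcr_als()] fit.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  payload <- list(K = model$K, L = model$L,
                  sample_ids = model$sample_ids,
                  C = model$C, S = model$S,
                  residual_fraction = unname(model$residual_fraction),
                  objective = model$objective,
                  iterations = model$iterations,
                  converged = model$converged)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(C = structure(p$C, dimnames = list(p$sample_ids, NULL)),
                 S = p$S, K = as.integer(p$K), L = as.integer(p$L),
                 residual_fraction = stats::setNames(p$residual_fraction,
                                                     p$sample_ids),
                 objective = p$objective,
                 iterations = as.integer(p$iterations),
                 converged = isTRUE(p$converged),
                 sample_ids = p$sample_ids),
            class = "mcr_model")
}

#' @rdname write_model_json
#' @param component_names Optional labels for the score table columns.
#' @export
write_scores_tsv <- function(model, path, component_names = NULL) {
  if (is.null(component_names)) {
    component_names <- sprintf("component_%d", seq_len(model$K))
  }
  df <- data.frame(
    sample_id = rep(model$sample_ids, times = model$K),
    component = rep(component_names, each = length(model$sample_ids)),
    score = as.vector(model$C))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
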