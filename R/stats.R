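#' Grouped series of per-bee measurements
#'
#' The unit of all seasonal tests: an ordered set of groups (months, time
#' points, colonies) with a numeric vector of per-bee values each —
#' MCR-ALS scores of one component, alpha-diversities, or log load
#' ratios.
#'
#' @param values Named list of numeric vectors; names are the ordered
#'   group labels.
#' @return Object of class `grouped_series`.
#' @export
grouped_series <- function(values) {
  if (is.null(names(values)) || any(names(values) == "")) {
    stop("groups must be named")
  }
  values <- lapply(values, as.numeric)
  if (any(vapply(values, length, integer(1)) < 1L)) {
    stop("every group needs at least one value")
  }
  structure(list(values = values, groups = names(values)),
            class = "grouped_series")
}

#' Split a value column by month into a grouped series
#'
#' @param df data.frame with the value column and a `month` column
#'   (factor order respected).
#' @param value Name of the value column.
#' @export
group_by_month <- function(df, value) {
  lev <- if (is.factor(df$month)) levels(df$month) else unique(df$month)
  lev <- lev[lev %in% df$month]
  grouped_series(split(df[[value]], factor(df$month, levels = lev)))
}

#' Per-group mean, SD and SEM
#'
#' Sample SD (`n - 1` denominator) and SEM = SD / sqrt(n). Singleton
#' groups report 0 for both and are flagged in the `singleton` column.
#'
#' @param g A [grouped_series].
#' @return data.frame `group, n, mean, sd, sem, singleton`.
#' @export
summarize_groups <- function(g) {
  stopifnot(inherits(g, "grouped_series"))
  rows <- lapply(g$groups, function(grp) {
    v <- g$values[[grp]]
    n <- length(v)
    s <- if (n > 1L) stats::sd(v) else 0
    data.frame(group = grp, n = n, mean = mean(v), sd = s,
               sem = if (n > 1L) s / sqrt(n) else 0, singleton = n == 1L)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA across groups
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test) of the
#' complete trend across time points, via `stats::oneway.test` with
#' `var.equal = TRUE`. The degenerate case of zero within-group variance
#' is reported explicitly rather than as a spurious infinite F: with equal
#' means the F statistic is undefined, with unequal means it is infinite
#' and p is 0.
#'
#' @param g A [grouped_series] with at least 2 groups and more values
#'   than groups.
#' @return List with `F`, `df_between`, `df_within`, `p`, `degenerate`.
#' @export
one_way_anova <- function(g) {
  stopifnot(inherits(g, "grouped_series"))
  k <- length(g$groups)
  if (k < 2L) stop("ANOVA needs at least 2 groups")
  values <- unlist(g$values, use.names = FALSE)
  n <- length(values)
  if (n <= k) stop("ANOVA needs more observations than groups")
  group <- factor(rep(g$groups, vapply(g$values, length, integer(1))),
                  levels = g$groups)
  within_ss <- sum(vapply(g$values, function(v) sum((v - mean(v))^2),
                          numeric(1)))
  if (within_ss == 0) {
    means <- vapply(g$values, mean, numeric(1))
    if (max(means) - min(means) == 0) {
      return(list(F = NA_real_, df_between = k - 1L, df_within = n - k,
                  p = NA_real_, degenerate = TRUE))
    }
    return(list(F = Inf, df_between = k - 1L, df_within = n - k,
                p = 0, degenerate = TRUE))
  }
  ow <- stats::oneway.test(values ~ group, var.equal = TRUE)
  list(F = unname(ow$statistic),
       df_between = unname(ow$parameter[1L]),
       df_within = unname(ow$parameter[2L]),
       p = ow$p.value, degenerate = FALSE)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range test on group means using the pooled within-group
#' mean square from the one-way ANOVA. Unequal group sizes use the
#' Tukey-Kramer standard error. With `adjacent_only`, only consecutive
#' time-point pairs are reported — the comparison set used for seasonal
#' month-to-month trajectories. Significance is flagged at the 0.05 and
#' 0.01 family-wise levels.
#'
#' @param g A [grouped_series].
#' @param adjacent_only Report only consecutive group pairs
#'   (default `FALSE`: all pairs).
#' @return data.frame `group1, group2, diff, se, q, p, sig05, sig01`.
#' @export
tukey_hsd <- function(g, adjacent_only = FALSE) {
  stopifnot(inherits(g, "grouped_series"))
  k <- length(g$groups)
  if (k < 2L) stop("need at least 2 groups")
  ns <- vapply(g$values, length, integer(1))
  means <- vapply(g$values, mean, numeric(1))
  n <- sum(ns)
  if (n <= k) stop("need more observations than groups")
  df_within <- n - k
  ms_within <- sum(vapply(g$values, function(v) sum((v - mean(v))^2),
                          numeric(1))) / df_within
  pairs <- if (adjacent_only) {
    cbind(seq_len(k - 1L), seq_len(k - 1L) + 1L)
  } else {
    t(utils::combn(k, 2L))
  }
  rows <- apply(pairs, 1L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    se <- sqrt(ms_within / 2 * (1 / ns[i] + 1 / ns[j]))
    diff <- means[j] - means[i]
    if (ms_within == 0) {
      q <- if (diff == 0) 0 else Inf
      p <- if (diff == 0) 1 else 0
    } else {
      q <- abs(diff) / se
      p <- stats::ptukey(q, nmeans = k, df = df_within, lower.tail = FALSE)
    }
    data.frame(group1 = g$groups[i], group2 = g$groups[j],
               diff = unname(diff), se = unname(se), q = unname(q),
               p = p, sig05 = p < 0.05, sig01 = p < 0.01)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sided t-tests with Bonferroni threshold division
#'
#' Pooled-variance Student's t-tests for a family of two-sample
#' comparisons, declared significant when the raw p-value falls below
#' `alpha` divided by the number of tests in the family — threshold
#' division, not p-value multiplication, so the reported p-values stay
#' raw. Zero-variance pairs are flagged as degenerate (t undefined when
#' the means also coincide).
#'
#' @param pairs Named list; each element a list/pair of two numeric
#'   vectors (each of length at least 2).
#' @param alpha Family-wise level before division (default 0.05).
#' @param welch Use the Welch (unequal-variance) t instead of the pooled
#'   Student's t.
#' @return data.frame `comparison, t, df, p, threshold, significant,
#'   degenerate`, one row per pair; `threshold = alpha / length(pairs)`.
#' @export
ttests_bonferroni <- function(pairs, alpha = 0.05, welch = FALSE) {
  m <- length(pairs)
  if (m < 1L) stop("no comparisons supplied")
  if (is.null(names(pairs))) names(pairs) <- sprintf("pair_%d", seq_len(m))
  threshold <- alpha / m
  rows <- lapply(names(pairs), function(nm) {
    x <- as.numeric(pairs[[nm]][[1L]])
    y <- as.numeric(pairs[[nm]][[2L]])
    if (length(x) < 2L || length(y) < 2L) {
      stop("each sample needs at least 2 values: ", nm)
    }
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      same <- mean(x) == mean(y)
      return(data.frame(comparison = nm,
                        t = if (same) 0 else Inf,
                        df = length(x) + length(y) - 2L,
                        p = if (same) 1 else 0,
                        threshold = threshold,
                        significant = !same, degenerate = TRUE))
    }
    tt <- stats::t.test(x, y, var.equal = !welch)
    data.frame(comparison = nm, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               threshold = threshold,
               significant = tt$p.value < threshold, degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Machine-readable report of a seasonal test battery
#'
#' Runs [summarize_groups()], [one_way_anova()] and adjacent-pair
#' [tukey_hsd()] on one grouped series and returns (optionally writes) a
#' JSON-ready list — the per-analysis statistics block emitted by the
#' pipeline for every measured quantity.
#'
#' @param g A [grouped_series].
#' @param label Name of the analysed quantity.
#' @param path Optional JSON output path.
#' @export
seasonal_tests <- function(g, label = "value", path = NULL) {
  res <- list(label = label,
              summary = summarize_groups(g),
              anova = one_way_anova(g),
              tukey_adjacent = tukey_hsd(g, adjacent_only = TRUE))
  if (!is.null(path)) {
    jsonlite::write_json(res, path, digits = NA, auto_unbox = TRUE,
                         dataframe = "rows", na = "null")
  }
  res
}
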