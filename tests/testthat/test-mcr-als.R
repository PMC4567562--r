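test_that("estimate_k finds the rank of noiseless mixtures", {
  pan <- small_panel(2, L = 80)
  props <- withr::with_seed(2, matrix(runif(20, 0.1, 0.8), 10, 2))
  al <- align_spectra(render_set(pan, props))
  expect_equal(estimate_k(al, 0.99), 2L)

  # all samples identical: rank one
  al1 <- align_spectra(render_set(pan, rbind(c(0.5, 0.4), c(0.5, 0.4),
                                             c(0.5, 0.4))))
  expect_equal(estimate_k(al1, 0.99), 1L)

  # pure noise at a permissive threshold: bounded by 1 and N
  noise <- withr::with_seed(3, lapply(1:5, function(i) {
    spectrum_matrix(matrix(abs(rnorm(80 * 4)), 80, 4), paste0("n", i))
  }))
  k <- estimate_k(align_spectra(noise), 0.5)
  expect_gte(k, 1L)
  expect_lte(k, 5L)
})

test_that("purest-sample initialization picks pure and extreme samples", {
  # two orthogonal pure samples are both chosen at K=2
  pan <- homopoly_panel(c("A", "C"))
  sp <- render_set(pan, rbind(c(1, 0), c(0, 1), c(0.5, 0.5)))
  al <- align_spectra(sp)
  init <- initialize_components(al, 2)
  expect_setequal(init$picked, c(1L, 2L))

  # K=1: the largest-norm sample
  sp2 <- render_set(pan, rbind(c(0.3, 0), c(0.9, 0), c(0.5, 0)))
  expect_equal(initialize_components(align_spectra(sp2), 1)$picked, 2L)

  expect_error(initialize_components(al, 4), "between 1 and the sample")
})

test_that("greedy max-min selection matches exhaustive search on separated clusters", {
  # three well-separated clusters; the greedy rule must cover all three,
  # as the exhaustive minimizer of within-subset maximal cosine does
  pan <- homopoly_panel(c("A", "C", "G"))
  props <- rbind(c(1.00, 0.05, 0.00), c(0.95, 0.00, 0.05),
                 c(0.05, 1.00, 0.00), c(0.00, 0.90, 0.05),
                 c(0.00, 0.05, 1.05), c(0.05, 0.00, 0.98))
  al <- align_spectra(render_set(pan, props))
  picked <- initialize_components(al, 3)$picked
  cluster <- c(1, 1, 2, 2, 3, 3)
  expect_setequal(cluster[picked], 1:3)

  # exhaustive oracle over all 3-subsets containing the largest-norm sample
  X <- stack_spectra(al)
  unit <- X / sqrt(rowSums(X^2))
  cos_all <- tcrossprod(unit)
  first <- which.max(sqrt(rowSums(X^2)))
  subsets <- utils::combn(setdiff(1:6, first), 2)
  worst <- apply(subsets, 2, function(rest) {
    s <- c(first, rest)
    max(cos_all[s, s][upper.tri(diag(3))])
  })
  best_subset <- sort(c(first, subsets[, which.min(worst)]))
  expect_setequal(cluster[best_subset], cluster[picked])
})

test_that("noiseless rank-K data is reconstructed exactly with true sequences", {
  pan <- small_panel(3, L = 70, seed = 19)
  props <- withr::with_seed(4, matrix(runif(60, 0, 0.6), 20, 3))
  props[1:3, ] <- diag(0.8, 3)  # include near-pure samples
  al <- align_spectra(render_set(pan, props))
  m <- mcr_als(al, 3)
  expect_true(all(m$residual_fraction < 1e-10))
  expect_true(all(m$C >= 0))
  expect_true(all(m$S >= 0))
  calls <- basecall_components(m)
  tx <- match_taxonomy(calls, pan)
  expect_setequal(tx$best_match, pan$names)
  expect_equal(tx$identity, rep(100, 3))
  # oracle equivalence: reconstruction matches the data
  X <- stack_spectra(al)
  g <- mean(rowSums(X)) / al$L
  expect_lt(max(abs(m$C %*% m$S - X / g)) / max(X / g), 1e-8)
})

test_that("rank-one data recovers per-sample scale ratios in C", {
  pan <- small_panel(1, L = 60)
  scales <- c(0.5, 1, 2, 3.5)
  al <- align_spectra(render_set(pan, matrix(1, 4, 1), scales = scales))
  m <- mcr_als(al, 1)
  expect_equal(m$C[, 1] / m$C[1, 1], scales / scales[1],
               tolerance = 1e-10, ignore_attr = TRUE)
  # S base-calls back to the panel sequence
  expect_equal(basecall_components(m), pan$sequences)
})

test_that("the ALS objective is non-increasing within a fit", {
  pan <- small_panel(3, L = 60, seed = 23)
  props <- withr::with_seed(6, matrix(runif(45, 0, 0.7), 15, 3))
  al <- align_spectra(render_set(pan, props, noise_sd = 0.15, seed = 6))
  m <- mcr_als(al, 3)
  expect_true(all(diff(m$objective) <= 1e-9 * max(1, m$objective[1])))
})

test_that("quality_filter partitions by residual fraction", {
  fake <- structure(list(
    residual_fraction = c(a = 0, b = 0.1, c = 0.31, d = 0.9),
    sample_ids = c("a", "b", "c", "d")), class = "mcr_model")
  qf <- quality_filter(fake)
  expect_equal(qf$kept, c("a", "b"))
  expect_equal(qf$removed, c("c", "d"))
  # all-zero residuals: nothing removed
  fake$residual_fraction[] <- 0
  expect_length(quality_filter(fake)$removed, 0)
  # threshold 0 removes every sample with any residual
  fake$residual_fraction <- c(a = 0, b = 1e-6, c = 0.2, d = 0.5)
  expect_equal(quality_filter(fake, 0)$kept, "a")
})

test_that("iterative filtered fit isolates noise-inflated samples", {
  # a design inside the separable regime: enough bees and positions that
  # good and noise-inflated chromatograms occupy distinct residual bands
  d <- seasonal_design(bees_per_month = 20L, lowquality_fraction = 0.15,
                       seed = 31)
  pan <- make_reference_panel(4, L = 150, min_divergence = 0.15, seed = 5,
                              names = colnames(d$proportions))
  sim <- simulate_dataset(pan, d)
  al <- align_spectra(sim$spectra)
  ff <- mcr_fit_filtered(al, 4)
  flagged <- sim$truth$sample_id[sim$truth$low_quality]
  expect_setequal(ff$removed, flagged)
  expect_true(all(ff$residual_fraction[flagged] > 0.30))
  expect_true(all(ff$residual_fraction[setdiff(sim$truth$sample_id,
                                               flagged)] <= 0.30))
})

test_that("component base-calling follows the argmax/N rule on S", {
  S <- rbind(as.vector(t(rbind(c(0.9, 0.05, 0.05, 0),
                               c(0, 0, 1, 0),
                               c(0.5, 0.5, 0, 0)))),
             rep(0, 12))
  fake <- structure(list(S = S, K = 2L, L = 3L), class = "mcr_model")
  calls <- basecall_components(fake)
  expect_equal(calls, c("AGN", "NNN"))
})

test_that("taxonomy matching is an exhaustive nearest-reference search", {
  pan <- make_reference_panel(4, L = 100, min_divergence = 0.2, seed = 13)
  # identical call
  tx <- match_taxonomy(pan$sequences[2], pan)
  expect_equal(tx$best_match, pan$names[2])
  expect_equal(tx$identity, 100)

  # 5 mismatches in 100 compared positions
  chars <- strsplit(pan$sequences[1], "")[[1]]
  flip <- c("A" = "C", "C" = "G", "G" = "T", "T" = "A")
  chars[1:5] <- flip[chars[1:5]]
  tx2 <- match_taxonomy(paste(chars, collapse = ""), pan)
  expect_equal(tx2$identity, 95)
  expect_equal(tx2$best_match, pan$names[1])

  # random call: best hit equals brute-force max over entries
  rand <- fixed_seq(100, seed = 77)
  tx3 <- match_taxonomy(rand, pan, min_identity = 0)
  oracle <- vapply(pan$sequences, hamming_identity, numeric(1), a = rand)
  expect_equal(tx3$identity, 100 * max(oracle))
  expect_equal(tx3$best_match, pan$names[which.max(oracle)])

  # N positions drop out of the denominator; floor yields 'unassigned'
  call_n <- paste0("NNNNN", substr(pan$sequences[3], 6, 100))
  tx4 <- match_taxonomy(call_n, pan)
  expect_equal(tx4$identity, 100)
  tx5 <- match_taxonomy(rand, pan, min_identity = 80)
  expect_equal(tx5$best_match, "unassigned")
})

test_that("model JSON and score TSV round-trip", {
  pan <- small_panel(2, L = 60)
  props <- rbind(c(0.8, 0.1), c(0.2, 0.7), c(0.5, 0.5), c(0.9, 0.05))
  al <- align_spectra(render_set(pan, props))
  m <- mcr_als(al, 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(m2$C, m$C, tolerance = 1e-12)
  expect_equal(m2$S, m$S, tolerance = 1e-12)
  expect_equal(m2$residual_fraction, m$residual_fraction, tolerance = 1e-12)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_scores_tsv(m, tsv)
  tab <- utils::read.delim(tsv)
  expect_equal(nrow(tab), 8)
  expect_equal(tab$score, as.vector(m$C), tolerance = 1e-12)
})

test_that("project_scores reproduces the fit scores for fitted samples", {
  pan <- small_panel(2, L = 60)
  props <- rbind(c(0.8, 0.1), c(0.2, 0.7), c(0.5, 0.5), c(0.1, 0.2))
  al <- align_spectra(render_set(pan, props, noise_sd = 0.05, seed = 12))
  m <- mcr_als(al, 2)
  pr <- project_scores(m, al)
  expect_equal(pr$C, m$C, tolerance = 1e-4)
  expect_equal(unname(pr$residual_fraction),
               unname(m$residual_fraction), tolerance = 1e-4)
})
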