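test_that("random panels respect the pairwise divergence constraint", {
  # brute-force Hamming identity as the oracle
  p <- make_reference_panel(4, L = 450, min_divergence = 0.1, seed = 7)
  combs <- utils::combn(4, 2)
  ids <- apply(combs, 2, function(ij) {
    hamming_identity(p$sequences[ij[1]], p$sequences[ij[2]])
  })
  expect_length(ids, 6)
  expect_true(all(ids <= 0.9))

  p2 <- make_reference_panel(2, L = 100, min_divergence = 0.3, seed = 1)
  expect_lte(hamming_identity(p2$sequences[1], p2$sequences[2]), 0.7)

  # degenerate single-sequence panel: no pairwise constraint applies
  expect_s3_class(make_reference_panel(1, L = 80, min_divergence = 0.3,
                                       seed = 2), "reference_panel")
})

test_that("panel generation is deterministic and validates inputs", {
  a <- make_reference_panel(3, L = 60, min_divergence = 0.2, seed = 5)
  b <- make_reference_panel(3, L = 60, min_divergence = 0.2, seed = 5)
  expect_identical(a, b)
  expect_error(make_reference_panel(2, L = 60, min_divergence = 0),
               "min_divergence")
  # unreachable divergence on a bounded number of attempts
  expect_error(make_reference_panel(2, L = 60, min_divergence = 0.99,
                                    seed = 1, max_tries = 3),
               "could not draw")
  expect_error(reference_panel(c("a", "b"),
                               c(homopoly("A"), homopoly("A"))),
               "identical")
  expect_error(reference_panel("a", "ACGT"), "at least 50")
})

test_that("noiseless renders are the exact linear mixture of indicators", {
  # pure single sequence: one unit channel per position
  pan <- homopoly_panel(c("A", "C"))
  s <- render_spectrum(pan, c(1, 0))
  expect_equal(unname(s$intensities[, "A"]), rep(1, 60))
  expect_equal(sum(s$intensities[, c("C", "G", "T")]), 0)

  # linear mixing of everywhere-different sequences
  m <- render_spectrum(pan, c(0.6, 0.4))
  expect_equal(unname(m$intensities[1, ]), c(0.6, 0.4, 0, 0))
  expect_true(all(abs(m$intensities[, 1] - 0.6) < 1e-15))

  # summation identity: row sums equal scale * sum(proportions) everywhere
  pan3 <- small_panel(3)
  x <- render_spectrum(pan3, c(0.5, 0.3, 0.1), scale = 2.5)
  expect_equal(rowSums(x$intensities),
               rep(2.5 * 0.9, pan3$L), tolerance = 1e-12)

  expect_error(render_spectrum(pan3, c(1, 0)), "one entry per panel")
})

test_that("rendered noise is truncated at zero and seed-reproducible", {
  pan <- small_panel(2)
  a <- render_spectrum(pan, c(0.5, 0.3), noise_sd = 0.3, seed = 42)
  b <- render_spectrum(pan, c(0.5, 0.3), noise_sd = 0.3, seed = 42)
  expect_identical(a$intensities, b$intensities)
  expect_true(all(a$intensities >= 0))
  c_ <- render_spectrum(pan, c(0.5, 0.3), noise_sd = 0.3, seed = 43)
  expect_false(identical(a$intensities, c_$intensities))
})

test_that("simulate_dataset honors the sampling design bookkeeping", {
  d <- seasonal_design(bees_per_month = 30L, seed = 9)
  pan <- make_reference_panel(4, L = 60, min_divergence = 0.2, seed = 3,
                              names = colnames(d$proportions))
  sim <- simulate_dataset(pan, d)
  # six months x 30 bees
  expect_length(sim$spectra, 180)
  expect_equal(nrow(sim$truth), 180)
  expect_equal(as.vector(table(sim$meta$month)), rep(30L, 6))
  expect_setequal(sim$meta$sample_id, sim$truth$sample_id)
  # low-quality flag count is exact, not binomial
  expect_equal(sum(sim$truth$low_quality),
               round(d$lowquality_fraction * 180))
  # determinism
  sim2 <- simulate_dataset(pan, d)
  expect_identical(sim$truth, sim2$truth)
  expect_identical(sim$spectra[[17]]$intensities,
                   sim2$spectra[[17]]$intensities)
})

test_that("exactly the requested fraction of samples is flagged low quality", {
  d <- seasonal_design(bees_per_month = 25L, lowquality_fraction = 0.2,
                       seed = 4)
  pan <- make_reference_panel(4, L = 60, min_divergence = 0.2, seed = 3)
  sim <- simulate_dataset(pan, d)
  expect_equal(sum(sim$truth$low_quality), 30)  # 0.2 * 150
})

test_that("infinite dispersion reproduces the monthly means exactly", {
  d <- seasonal_design(bees_per_month = 5L, dispersion = Inf,
                       lowquality_fraction = 0, seed = 2)
  pan <- make_reference_panel(4, L = 60, min_divergence = 0.2, seed = 3)
  sim <- simulate_dataset(pan, d)
  p_cols <- grep("^p_", names(sim$truth))
  for (m in d$months) {
    rows <- sim$truth[sim$meta$month == m, p_cols]
    expect_true(all(apply(rows, 2, function(v) max(v) - min(v)) == 0))
    expect_equal(unname(unlist(rows[1, ])),
                 unname(d$proportions[m, ]))
  }
})

test_that("within-month proportions keep their design mean on average", {
  d <- seasonal_design(bees_per_month = 400L, dispersion = 100,
                       lowquality_fraction = 0, seed = 8)
  pan <- make_reference_panel(4, L = 60, min_divergence = 0.2, seed = 3)
  sim <- simulate_dataset(pan, d)
  p_cols <- grep("^p_", names(sim$truth))
  may <- sim$truth[sim$meta$month == "May", p_cols]
  expect_equal(unname(colMeans(may)), unname(d$proportions["May", ]),
               tolerance = 0.02)
  expect_true(all(sim$truth[, p_cols] >= 0))
})

test_that("simulated qPCR inverts the load formula exactly at zero noise", {
  ratios <- 10^seq(-1, 1, length.out = 50)
  rec <- simulate_qpcr(ratios, efficiencies = c(2, 1.9), ct_noise_sd = 0,
                       seed = 1)
  loads <- relative_load_table(rec)
  expect_equal(nrow(loads), 50)
  expect_lt(max(abs(loads$log_ratio - log10(ratios))), 1e-9)

  # ratio 1 at equal efficiencies: CT pair identical
  r1 <- simulate_qpcr(1, efficiencies = c(2, 2), seed = 1)
  expect_equal(r1$ct[r1$target == "bee"], r1$ct[r1$target == "bacteria"])

  # hand-evaluated: ratio 10^1.505 at E=2/2 and CT_bact=25 puts CT_bee ~ 30
  r2 <- simulate_qpcr(10^1.505, efficiencies = c(2, 2), base_ct = 25,
                      seed = 1)
  expect_equal(r2$ct[r2$target == "bee"], 25 + 1.505 / log10(2),
               tolerance = 1e-12)
  expect_error(simulate_qpcr(-1), "positive")
  expect_error(simulate_qpcr(1, efficiencies = c(2.2, 2)), "efficienc")
})

test_that("design validation rejects malformed inputs", {
  expect_error(mixing_design(c("a", "b"), matrix(0.2, 1, 3)),
               "one row per month")
  expect_error(mixing_design("a", matrix(-0.1, 1, 2)), "non-negative")
  expect_error(seasonal_design(lowquality_fraction = 1.2), "lowquality")
})
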