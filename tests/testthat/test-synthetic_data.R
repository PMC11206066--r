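test_that("spec validation and determinism", {
  expect_error(synth_spec(m_true = 0), "m_true")
  expect_error(synth_spec(m_true = 1.5), "m_true")
  expect_error(synth_spec(frac_generalist = 0.6, frac_specialist = 0.6),
               "fractions")
  expect_error(synth_spec(band_sizes = c(10, 10, 10)), "band_sizes")

  spec <- synth_spec(n_otus = 120, n_samples = 24, rng_seed = 9)
  a <- simulate_dataset(spec)
  b <- simulate_dataset(spec)
  expect_identical(unclass(a$table), unclass(b$table))
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$category, b$truth$category)
})

test_that("neutral backbone: sample totals, large-N limit, beta marginals", {
  spec <- synth_spec(n_otus = 100, n_samples = 20, reads_per_sample = 500,
                     frac_generalist = 0, frac_specialist = 0, rng_seed = 2)
  sim <- simulate_neutral_community(spec)
  expect_true(all(colSums(sim$table) == 500))
  expect_true(all(sim$truth$category == "neutral"))

  # m = 1 with a huge read depth: local composition converges to p
  spec_lim <- synth_spec(n_otus = 40, n_samples = 6, m_true = 1,
                         reads_per_sample = 500000, frac_generalist = 0,
                         frac_specialist = 0, rng_seed = 5)
  lim <- simulate_neutral_community(spec_lim)
  ra <- relative_abundance(lim$table, "per_sample")
  expect_lt(max(abs(ra - lim$truth$p)), 0.01)

  # marginal moments: mean ~ p_i; variance ~ Beta term + multinomial term
  spec_mom <- synth_spec(n_otus = 30, n_samples = 400, m_true = 0.1,
                         reads_per_sample = 1000, frac_generalist = 0,
                         frac_specialist = 0, rng_seed = 8)
  mom <- simulate_neutral_community(spec_mom)
  ra <- relative_abundance(mom$table, "per_sample")
  p <- mom$truth$p
  N <- 1000
  big <- which(p > 0.02)  # informative taxa with decent Monte-Carlo error
  emp_mean <- rowMeans(ra)[big]
  emp_var <- apply(ra, 1, stats::var)[big]
  pred_var <- p[big] * (1 - p[big]) *
    (1 / (N * spec_mom$m_true + 1) + 1 / N)
  expect_lt(max(abs(emp_mean / p[big] - 1)), 0.15)
  expect_lt(max(abs(emp_var / pred_var - 1)), 0.35)

  expect_s3_class(
    simulate_neutral_community(
      synth_spec(n_otus = 50, n_samples = 6,
                 metacommunity_shape = "logseries", frac_generalist = 0,
                 frac_specialist = 0, rng_seed = 1))$table, "otu_table")
})

test_that("planting: identity, banding of specialists, renormalization", {
  spec0 <- synth_spec(n_otus = 80, n_samples = 24, frac_generalist = 0,
                      frac_specialist = 0, rng_seed = 4)
  sim <- simulate_neutral_community(spec0)
  same <- plant_niche_structure(sim$table, sim$truth, spec0)
  expect_identical(unclass(same$table), unclass(sim$table))

  spec <- synth_spec(n_otus = 80, n_samples = 24, rng_seed = 4)
  planted <- plant_niche_structure(sim$table, sim$truth, spec)
  expect_true(all(colSums(planted$table) == spec$reads_per_sample))
  sp <- names(planted$truth$specialist_band)
  for (otu in sp) {
    home <- planted$truth$specialist_band[[otu]]
    outside <- planted$truth$band != home
    expect_true(all(unclass(planted$table)[otu, outside] == 0))
  }
  expect_equal(sum(planted$truth$category == "specialist"),
               round(0.415 * 80))
  expect_equal(sum(planted$truth$category == "generalist"),
               round(0.06 * 80))

  tiny <- synth_spec(n_otus = 10, n_samples = 24, frac_generalist = 0.9,
                     frac_specialist = 0.1, rng_seed = 4)
  expect_error(plant_niche_structure(sim$table[1:10, ], sim$truth, tiny),
               NA)  # exactly 10 planted of 10 is allowed
})

test_that("metadata: band-separated elevation, covariate structure", {
  spec <- synth_spec(n_otus = 60, rng_seed = 6)
  d <- simulate_dataset(spec)
  meta <- d$metadata
  band <- d$truth$band
  for (i in 1:3) {
    sel <- band == levels(band)[i]
    expect_true(all(meta$MEA[sel] >= spec$band_ranges[i, 1]))
    expect_true(all(meta$MEA[sel] <= spec$band_ranges[i, 2]))
  }
  # bands non-overlapping in MEA => breakpoints recoverable
  expect_lt(max(meta$MEA[band == "LEG"]), min(meta$MEA[band == "MEG"]))
  expect_lt(max(meta$MEA[band == "MEG"]), min(meta$MEA[band == "HEG"]))
  # covariates track elevation with the recipe's sign
  expect_gt(cor(meta$MEA, meta$water_content), 0.3)
  expect_lt(cor(meta$MEA, meta$soil_pH), -0.3)
  expect_true(all(meta$CC >= 0 & meta$CC <= 1))

  # zero soil effect: soil block decorrelates from elevation
  spec0 <- synth_spec(n_otus = 60, rng_seed = 6,
                      covariate_effects = c(topography = 1, light = 1,
                                            soil = 0))
  d0 <- simulate_dataset(spec0)
  expect_lt(abs(cor(d0$metadata$MEA, d0$metadata$water_content)), 0.25)
})
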