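test_that("atlas generation honors bounds, separation, and determinism", {
  a2 <- generate_atlas(2, seed = 1)
  expect_equal(nrow(a2), 2)
  expect_gt(sqrt(sum((a2[1, c("x", "y", "z")] - a2[2, c("x", "y", "z")])^2)), 2)

  a <- generate_atlas(60, seed = 7)
  b <- generate_atlas(60, seed = 7)
  expect_identical(a, b)

  big <- generate_atlas(438, seed = 1)
  expect_identical(big$id, 1:438)
  d <- stats::dist(big[, c("x", "y", "z")])
  expect_gte(min(d), 8)

  expect_error(generate_atlas(1, seed = 1), "n_parcels")
})

test_that("synth_config validates its invariants", {
  expect_error(synth_config(connection_sparsity = 1), "sparsity")
  expect_error(synth_config(effect_baseline = -1), "planted correlations")
  expect_error(synth_config(n_closed = 0), "counts")
  expect_s3_class(synth_config(), "synth_config")
})

test_that("tractogram counts are zero-inflated and overdispersed", {
  cfg <- synth_config(n_parcels = 142, n_closed = 2, n_random = 2,
                      streamline_density = 5, connection_sparsity = 0.5)
  atlas <- generate_atlas(cfg$n_parcels, seed = 3)
  tr <- generate_tractogram(atlas, cfg, seed = 4)
  n_pairs <- choose(142, 2)  # > 10^4 pairs
  key <- paste(tr$parcel_a, tr$parcel_b)
  counts <- rep(0L, n_pairs)
  tab <- table(key)
  counts[seq_along(tab)] <- as.integer(tab)
  frac_zero <- 1 - length(tab) / n_pairs
  expect_lt(abs(frac_zero - cfg$connection_sparsity), 0.05)
  expect_gt(stats::var(counts), mean(counts))
})

test_that("near-total sparsity leaves almost all pairs unconnected", {
  cfg <- synth_config(n_parcels = 40, connection_sparsity = 0.999,
                      streamline_density = 1)
  atlas <- generate_atlas(40, seed = 5)
  tr <- generate_tractogram(atlas, cfg, seed = 6)
  expect_lt(length(unique(paste(tr$parcel_a, tr$parcel_b))),
            0.02 * choose(40, 2))
})

test_that("tractogram generation is deterministic and well-formed", {
  w <- small_world()
  tr2 <- generate_tractogram(w$atlas, w$cfg, w$cfg$seed + 10L)
  expect_identical(w$tract$vertices, tr2$vertices)
  expect_true(all(vapply(w$tract$vertices, nrow, integer(1)) >= 8))
  expect_true(all(c(w$tract$parcel_a, w$tract$parcel_b) %in% w$atlas$id))
})

test_that("encoding network plants a recoverable high-weight core", {
  w <- small_world()
  core <- attr(w$weights, "core")
  mask <- threshold_network(w$weights, 0.3)
  expect_true(all(mask[core]))  # core within the top-30% positive mask
  expect_identical(w$weights,
                   generate_encoding_network(w$atlas, seed = w$cfg$seed + 20L))
  all_core <- generate_encoding_network(w$atlas, n_core = nrow(w$atlas),
                                        seed = 9)
  expect_true(all(all_core > 0))
})

test_that("time series carry task coactivation and standardized rows", {
  w <- small_world()
  ts <- generate_timeseries(w$atlas, 2, 120, encoding_weights = w$weights,
                            seed = 1)
  expect_identical(ts, generate_timeseries(w$atlas, 2, 120,
                                           encoding_weights = w$weights,
                                           seed = 1))
  expect_equal(unname(apply(ts[[1]], 1, stats::sd)), rep(1, nrow(w$atlas)))

  # no task loading, independent noise: off-diagonal correlations near zero
  ts0 <- generate_timeseries(w$atlas, 1, 500, noise_range = 0, seed = 2)
  r <- stats::cor(t(ts0[[1]]))
  expect_lt(abs(mean(r[upper.tri(r)])), 0.05)

  # dominant shared task loading drives correlation toward 1
  w2 <- stats::setNames(rep(1, nrow(w$atlas)), w$atlas$id)
  ts1 <- generate_timeseries(w$atlas, 1, 200, encoding_weights = w2,
                             task_amplitude = 100, noise_range = 0, seed = 3)
  r2 <- stats::cor(ts1[[1]][1, ], ts1[[1]][2, ])
  expect_gt(r2, 0.99)
})

test_that("cohort sessions satisfy task structure and inclusion rule", {
  w <- small_world()
  cohort <- generate_cohort(w$atlas, w$tract, w$weights, w$cfg)
  sess <- cohort$sessions
  expect_equal(nrow(cohort$sites), w$cfg$n_closed + w$cfg$n_random)
  # first three lists never stimulated
  expect_false(any(sess$stimulated_flag[sess$list_index <= 3]))
  out <- memory_change(sess, cohort$sites)
  expect_true(all(out$included))
  expect_true(all(out$r_ns >= 100 / 12))
  # determinism
  cohort2 <- generate_cohort(w$atlas, w$tract, w$weights, w$cfg)
  expect_identical(cohort$sessions, cohort2$sessions)
})

test_that("infeasible planted-correlation combinations are rejected", {
  w <- small_world()
  bad <- small_cfg(effect_sc_memory = 0.9, effect_baseline = -0.9,
                   noise_sd = 5)
  sites <- generate_sites(w$atlas, w$tract, w$weights, small_cfg())
  expect_error(generate_behavior(sites, bad), "infeasible")
})

test_that("white-matter proximity is negatively coupled to connectivity", {
  s <- study_world()
  expect_lt(stats::cor(s$sites$wmp_mm, s$sites$total_sc,
                       method = "spearman"), -0.15)
  expect_true(all(s$sites$wmp_mm >= 0))
})
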