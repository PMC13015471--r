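test_that("sphere intersection handles the canonical geometries", {
  through <- rbind(c(-10, 0, 0), c(10, 0, 0))
  expect_true(streamline_intersects_sphere(through, c(0, 0, 0), 5))
  # both endpoints at 3r on the same side, straight segment
  away <- rbind(c(15, 0, 0), c(25, 0, 0))
  expect_false(streamline_intersects_sphere(away, c(0, 0, 0), 5))
  # segment interior closest (endpoints outside, chord inside)
  chord <- rbind(c(-20, 4, 0), c(20, 4, 0))
  expect_true(streamline_intersects_sphere(chord, c(0, 0, 0), 5))
  expect_error(streamline_intersects_sphere(matrix(0, 1, 3), c(0, 0, 0), 5),
               "vertices")
  expect_error(streamline_intersects_sphere(through, c(0, 0, 0), 0),
               "radius")
})

test_that("segment test agrees with the dense-sampling oracle", {
  set.seed(101)
  for (i in 1:200) {
    v <- random_polyline()
    center <- stats::runif(3, -30, 30)
    radius <- stats::runif(1, 2, 15)
    expect_identical(streamline_intersects_sphere(v, center, radius),
                     intersects_by_sampling(v, center, radius),
                     label = paste("case", i))
  }
})

test_that("pairwise ChaCo ratios follow the counting definition", {
  tr <- two_parcel_tract(n = 4, k_through = 1)
  pw <- pairwise_chaco(tr, c(0, 0, 0), 5)
  expect_equal(pw$ratio, 0.25)
  expect_equal(pw$n_total, 4L)

  w <- small_world()
  # sphere engulfing everything: every connected pair has ratio 1
  pw_all <- pairwise_chaco(w$tract, c(0, 0, 0), 1e4)
  expect_true(all(pw_all$ratio == 1))
  # sphere far outside the bounding box: all ratios 0
  pw_none <- pairwise_chaco(w$tract, c(1e4, 1e4, 1e4), 12)
  expect_true(all(pw_none$ratio == 0))
  expect_true(all(pw_all$ratio >= 0 & pw_all$ratio <= 1))
})

test_that("cumulative ChaCo sums pairwise ratios per parcel", {
  atlas3 <- generate_atlas(3, seed = 1)
  pw <- data.frame(parcel_a = c(1L, 1L), parcel_b = c(2L, 3L),
                   n_total = c(4L, 2L), n_hit = c(1L, 1L),
                   ratio = c(0.25, 0.5))
  cum <- cumulative_chaco(pw, atlas3)
  expect_equal(unname(cum), c(0.75, 0.25, 0.5))

  w <- small_world()
  pw2 <- pairwise_chaco(w$tract, c(0, 0, 10), 12)
  cum2 <- cumulative_chaco(pw2, w$atlas)
  expect_equal(sum(cum2), 2 * sum(pw2$ratio))  # double-counting identity
  expect_equal(unname(cumulative_chaco(pw2[pw2$ratio > 0, ][0, ], w$atlas)),
               rep(0, nrow(w$atlas)))
})

test_that("shrinking the radius never increases a ratio", {
  w <- small_world()
  set.seed(11)
  for (k in 1:5) {
    center <- stats::runif(3, -40, 40)
    big <- pairwise_chaco(w$tract, center, 15)
    small <- pairwise_chaco(w$tract, center, 8)
    m <- merge(big, small, by = c("parcel_a", "parcel_b"))
    expect_true(all(m$ratio.y <= m$ratio.x))
  }
})

test_that("translating tractogram and site together leaves ratios fixed", {
  w <- small_world()
  shift <- c(13.5, -7.2, 21.9)
  tr2 <- tractogram(w$tract$parcel_a, w$tract$parcel_b,
                    lapply(w$tract$vertices, function(v) sweep(v, 2, -shift)),
                    w$tract$n_parcels)
  center <- c(5, 5, 5)
  expect_equal(pairwise_chaco(w$tract, center, 12)$ratio,
               pairwise_chaco(tr2, center + shift, 12)$ratio)
})

test_that("normative averaging is the element-wise mean of ratios", {
  atlas2 <- generate_atlas(2, seed = 2)
  mk <- function(k_through) {
    tr <- two_parcel_tract(n = 2, k_through = k_through)
    chaco_profile(tr, data.frame(site_id = "s", x = 0, y = 0, z = 0,
                                 radius_mm = 5), atlas2)
  }
  p0 <- mk(0); p2 <- mk(2)   # ratios 0 and 1 for the single pair
  expect_identical(normative_average(list(p2), atlas2)$cumulative,
                   p2$cumulative)
  avg <- normative_average(list(p0, p2), atlas2)
  expect_equal(avg$pairwise$ratio, 0.5)
  expect_true(all(avg$pairwise$ratio >= 0 & avg$pairwise$ratio <= 1))
  atlas3 <- generate_atlas(3, seed = 3)
  p_other <- chaco_profile(two_parcel_tract(), data.frame(
    site_id = "s", x = 0, y = 0, z = 0, radius_mm = 5), atlas3)
  expect_error(normative_average(list(p0, p_other), atlas2), "mismatch")
})
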