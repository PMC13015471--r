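make_session <- function(recalls_ns, recalls_s, lead = c(4, 4, 4),
                         site = "s1", words = 12) {
  n <- 3 + length(recalls_ns) + length(recalls_s)
  data.frame(site_id = site, list_index = seq_len(n),
             stimulated_flag = c(rep(FALSE, 3 + length(recalls_ns)),
                                 rep(TRUE, length(recalls_s))),
             n_words = words,
             n_recalled = c(lead, recalls_ns, recalls_s))
}

test_that("memory change implements the percent-change definition", {
  # R_S = R_NS gives 0
  s <- make_session(recalls_ns = c(4, 4), recalls_s = c(4, 4))
  expect_equal(memory_change(s)$delta, 0)
  # R_S = 33.33%, R_NS = 30% -> 11.11
  s2 <- make_session(recalls_ns = c(4, 3, 4, 3, 4), recalls_s = c(4, 4, 4),
                     lead = c(0, 0, 0), words = 12)
  # R_NS = mean(4,3,4,3,4)/12 = 30%; R_S = 4/12 = 33.33%
  expect_equal(memory_change(s2)$delta, 11.1111, tolerance = 1e-4)
  # doubled recall on stimulated lists -> 100
  s3 <- make_session(recalls_ns = c(3, 3), recalls_s = c(6, 6))
  expect_equal(memory_change(s3)$delta, 100)
})

test_that("the first three lists are excluded from the baseline", {
  # leading lists have absurdly high recall; they must not touch R_NS
  s <- make_session(recalls_ns = c(3, 3), recalls_s = c(6, 6),
                    lead = c(12, 12, 12))
  out <- memory_change(s)
  expect_equal(out$r_ns, 25)
  expect_equal(out$delta, 100)
})

test_that("low-baseline sites are excluded with a code", {
  s <- make_session(recalls_ns = c(0, 1), recalls_s = c(2, 2))  # R_NS 4.17%
  out <- memory_change(s)
  expect_false(out$included)
  expect_identical(out$exclusion_code, "low_baseline")
  expect_true(is.na(out$delta))
  # boundary: exactly one word per list is included
  s2 <- make_session(recalls_ns = c(1, 1), recalls_s = c(2, 2))
  expect_true(memory_change(s2)$included)
})

test_that("delta is invariant to the word-count unit", {
  s12 <- make_session(recalls_ns = c(3, 4), recalls_s = c(5, 6), words = 12)
  s24 <- make_session(recalls_ns = c(6, 8), recalls_s = c(10, 12),
                      lead = c(8, 8, 8), words = 24)
  expect_equal(memory_change(s12)$delta, memory_change(s24)$delta)
})

test_that("one- and two-sample t statistics match closed forms", {
  expect_equal(one_sample_t(c(1, -1))$t, 0)
  expect_error(one_sample_t(c(2, 2, 2)), "variance")
  x <- c(3.1, 0.2, -1.4, 5.9, 2.2)
  ot <- one_sample_t(x)
  expect_equal(ot$t, mean(x) / (sd(x) / sqrt(5)))
  expect_equal(ot$df, 4)

  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  # hand calculation: means 1 and -1, each var 2 -> t = sqrt(2)
  ht <- two_sample_t(c(0, 2), c(0, -2))
  expect_equal(ht$t, sqrt(2))
  ht_p <- two_sample_t(c(0, 2), c(0, -2), pooled = TRUE)
  expect_equal(ht_p$t, sqrt(2))
  expect_equal(ht_p$df, 2)
  expect_equal(two_sample_t(c(0, -2), c(0, 2))$t, -ht$t)  # antisymmetry
})

test_that("t from printed summaries is plain mean/sem arithmetic", {
  r <- t_from_summary(10, 4, df = 20)
  expect_equal(r$t, 2.5)
  expect_equal(r$p, 2 * pt(-2.5, 20))
  expect_error(t_from_summary(1, 0, 10), "sem")
})

test_that("baseline stratification assigns ties to the high group", {
  out <- data.frame(site_id = letters[1:4], r_ns = c(10, 30, 29.9, 50),
                    delta = 1:4)
  st <- stratify_baseline(out, 30)
  expect_identical(st$low$site_id, c("a", "c"))
  expect_identical(st$high$site_id, c("b", "d"))
  expect_equal(nrow(stratify_baseline(out, 0)$low), 0)
  expect_equal(nrow(stratify_baseline(out, 100)$high), 0)
})

test_that("low-baseline sites benefit more in planted cohorts", {
  s <- study_world()
  wins <- 0
  n_rep <- 25
  for (r in seq_len(n_rep)) {
    sess <- generate_behavior(s$sites, s$cfg, seed = 300 + r)
    out <- memory_change(sess, s$sites)
    cl <- out[out$mode == "closed" & out$included, ]
    st <- stratify_baseline(cl, 30)
    wins <- wins + (mean(st$low$delta) > mean(st$high$delta))
  }
  expect_gte(wins / n_rep, 0.9)
})

test_that("correlation wrappers agree with their definitions", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  expect_equal(pearson_r(x, x)$estimate, 1)
  expect_equal(spearman_rho(x, x)$estimate, 1)
  expect_equal(kendall_tau_b(x, x)$estimate, 1)
  expect_error(pearson_r(x, rep(1, 5)), "constant")
  # worked example: exactly one discordant pair out of six
  expect_equal(kendall_tau_b(c(1, 2, 3, 4), c(1, 3, 2, 4))$estimate, 2 / 3)
})

test_that("tau-b equals brute-force concordance counting under ties", {
  set.seed(202)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    x <- sample(0:3, n, replace = TRUE)   # heavy ties, zero-inflated
    y <- sample(1:5, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(kendall_tau_b(x, y)$estimate, tau_b_brute(x, y),
                 tolerance = 1e-12, label = paste("case", i))
  }
})
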