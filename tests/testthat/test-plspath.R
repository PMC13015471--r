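simple_spec <- function(moderations = NULL, ...) {
  pls_model_spec(
    blocks = list(X = "x", M = "m", Y = "y"),
    paths = data.frame(from = c("X", "X", "M"), to = c("M", "Y", "Y")),
    moderations = moderations, ...)
}

test_that("model specs validate blocks and acyclicity", {
  expect_s3_class(simple_spec(), "pls_model_spec")
  expect_error(pls_model_spec(list(A = "x", B = "x"),
                              data.frame(from = "A", to = "B")),
               "exactly one block")
  expect_error(pls_model_spec(list(A = "x", B = "y"),
                              data.frame(from = c("A", "B"),
                                         to = c("B", "A"))),
               "acyclic")
  expect_error(simple_spec(moderations = list(c("X", "M"))), "moderation")
})

test_that("indicator preprocessing zero-replaces, logs, standardizes", {
  d <- data.frame(sc = c(0, 1, exp(1)), other = c(5, 7, 9))
  out <- preprocess_indicators(d, log_columns = "sc")
  # {0,1,e} -> zeros to min nonzero (1) -> log -> {0,0,1}
  expect_equal(out$sc, as.numeric(scale(c(0, 0, 1))))
  expect_equal(out$other, as.numeric(scale(c(5, 7, 9))))
  expect_equal(vapply(out, mean, numeric(1)), c(sc = 0, other = 0))
  expect_equal(vapply(out, sd, numeric(1)), c(sc = 1, other = 1))
  expect_error(preprocess_indicators(data.frame(sc = c(0, 0)),
                                     log_columns = "sc"), "all zero")
})

test_that("single-indicator models equal standardized OLS path analysis", {
  set.seed(51)
  n <- 80
  x <- rnorm(n)
  m <- 0.5 * x + rnorm(n)
  y <- 0.4 * m - 0.3 * x + rnorm(n)
  d <- data.frame(x = x, m = m, y = y)
  fit <- fit_pls(simple_spec(), d)
  oracle_m <- ols_paths_oracle(d, "x", "m")
  oracle_y <- ols_paths_oracle(d, c("x", "m"), "y")
  expect_equal(path_via <- fit$paths$beta[fit$paths$from == "X" &
                                            fit$paths$to == "M"],
               unname(oracle_m["x"]), tolerance = 1e-6)
  expect_equal(fit$paths$beta[fit$paths$from == "M" & fit$paths$to == "Y"],
               unname(oracle_y["m"]), tolerance = 1e-6)
  expect_equal(fit$paths$beta[fit$paths$from == "X" & fit$paths$to == "Y"],
               unname(oracle_y["x"]), tolerance = 1e-6)
  # latent scores standardized
  expect_equal(unname(colMeans(fit$scores)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(fit$scores, 2, sd)), rep(1, 3))
})

test_that("duplicated noise-free indicators recover the saturated case", {
  set.seed(52)
  n <- 60
  f1 <- rnorm(n); f2 <- 0.6 * f1 + 0.8 * rnorm(n)
  d <- data.frame(a1 = f1, a2 = f1, b1 = f2, b2 = f2)
  spec <- pls_model_spec(list(A = c("a1", "a2"), B = c("b1", "b2")),
                         data.frame(from = "A", to = "B"))
  fit <- fit_pls(spec, d)
  expect_equal(fit$paths$beta, cor(fit$scores[, "A"], fit$scores[, "B"]))
  expect_equal(fit$paths$beta, cor(f1, f2), tolerance = 1e-6)
  expect_true(all(abs(unlist(fit$loadings)) <= 1 + 1e-8))
})

test_that("reflective measurement recovers a planted path of 0.5", {
  set.seed(53)
  est <- replicate(30, {
    n <- 200
    fx <- rnorm(n)
    fy <- 0.5 * fx + sqrt(0.75) * rnorm(n)
    mk <- function(f) 0.85 * f + sqrt(1 - 0.85^2) * rnorm(n)
    d <- data.frame(x1 = mk(fx), x2 = mk(fx), x3 = mk(fx),
                    y1 = mk(fy), y2 = mk(fy), y3 = mk(fy))
    spec <- pls_model_spec(list(X = c("x1", "x2", "x3"),
                                Y = c("y1", "y2", "y3")),
                           data.frame(from = "X", to = "Y"))
    fit_pls(spec, d)$paths$beta
  })
  expect_lt(abs(mean(est) - 0.5), 0.1)
})

test_that("bootstrap inference is deterministic and self-consistent", {
  set.seed(54)
  n <- 60
  x <- rnorm(n); m <- 0.6 * x + rnorm(n); y <- 0.5 * m + rnorm(n)
  d <- data.frame(x = x, m = m, y = y)
  b1 <- bootstrap_inference(simple_spec(), d, n_boot = 150, seed = 3)
  b2 <- bootstrap_inference(simple_spec(), d, n_boot = 150, seed = 3)
  expect_identical(b1$paths, b2$paths)
  expect_identical(b1$indirect, b2$indirect)
  # indirect effect is the product of its two observed paths
  a_hat <- b1$paths$beta[b1$paths$from == "X" & b1$paths$to == "M"]
  b_hat <- b1$paths$beta[b1$paths$from == "M" & b1$paths$to == "Y"]
  ind <- b1$indirect[b1$indirect$from == "X" & b1$indirect$to == "Y", ]
  expect_equal(ind$beta, a_hat * b_hat)
  expect_true(all(b1$paths$se > 0))
})

test_that("moderation interactions are centered and detectable", {
  set.seed(55)
  n <- 200
  g <- rep(c(1, 0), each = n / 2)
  x <- rnorm(n)
  y <- 0.6 * x * g + rnorm(n)             # slope only in group 1
  d <- data.frame(x = x, g = g, y = y)
  spec <- pls_model_spec(list(X = "x", G = "g", Y = "y"),
                         data.frame(from = c("X", "G"), to = c("Y", "Y")),
                         moderations = list(c("G", "X", "Y")))
  b <- bootstrap_inference(spec, d, n_boot = 200, seed = 4)
  row <- moderation_effect(b, "G", "X", "Y")
  expect_lt(row$p, 0.05)
  # the interaction regressor is a standardized product of latent scores
  fit <- b$fit
  term <- fit$scores[, "G"] * fit$scores[, "X"]
  expect_equal(mean((term - mean(term)) / sd(term)), 0, tolerance = 1e-12)
})

test_that("mediation decomposes total effects and flags degeneracies", {
  set.seed(56)
  n <- 300
  x <- rnorm(n); m <- -0.3 * x + rnorm(n); y <- 0.5 * m - 0.2 * x + rnorm(n)
  fit <- fit_pls(simple_spec(), data.frame(x = x, m = m, y = y))
  med <- mediation(fit, "X", "M", "Y")
  expect_equal(med$indirect, med$a * med$b)
  expect_equal(med$total, med$direct + med$indirect)
  expect_equal(med$proportion_mediated,
               100 * med$indirect / med$total)
  # a = 0 in the population: indirect near zero, proportion defined
  m0 <- rnorm(n); y0 <- 0.5 * m0 - 0.4 * x + rnorm(n)
  fit0 <- fit_pls(simple_spec(), data.frame(x = x, m = m0, y = y0))
  med0 <- mediation(fit0, "X", "M", "Y")
  expect_lt(abs(med0$indirect), 0.1)
})

test_that("quality diagnostics match their formulas", {
  set.seed(57)
  n <- 150
  fx <- rnorm(n); fy <- rnorm(n)          # independent blocks
  mk <- function(f) 0.9 * f + sqrt(1 - 0.81) * rnorm(n)
  d <- data.frame(x1 = mk(fx), x2 = mk(fx), y1 = mk(fy), y2 = mk(fy))
  spec <- pls_model_spec(list(X = c("x1", "x2"), Y = c("y1", "y2")),
                         data.frame(from = "X", to = "Y"))
  fit <- fit_pls(spec, d)
  q <- quality_diagnostics(fit)
  expect_equal(unname(q$ave["X"]), mean(fit$loadings$X^2))
  expect_true(all(q$ave >= 0 & q$ave <= 1))
  expect_lt(q$htmt["X", "Y"], 0.2)        # independent blocks: HTMT near 0
  # perfectly unidimensional block: duplicated indicator, AVE = 1
  d2 <- data.frame(x1 = fx, x2 = fx, y1 = mk(fy), y2 = mk(fy))
  fit2 <- fit_pls(spec, d2)
  expect_equal(unname(quality_diagnostics(fit2)$ave["X"]), 1)
})

test_that("BIC ranks structural models as expected", {
  set.seed(58)
  n <- 61
  x <- rnorm(n); y <- 0.6 * x + rnorm(n); junk <- rnorm(n)
  d <- data.frame(x = x, y = y, z = junk)
  s1 <- pls_model_spec(list(X = "x", Y = "y"),
                       data.frame(from = "X", to = "Y"))
  s2 <- pls_model_spec(list(X = "x", Z = "z", Y = "y"),
                       data.frame(from = c("X", "Z"), to = c("Y", "Y")))
  f1 <- fit_pls(s1, d[, c("x", "y")])
  f2 <- fit_pls(s2, d)
  expect_equal(model_bic(f1, "Y") - model_bic(f1, "Y"), 0)
  # adding a null predictor should usually worsen BIC
  favors_small <- replicate(40, {
    y <- 0.6 * x + rnorm(n); z <- rnorm(n)
    dd <- data.frame(x = x, y = y, z = z)
    model_bic(fit_pls(s1, dd[, c("x", "y")]), "Y") <
      model_bic(fit_pls(s2, dd), "Y")
  })
  expect_gte(mean(favors_small), 0.8)
  # BIC is monotone in SSE at fixed k
  y_tight <- 0.6 * x + 0.3 * rnorm(n)
  f_tight <- fit_pls(s1, data.frame(x = x, y = y_tight))
  expect_lt(model_bic(f_tight, "Y"), model_bic(f1, "Y"))
})
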