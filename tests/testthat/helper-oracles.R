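# Independent oracles kept deliberately naive: they re-derive the quantity
# from first principles so implementation and check never share code.

# Sphere intersection by dense sampling along every segment at a step of
# radius/100.
intersects_by_sampling <- function(vertices, center, radius) {
  for (i in seq_len(nrow(vertices) - 1)) {
    a <- vertices[i, ]; b <- vertices[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    ts <- seq(0, 1, length.out = max(2, ceiling(len / (radius / 100)) + 1))
    pts <- outer(1 - ts, a) + outer(ts, b)
    if (min(sqrt(rowSums(sweep(pts, 2, center)^2))) <= radius) return(TRUE)
  }
  FALSE
}

# Kendall tau-b by exhaustive concordant/discordant counting with the
# tie-corrected denominator.
tau_b_brute <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  n1 <- sum(choose(table(x), 2))
  n2 <- sum(choose(table(y), 2))
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

# Standardized OLS path coefficients: the closed-form oracle that a
# single-indicator PLS model must reproduce.
ols_paths_oracle <- function(data, formula_rhs, target) {
  z <- as.data.frame(lapply(data, function(x) as.numeric(scale(x))))
  f <- stats::as.formula(paste(target, "~", paste(formula_rhs, collapse = "+")))
  stats::coef(stats::lm(f, data = z))[-1]
}
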