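#' Specify a PLS path model
#'
#' Declares the measurement model (reflective blocks of indicator columns),
#' the structural model (directed paths between latent variables; the graph
#' must be acyclic), and optional moderation terms (the standardized product
#' of two latent scores entering the structural regression of a target).
#'
#' @param blocks named list: latent name -> character vector of indicator
#'   column names. Every indicator belongs to exactly one block.
#' @param paths two-column data frame or matrix (`from`, `to`) of directed
#'   structural paths.
#' @param moderations optional list of character triples
#'   `c(moderator, predictor, target)`.
#' @param n_boot default bootstrap resamples for [bootstrap_inference()].
#' @param seed default bootstrap seed.
#' @param tol outer-weight convergence tolerance.
#' @param max_iter maximum PLS iterations.
#' @return object of class `pls_model_spec`.
#' @export
pls_model_spec <- function(blocks, paths, moderations = NULL,
                           n_boot = 5000, seed = 1L,
                           tol = 1e-7, max_iter = 1000) {
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    stop_arg("blocks must be a named list")
  inds <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(inds))
    stop_arg("every indicator must appear in exactly one block")
  paths <- as.data.frame(paths, stringsAsFactors = FALSE)
  names(paths) <- c("from", "to")
  lat <- names(blocks)
  if (!all(c(paths$from, paths$to) %in% lat))
    stop_arg("paths reference unknown latent variables")
  # acyclicity: Kahn's algorithm, repeatedly removing source nodes
  g <- paths
  remaining <- lat
  while (length(remaining) > 0) {
    no_incoming <- remaining[!remaining %in% g$to]
    if (length(no_incoming) == 0) stop_arg("path graph must be acyclic")
    remaining <- setdiff(remaining, no_incoming)
    g <- g[!(g$from %in% no_incoming), , drop = FALSE]
  }
  if (!is.null(moderations)) {
    moderations <- lapply(moderations, function(m) {
      if (length(m) != 3 || !all(m %in% lat))
        stop_arg("each moderation must be c(moderator, predictor, target) ",
                 "over declared latents")
      as.character(m)
    })
  }
  structure(list(blocks = blocks, paths = paths,
                 moderations = moderations %||% list(),
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "pls_model_spec")
}

#' Preprocess indicator columns for path modeling
#'
#' Structural-connectivity indicators are zero-inflated and right-skewed:
#' for the flagged columns, zeros are replaced with the column's minimal
#' non-zero value and a natural log is applied. All columns are then
#' z-standardized.
#'
#' @param data data frame of indicator columns (numeric).
#' @param log_columns character vector of columns to zero-replace and
#'   log-transform.
#' @return data frame of standardized columns.
#' @export
preprocess_indicators <- function(data, log_columns = character()) {
  data <- as.data.frame(data)
  for (cn in log_columns) {
    x <- data[[cn]]
    if (is.null(x)) stop_arg("unknown column: ", cn)
    nz <- x[x != 0]
    if (length(nz) == 0) stop_arg("column ", cn, " is all zero")
    x[x == 0] <- min(nz)
    data[[cn]] <- log(x)
  }
  for (cn in names(data)) {
    if (stats::sd(data[[cn]]) == 0)
      stop_arg("column ", cn, " is constant after transformation")
    data[[cn]] <- as.numeric(scale(data[[cn]]))
  }
  data
}

# Standardize to mean 0, sd 1 (population-free: sample sd).
std1 <- function(x) (x - mean(x)) / stats::sd(x)

# Core PLS algorithm on a standardized indicator matrix. Mode A outer
# estimation, path-weighting inner scheme.
pls_engine <- function(spec, X) {
  blocks <- spec$blocks
  lat <- names(blocks)
  L <- length(lat)
  n <- nrow(X)
  bidx <- lapply(blocks, function(cols) match(cols, colnames(X)))
  if (anyNA(unlist(bidx))) stop_arg("data lacks some indicator columns")
  preds <- lapply(lat, function(j) spec$paths$from[spec$paths$to == j])
  succs <- lapply(lat, function(j) spec$paths$to[spec$paths$from == j])
  names(preds) <- names(succs) <- lat

  w <- lapply(bidx, function(ix) rep(1 / sqrt(length(ix)), length(ix)))
  scores <- function(w) {
    Y <- vapply(seq_len(L), function(j)
      std1(as.numeric(X[, bidx[[j]], drop = FALSE] %*% w[[j]])), numeric(n))
    colnames(Y) <- lat
    Y
  }
  Y <- scores(w)
  converged <- FALSE
  for (it in seq_len(spec$max_iter)) {
    # inner proxies, path-weighting scheme
    Z <- matrix(0, n, L, dimnames = list(NULL, lat))
    for (j in seq_len(L)) {
      e <- numeric(L)
      pj <- preds[[j]]
      if (length(pj) > 0) {
        Xp <- Y[, pj, drop = FALSE]
        e[match(pj, lat)] <- solve(crossprod(Xp), crossprod(Xp, Y[, j]))
      }
      sj <- succs[[j]]
      if (length(sj) > 0)
        e[match(sj, lat)] <- as.numeric(stats::cor(Y[, j], Y[, sj, drop = FALSE]))
      if (all(e == 0)) e[j] <- 1  # isolated latent: self proxy
      Z[, j] <- Y %*% e
    }
    # Mode A outer update
    w_new <- lapply(seq_len(L), function(j) {
      wj <- as.numeric(stats::cor(X[, bidx[[j]], drop = FALSE], Z[, j]))
      wj <- wj / sqrt(sum(wj^2))
      if (sum(wj) < 0) wj <- -wj  # sign convention for stable comparison
      wj
    })
    delta <- max(abs(unlist(w_new) - unlist(lapply(w, function(x) {
      x <- x / sqrt(sum(x^2)); if (sum(x) < 0) -x else x
    }))))
    w <- w_new
    Y <- scores(w)
    if (delta < spec$tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop_arg("PLS did not converge in ", spec$max_iter,
             " iterations (last max weight change ", signif(delta, 3), ")")
  # orient each latent so the majority of its loadings are positive
  load <- vector("list", L)
  for (j in seq_len(L)) {
    lj <- as.numeric(stats::cor(X[, bidx[[j]], drop = FALSE], Y[, j]))
    if (sum(sign(lj)) < 0 || (sum(sign(lj)) == 0 && sum(lj) < 0)) {
      w[[j]] <- -w[[j]]
      Y[, j] <- -Y[, j]
      lj <- -lj
    }
    load[[j]] <- lj
  }
  names(w) <- names(load) <- lat
  list(weights = w, loadings = load, scores = Y, bidx = bidx,
       preds = preds, iterations = it)
}

# Structural regressions on latent scores (plus moderation interactions).
structural_fit <- function(spec, Y) {
  lat <- colnames(Y)
  n <- nrow(Y)
  inter <- list()
  for (m in spec$moderations) {
    nm <- paste0(m[1], "x", m[2])
    inter[[nm]] <- list(term = std1(Y[, m[1]] * Y[, m[2]]), target = m[3])
  }
  targets <- unique(c(spec$paths$to,
                      vapply(spec$moderations, `[`, character(1), 3)))
  paths_out <- NULL
  r2 <- stats::setNames(numeric(length(targets)), targets)
  resid <- list()
  for (t in targets) {
    pn <- spec$paths$from[spec$paths$to == t]
    Xs <- Y[, pn, drop = FALSE]
    for (nm in names(inter))
      if (inter[[nm]]$target == t)
        Xs <- cbind(Xs, stats::setNames(data.frame(inter[[nm]]$term), nm))
    Xs <- as.matrix(Xs)
    beta <- solve(crossprod(Xs), crossprod(Xs, Y[, t]))
    fitted <- Xs %*% beta
    r2[t] <- 1 - sum((Y[, t] - fitted)^2) / sum(Y[, t]^2)
    resid[[t]] <- Y[, t] - fitted
    paths_out <- rbind(paths_out, data.frame(
      from = colnames(Xs), to = t, beta = as.numeric(beta),
      stringsAsFactors = FALSE))
  }
  list(paths = paths_out, r2 = r2, residuals = resid)
}

#' Fit a PLS path model
#'
#' Iterative partial least squares estimation: outer weights initialized
#' equal, inner proxies formed with the path-weighting scheme (regression
#' weights toward predecessors, correlations toward successors), Mode A
#' (correlation) outer updates, iterated until the largest outer-weight
#' change falls below `tol`. Latent scores are standardized and oriented so
#' that the majority of each block's loadings are positive. Path
#' coefficients are OLS regressions of each endogenous latent score on its
#' predecessors (plus any moderation interaction terms, entered two-stage as
#' standardized products of latent scores).
#'
#' @param spec a [pls_model_spec()].
#' @param data data frame holding all indicator columns (ideally from
#'   [preprocess_indicators()]; columns are re-standardized internally).
#' @return object of class `pls_fit`: outer `weights` and `loadings` per
#'   block, standardized latent `scores`, structural `paths`
#'   (`from`, `to`, `beta`), `r2` per endogenous latent, `iterations`.
#' @export
fit_pls <- function(spec, data) {
  stopifnot(inherits(spec, "pls_model_spec"))
  inds <- unlist(spec$blocks, use.names = FALSE)
  X <- as.matrix(data[, inds, drop = FALSE])
  if (nrow(X) <= max(lengths(spec$blocks)))
    stop_arg("need more observations than the largest block")
  X <- apply(X, 2, std1)
  eng <- pls_engine(spec, X)
  st <- structural_fit(spec, eng$scores)
  structure(list(spec = spec, X = X,
                 weights = eng$weights, loadings = eng$loadings,
                 scores = eng$scores, paths = st$paths, r2 = st$r2,
                 residuals = st$residuals, iterations = eng$iterations),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat("PLS path model fit (", x$iterations, " iterations)\n", sep = "")
  print(x$paths, row.names = FALSE)
  cat("R-squared:\n"); print(round(x$r2, 4))
  invisible(x)
}

path_beta <- function(fit, from, to) {
  i <- which(fit$paths$from == from & fit$paths$to == to)
  if (length(i) != 1) stop_arg("path ", from, " -> ", to, " not in model")
  fit$paths$beta[i]
}

#' Bootstrap inference for a PLS path model
#'
#' Resamples observations with replacement, refits the full model, and
#' summarizes path coefficients, loadings, and all two-step indirect
#' effects. p values are two-tailed normal-theory values from
#' `beta / bootstrap SE`; percentile confidence intervals are reported
#' alongside. More than 5% failed resamples is an error.
#'
#' @param spec a [pls_model_spec()].
#' @param data indicator data frame.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @param conf confidence level for percentile intervals.
#' @return object of class `pls_boot`: `fit` (observed fit), `paths` and
#'   `loadings` and `indirect` tables with `beta`/`loading`, `se`, `p`,
#'   `ci_lo`, `ci_hi`, plus `n_boot`, `n_fail`, `seed`.
#' @export
bootstrap_inference <- function(spec, data, n_boot = spec$n_boot,
                                seed = spec$seed, conf = 0.95) {
  fit <- fit_pls(spec, data)
  n <- nrow(data)
  npath <- nrow(fit$paths)
  load_obs <- unlist(fit$loadings)
  boot_paths <- matrix(NA_real_, n_boot, npath)
  boot_load <- matrix(NA_real_, n_boot, length(load_obs))
  n_fail <- 0
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      fb <- tryCatch(fit_pls(spec, data[idx, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(fb)) { n_fail <- n_fail + 1; next }
      # align on (from, to); identical ordering by construction
      boot_paths[b, ] <- fb$paths$beta
      boot_load[b, ] <- unlist(fb$loadings)
    }
  })
  if (n_fail > 0.05 * n_boot)
    stop_arg(n_fail, " of ", n_boot, " bootstrap resamples failed (> 5%)")
  a2 <- (1 - conf) / 2
  summarize <- function(obs, mat) {
    se <- apply(mat, 2, stats::sd, na.rm = TRUE)
    data.frame(se = se,
               p = 2 * stats::pnorm(-abs(obs / se)),
               ci_lo = apply(mat, 2, stats::quantile, a2, na.rm = TRUE),
               ci_hi = apply(mat, 2, stats::quantile, 1 - a2, na.rm = TRUE))
  }
  paths <- cbind(fit$paths, summarize(fit$paths$beta, boot_paths))
  lat_of <- rep(names(fit$loadings), lengths(fit$loadings))
  ind_of <- unlist(spec$blocks[names(fit$loadings)], use.names = FALSE)
  loadings <- cbind(data.frame(latent = lat_of, indicator = ind_of,
                               loading = load_obs, stringsAsFactors = FALSE),
                    summarize(load_obs, boot_load))
  # all two-step indirect effects x -> m -> y present in the path set
  ind <- NULL
  pp <- fit$paths
  for (i in seq_len(npath)) {
    for (j in seq_len(npath)) {
      if (pp$to[i] == pp$from[j]) {
        prod_obs <- pp$beta[i] * pp$beta[j]
        prod_boot <- boot_paths[, i] * boot_paths[, j]
        se <- stats::sd(prod_boot, na.rm = TRUE)
        ind <- rbind(ind, data.frame(
          from = pp$from[i], via = pp$to[i], to = pp$to[j],
          beta = prod_obs, se = se,
          p = 2 * stats::pnorm(-abs(prod_obs / se)),
          ci_lo = stats::quantile(prod_boot, a2, na.rm = TRUE),
          ci_hi = stats::quantile(prod_boot, 1 - a2, na.rm = TRUE),
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(paths) <- rownames(loadings) <- NULL
  if (!is.null(ind)) rownames(ind) <- NULL
  structure(list(fit = fit, paths = paths, loadings = loadings,
                 indirect = ind, n_boot = n_boot, n_fail = n_fail,
                 seed = seed),
            class = "pls_boot")
}

#' Extract a moderation (interaction) effect
#'
#' Moderation terms declared in the model spec enter the structural
#' regression as standardized products of latent scores; this accessor
#' returns the corresponding interaction path row.
#'
#' @param object a `pls_fit` or `pls_boot`.
#' @param moderator,predictor,target latent names of the declared
#'   moderation.
#' @return one-row data frame with the interaction coefficient (and
#'   bootstrap inference when available).
#' @export
moderation_effect <- function(object, moderator, predictor, target) {
  paths <- if (inherits(object, "pls_boot")) object$paths else object$paths
  nm <- paste0(moderator, "x", predictor)
  row <- paths[paths$from == nm & paths$to == target, , drop = FALSE]
  if (nrow(row) != 1)
    stop_arg("moderation ", nm, " -> ", target, " not in the fitted model")
  row
}

#' Mediation decomposition
#'
#' Decomposes the effect of a predictor on an outcome through a mediator:
#' indirect = a x b (predictor -> mediator times mediator -> outcome),
#' total = direct (c') + indirect, and the proportion mediated
#' (indirect / total, as a percentage) when the two agree in sign. The
#' proportion is flagged undefined when the total is (near) zero or the
#' signs disagree.
#'
#' @param object a `pls_fit` or `pls_boot`.
#' @param predictor,mediator,outcome latent names; the paths
#'   predictor -> mediator, mediator -> outcome and predictor -> outcome
#'   must all be present.
#' @return list with `a`, `b`, `direct`, `indirect`, `total`,
#'   `proportion_mediated` (percent, or `NA` with `flag`).
#' @export
mediation <- function(object, predictor, mediator, outcome) {
  fit <- if (inherits(object, "pls_boot")) object$fit else object
  a <- path_beta(fit, predictor, mediator)
  b <- path_beta(fit, mediator, outcome)
  cp <- path_beta(fit, predictor, outcome)
  indirect <- a * b
  total <- cp + indirect
  flag <- ""
  prop <- NA_real_
  if (abs(total) < 1e-8) {
    flag <- "total_near_zero"
  } else if (sign(indirect) != sign(total) && indirect != 0) {
    flag <- "inconsistent_signs"
  } else {
    prop <- 100 * indirect / total
  }
  list(a = a, b = b, direct = cp, indirect = indirect, total = total,
       proportion_mediated = prop, flag = flag)
}

#' Measurement-quality diagnostics
#'
#' Convergent validity (average variance extracted, AVE: the mean squared
#' standardized loading per block, conventionally required > 0.50),
#' composite reliability, and discriminant validity (heterotrait-monotrait
#' ratio, HTMT: mean absolute between-block indicator correlation over the
#' geometric mean of the within-block mean absolute correlations,
#' conventionally required < 0.85). Single-indicator blocks have AVE = 1
#' and enter HTMT through the indicator itself (within-block mean set
#' to 1).
#'
#' @param fit a `pls_fit`.
#' @return list with `ave` and `composite_reliability` (named per block)
#'   and `htmt` (block-by-block matrix).
#' @export
quality_diagnostics <- function(fit) {
  lat <- names(fit$spec$blocks)
  ave <- cr <- stats::setNames(numeric(length(lat)), lat)
  for (j in seq_along(lat)) {
    l <- fit$loadings[[lat[j]]]
    ave[j] <- mean(l^2)
    cr[j] <- sum(l)^2 / (sum(l)^2 + sum(1 - l^2))
  }
  R <- stats::cor(fit$X)
  mono <- stats::setNames(numeric(length(lat)), lat)
  for (j in seq_along(lat)) {
    cols <- fit$spec$blocks[[lat[j]]]
    if (length(cols) < 2) { mono[j] <- 1; next }
    rr <- abs(R[cols, cols])
    mono[j] <- mean(rr[upper.tri(rr)])
  }
  htmt <- matrix(NA_real_, length(lat), length(lat),
                 dimnames = list(lat, lat))
  for (i in seq_along(lat)) for (j in seq_along(lat)) {
    if (i >= j) next
    hetero <- mean(abs(R[fit$spec$blocks[[lat[i]]],
                         fit$spec$blocks[[lat[j]]], drop = FALSE]))
    htmt[i, j] <- htmt[j, i] <- hetero / sqrt(mono[i] * mono[j])
  }
  list(ave = ave, composite_reliability = cr, htmt = htmt)
}

#' Bayesian Information Criterion of a structural regression
#'
#' Regression BIC of the standardized structural equation for one
#' endogenous latent: `n * log(SSE / n) + (k + 1) * log(n)` where `k`
#' counts structural predictors (including interaction terms). Differences
#' between nested model fits give the usual Delta-BIC evidence scale.
#'
#' @param fit a `pls_fit`.
#' @param endogenous name of the endogenous latent.
#' @return numeric BIC value.
#' @export
model_bic <- function(fit, endogenous) {
  res <- fit$residuals[[endogenous]]
  if (is.null(res)) stop_arg(endogenous, " is not endogenous in this model")
  n <- length(res)
  k <- sum(fit$paths$to == endogenous)
  n * log(sum(res^2) / n) + (k + 1) * log(n)
}
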