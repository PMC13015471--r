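#' Configuration for the synthetic study generator
#'
#' Bundles the parameters that define a simulated closed-loop memory
#' stimulation study: atlas size, cohort composition, tractogram density and
#' zero inflation, and the planted effect structure that downstream analyses
#' are expected to recover.
#'
#' The defaults mirror the study conditions the pipeline is designed for:
#' 39 closed-loop and 22 random stimulation sessions, a negative baseline
#' memory vs. improvement correlation of -0.48 in the closed-loop arm, a
#' 12 mm stimulation sphere, and 25 lists of 12 words per session with the
#' first three lists never stimulated.
#'
#' @param n_parcels number of atlas parcels (>= 2); 60 by default, 438
#'   supported.
#' @param n_closed,n_random number of closed-loop / random-mode stimulation
#'   sessions.
#' @param streamline_density mean streamline count per connected parcel pair.
#' @param connection_sparsity fraction of parcel pairs with zero streamlines
#'   (zero inflation), in `[0, 1)`.
#' @param effect_sc_memory planted rank correlation between a site's
#'   structure-function congruence (Dice at the representative thresholds)
#'   and memory change, closed-loop arm only.
#' @param effect_baseline planted correlation between baseline recall and
#'   memory change, closed-loop arm only.
#' @param effect_wmp_sc planted correlation between white-matter proximity
#'   and total structural connectivity of the site (negative: sites closer
#'   to white matter are better connected).
#' @param noise_sd scale (SD, percentage points) of the latent memory-change
#'   distribution around its planted mean.
#' @param delta_mean mean planted memory change (%) in the closed-loop arm.
#' @param n_lists,words_per_list,n_baseline_lists free-recall task structure:
#'   lists per session, words per list, and leading never-stimulated lists.
#' @param radius_mm stimulation sphere radius.
#' @param seed base integer seed; every generator derives its stream from it.
#'
#' @return an object of class `synth_config` (a validated list).
#' @export
#' @examples
#' cfg <- synth_config(n_parcels = 20, n_closed = 10, n_random = 6)
synth_config <- function(n_parcels = 60, n_closed = 39, n_random = 22,
                         streamline_density = 5, connection_sparsity = 0.5,
                         effect_sc_memory = 0.6, effect_baseline = -0.48,
                         effect_wmp_sc = -0.4, noise_sd = 20,
                         delta_mean = 12.4,
                         n_lists = 25, words_per_list = 12,
                         n_baseline_lists = 3,
                         radius_mm = 12, seed = 1L) {
  counts <- c(n_parcels = n_parcels, n_closed = n_closed, n_random = n_random,
              n_lists = n_lists, words_per_list = words_per_list)
  if (any(counts < 1) || any(counts != round(counts)))
    stop_arg("all counts must be integers >= 1")
  if (n_parcels < 2) stop_arg("n_parcels must be >= 2")
  if (connection_sparsity < 0 || connection_sparsity >= 1)
    stop_arg("connection_sparsity must lie in [0, 1)")
  for (rho in c(effect_sc_memory, effect_baseline, effect_wmp_sc))
    if (abs(rho) >= 1) stop_arg("planted correlations must lie in (-1, 1)")
  if (noise_sd <= 0) stop_arg("noise_sd must be positive")
  if (radius_mm <= 0) stop_arg("radius_mm must be positive")
  if (n_baseline_lists < 0 || n_baseline_lists >= n_lists - 1)
    stop_arg("n_baseline_lists must leave at least two usable lists")
  structure(list(
    n_parcels = as.integer(n_parcels), n_closed = as.integer(n_closed),
    n_random = as.integer(n_random),
    streamline_density = streamline_density,
    connection_sparsity = connection_sparsity,
    effect_sc_memory = effect_sc_memory, effect_baseline = effect_baseline,
    effect_wmp_sc = effect_wmp_sc, noise_sd = noise_sd,
    delta_mean = delta_mean, n_lists = as.integer(n_lists),
    words_per_list = as.integer(words_per_list),
    n_baseline_lists = as.integer(n_baseline_lists),
    radius_mm = radius_mm, seed = as.integer(seed)
  ), class = "synth_config")
}

#' Generate a synthetic parcel atlas
#'
#' Draws parcel centroids uniformly inside a brain-sized bounding box with a
#' guaranteed minimum pairwise separation, and labels hemispheres by the sign
#' of the x coordinate. Deterministic given `seed`.
#'
#' @param n_parcels number of parcels (>= 2).
#' @param seed integer seed.
#' @param box_mm box half-extents (mm) along x, y, z; centroids are drawn in
#'   `[-box, +box]` per axis.
#' @param min_separation minimum pairwise centroid distance (mm).
#' @return a `parcel_atlas` data frame with columns `id`, `name`, `x`, `y`,
#'   `z`, `hemisphere`.
#' @export
generate_atlas <- function(n_parcels, seed,
                           box_mm = c(70, 55, 45), min_separation = 8) {
  if (n_parcels < 2) stop_arg("n_parcels must be >= 2")
  pts <- with_seed(seed, {
    out <- matrix(NA_real_, n_parcels, 3)
    k <- 0; tries <- 0
    while (k < n_parcels) {
      cand <- stats::runif(3, -box_mm, box_mm)
      ok <- k == 0 ||
        min(sqrt(colSums((t(out[seq_len(k), , drop = FALSE]) - cand)^2))) >=
          min_separation
      if (ok) { k <- k + 1; out[k, ] <- cand }
      tries <- tries + 1
      if (tries > 200 * n_parcels)
        stop_arg("could not place parcels at the requested separation")
    }
    out
  })
  atlas <- data.frame(
    id = seq_len(n_parcels),
    name = sprintf("P%03d", seq_len(n_parcels)),
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    hemisphere = ifelse(pts[, 1] < 0, "L", "R"),
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("parcel_atlas", "data.frame")
  atlas
}

#' Construct a tractogram object
#'
#' A tractogram is a set of streamlines (3-D polylines, coordinates in mm)
#' each labeled with the pair of atlas parcels its endpoints belong to. A
#' flattened segment table is precomputed for fast sphere intersection.
#'
#' @param parcel_a,parcel_b integer endpoint parcel ids, one per streamline.
#' @param vertices list of numeric matrices (>= 2 rows, 3 columns), one per
#'   streamline.
#' @param n_parcels number of parcels in the reference atlas.
#' @return an object of class `tractogram`.
#' @export
tractogram <- function(parcel_a, parcel_b, vertices, n_parcels) {
  n <- length(vertices)
  if (length(parcel_a) != n || length(parcel_b) != n)
    stop_arg("parcel labels and vertex list must have equal length")
  nv <- vapply(vertices, nrow, integer(1))
  if (any(nv < 2)) stop_arg("every streamline needs at least 2 vertices")
  if (!all(vapply(vertices, function(v) all(is.finite(v)), logical(1))))
    stop_arg("streamline vertices must be finite")
  ids <- c(parcel_a, parcel_b)
  if (any(ids < 1 | ids > n_parcels))
    stop_arg("endpoint parcel ids must be valid atlas ids")
  # segment table: one row per polyline segment, with owning streamline id
  starts <- do.call(rbind, lapply(vertices, function(v) v[-nrow(v), , drop = FALSE]))
  ends   <- do.call(rbind, lapply(vertices, function(v) v[-1, , drop = FALSE]))
  sid    <- rep.int(seq_len(n), nv - 1L)
  structure(list(parcel_a = as.integer(parcel_a),
                 parcel_b = as.integer(parcel_b),
                 vertices = vertices,
                 seg_start = starts, seg_end = ends, seg_stream = sid,
                 n_parcels = as.integer(n_parcels)),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  cat(sprintf("tractogram: %d streamlines, %d-parcel atlas\n",
              length(x$vertices), x$n_parcels))
  invisible(x)
}

#' Generate a synthetic normative tractogram
#'
#' For each unordered parcel pair a streamline count is drawn from a
#' zero-inflated, right-skewed distribution (zero with probability
#' `connection_sparsity`, otherwise shifted geometric with mean
#' `streamline_density`). Each streamline is a quadratic Bezier polyline
#' between jittered endpoint centroids with one random control point, so
#' streamlines are curved and sphere intersection is non-trivial.
#'
#' @param atlas a `parcel_atlas`.
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @param n_vertices vertices per streamline (>= 8).
#' @param endpoint_jitter,control_jitter SD (mm) of endpoint and mid-course
#'   control-point displacement.
#' @return a [tractogram()].
#' @export
generate_tractogram <- function(atlas, config, seed, n_vertices = 9,
                                endpoint_jitter = 2, control_jitter = 10) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  if (n_vertices < 8) stop_arg("n_vertices must be >= 8")
  np <- nrow(atlas)
  cent <- as.matrix(atlas[, c("x", "y", "z")])
  pr <- utils::combn(np, 2)
  with_seed(seed, {
    connected <- stats::runif(ncol(pr)) >= config$connection_sparsity
    counts <- integer(ncol(pr))
    p_geom <- 1 / max(config$streamline_density, 1)
    counts[connected] <- 1L + stats::rgeom(sum(connected), p_geom)
    a <- rep.int(pr[1, ], counts)
    b <- rep.int(pr[2, ], counts)
    ns <- length(a)
    if (ns == 0) {
      tractogram(integer(0), integer(0), list(), np)
    } else {
      p0 <- cent[a, , drop = FALSE] +
        matrix(stats::rnorm(3 * ns, 0, endpoint_jitter), ns)
      p1 <- cent[b, , drop = FALSE] +
        matrix(stats::rnorm(3 * ns, 0, endpoint_jitter), ns)
      ctrl <- (p0 + p1) / 2 + matrix(stats::rnorm(3 * ns, 0, control_jitter), ns)
      tt <- seq(0, 1, length.out = n_vertices)
      verts <- lapply(seq_len(ns), function(i) {
        v <- outer((1 - tt)^2, p0[i, ]) + outer(2 * tt * (1 - tt), ctrl[i, ]) +
          outer(tt^2, p1[i, ])
        dimnames(v) <- NULL
        v
      })
      tractogram(a, b, verts, np)
    }
  })
}

#' Generate a synthetic encoding-network weight map
#'
#' Emulates a group-level verbal-encoding activation pattern parcellated to
#' the atlas: `n_core` randomly chosen parcels receive high positive weights,
#' the remainder small zero-centered weights.
#'
#' @param atlas a `parcel_atlas`.
#' @param n_core number of strongly activated core parcels.
#' @param seed integer seed.
#' @return named numeric vector of parcel weights (names = parcel ids).
#' @export
generate_encoding_network <- function(atlas, n_core = NULL, seed = 1L) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  np <- nrow(atlas)
  if (is.null(n_core)) n_core <- max(2L, round(0.15 * np))
  if (n_core < 1 || n_core > np)
    stop_arg("n_core must lie in [1, n_parcels]")
  with_seed(seed, {
    w <- stats::rnorm(np, 0, 0.3)
    core <- sample.int(np, n_core)
    w[core] <- stats::rnorm(n_core, 3, 0.4)
    names(w) <- atlas$id
    attr(w, "core") <- sort(core)
    w
  })
}

#' Generate synthetic task time series
#'
#' Produces per-subject parcel-by-time matrices: a shared task-block boxcar
#' regressor loaded onto the positively weighted encoding-network parcels,
#' plus spatially correlated Gaussian noise whose covariance decays
#' exponentially with inter-centroid distance. Each parcel's series is
#' standardized.
#'
#' @param atlas a `parcel_atlas`.
#' @param n_subjects number of subjects.
#' @param n_timepoints time points per subject (>= 20).
#' @param encoding_weights optional parcel weight vector; positive weights
#'   set the task loading. `NULL` means no task signal.
#' @param task_amplitude loading of the task regressor on the strongest
#'   encoding parcel (noise has unit SD).
#' @param block_len task block half-period in time points (on/off boxcar).
#' @param noise_range spatial correlation length (mm) of the noise;
#'   `0` gives independent noise.
#' @param seed integer seed.
#' @return list of `n_subjects` matrices (`n_parcels` x `n_timepoints`),
#'   rownames = parcel ids.
#' @export
generate_timeseries <- function(atlas, n_subjects, n_timepoints,
                                encoding_weights = NULL, task_amplitude = 0.8,
                                block_len = 25, noise_range = 120, seed = 1L) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  if (n_timepoints < 20) stop_arg("n_timepoints must be >= 20")
  np <- nrow(atlas)
  lam <- numeric(np)
  if (!is.null(encoding_weights)) {
    pos <- pmax(as.numeric(encoding_weights), 0)
    if (max(pos) > 0) lam <- task_amplitude * pos / max(pos)
  }
  task <- rep_len(rep(c(1, 0), each = block_len), n_timepoints)
  task <- as.numeric(scale(task))
  chol_L <- NULL
  if (noise_range > 0) {
    d <- as.matrix(stats::dist(atlas[, c("x", "y", "z")]))
    chol_L <- chol(exp(-d / noise_range) + diag(1e-8, np))
  }
  with_seed(seed, {
    out <- lapply(seq_len(n_subjects), function(s) {
      noise <- matrix(stats::rnorm(np * n_timepoints), np, n_timepoints)
      if (!is.null(chol_L)) noise <- crossprod(chol_L, noise)
      x <- outer(lam, task) + noise
      x <- t(scale(t(x)))
      rownames(x) <- atlas$id
      x
    })
    names(out) <- sprintf("subj%02d", seq_len(n_subjects))
    out
  })
}

# Planted-effect plan: latent-scale copula coefficients that deliver the
# requested *observed* correlations once binomial recall noise and the
# shared-denominator bias of the percent-change score are taken into account.
# Returns list(a, b) for Z = a*U_dice + b*U_baseline + sqrt(1-a^2-b^2)*eps.
plan_planted_effects <- function(config, p_bar = 0.30, sigma_p = 0.08) {
  w <- config$words_per_list
  L_elig <- config$n_lists - config$n_baseline_lists
  L_s <- L_elig %/% 2L
  L_ns <- L_elig - L_s
  pq <- p_bar * (1 - p_bar)
  var_rs <- pq / (w * L_s)           # recall-fraction sampling variances
  var_rns <- pq / (w * L_ns)
  sd_meas <- (100 / p_bar) * sqrt(var_rs + var_rns)
  sd_obs <- sqrt(config$noise_sd^2 + sd_meas^2)
  atten <- config$noise_sd / sd_obs
  reliab_base <- sigma_p / sqrt(sigma_p^2 + var_rns)
  # R_NS appears in the denominator of the change score, inducing a negative
  # baseline-change correlation even with nothing planted; plant only the
  # remainder.
  cov_bias <- -(100^2) * var_rns / p_bar
  sd_rns_obs <- 100 * sqrt(sigma_p^2 + var_rns)
  corr_bias <- cov_bias / (sd_rns_obs * sd_obs)
  # Pearson latent correlation giving the requested Spearman on the output
  a <- 2 * sin(pi * config$effect_sc_memory / 6) / atten
  b <- (config$effect_baseline - corr_bias) / (reliab_base * atten)
  if (a^2 + b^2 >= 1)
    stop_arg("infeasible planted-correlation combination: requested ",
             "effect_sc_memory/effect_baseline too strong for noise_sd = ",
             config$noise_sd)
  list(a = a, b = b, p_bar = p_bar, sigma_p = sigma_p)
}

#' Generate stimulation sites with structural profiles
#'
#' Places one stimulation sphere per session near a randomly chosen parcel
#' centroid, computes its cumulative ChaCo profile against the tractogram,
#' its Dice congruence with the encoding network at the representative
#' thresholds (top 30% of positive weights; cumulative score > 1), and a
#' white-matter-proximity value correlated (negatively, by default) with the
#' site's total structural connectivity.
#'
#' @param atlas a `parcel_atlas`.
#' @param tract a [tractogram()].
#' @param encoding_weights parcel weight vector from
#'   [generate_encoding_network()].
#' @param config a [synth_config()].
#' @param seed integer seed (defaults to `config$seed + 1`).
#' @return a data frame of sites (`site_id`, `subject_id`, `x`, `y`, `z`,
#'   `radius_mm`, `mode`, `wmp_mm`, `congruence`, `total_sc`) with the
#'   sites-by-parcels cumulative ChaCo matrix in attribute `sc_profiles`.
#' @export
generate_sites <- function(atlas, tract, encoding_weights, config,
                           seed = config$seed + 1L) {
  stopifnot(inherits(atlas, "parcel_atlas"), inherits(tract, "tractogram"))
  n <- config$n_closed + config$n_random
  np <- nrow(atlas)
  cent <- as.matrix(atlas[, c("x", "y", "z")])
  with_seed(seed, {
    idx <- sample.int(np, n, replace = TRUE)
    centers <- cent[idx, , drop = FALSE] +
      matrix(stats::rnorm(3 * n, 0, 3), n)
    net_mask <- threshold_network(encoding_weights, 0.3)
    prof <- matrix(0, n, np, dimnames = list(NULL, atlas$id))
    cong <- numeric(n)
    for (i in seq_len(n)) {
      pw <- pairwise_chaco(tract, centers[i, ], config$radius_mm)
      cum <- cumulative_chaco(pw, atlas)
      prof[i, ] <- cum
      cong[i] <- dice(net_mask, threshold_sc(cum, 1))
    }
    total_sc <- rowSums(prof)
    rho_w <- config$effect_wmp_sc
    u_s <- normal_scores(total_sc)
    lat <- rho_w * u_s + sqrt(1 - rho_w^2) * stats::rnorm(n)
    wmp <- stats::qgamma(stats::pnorm(lat), shape = 4, scale = 1.25)
    sites <- data.frame(
      site_id = sprintf("site%03d", seq_len(n)),
      subject_id = sprintf("subj%03d", seq_len(n)),
      x = centers[, 1], y = centers[, 2], z = centers[, 3],
      radius_mm = config$radius_mm,
      mode = rep(c("closed", "random"), c(config$n_closed, config$n_random)),
      wmp_mm = wmp,
      congruence = cong,
      total_sc = total_sc,
      stringsAsFactors = FALSE
    )
    attr(sites, "sc_profiles") <- prof
    sites
  })
}

#' Generate per-session list-level recall records
#'
#' Simulates the free-recall task for each site: per-list Bernoulli recall at
#' `words_per_list` words over `n_lists` lists, the first `n_baseline_lists`
#' never stimulated and half of the remaining lists stimulated. In the
#' closed-loop arm the latent memory-change of a site is coupled, through a
#' Gaussian copula, to its structure-function congruence (rank correlation
#' `effect_sc_memory`) and to baseline recall (`effect_baseline`); in the
#' random arm memory change is pure noise around zero. The copula
#' coefficients are pre-compensated for binomial measurement noise so the
#' planted values are recovered on the observed scale; an infeasible
#' combination raises an error. Every generated session satisfies the
#' baseline-recall inclusion rule (>= 1 word per list on average) by
#' construction.
#'
#' @param sites data frame from [generate_sites()] (needs `mode` and
#'   `congruence`).
#' @param config a [synth_config()].
#' @param seed integer seed (defaults to `config$seed + 2`).
#' @return a sessions data frame (`site_id`, `list_index`,
#'   `stimulated_flag`, `n_words`, `n_recalled`) with the generating latents
#'   in attribute `truth`.
#' @export
generate_behavior <- function(sites, config, seed = config$seed + 2L) {
  plan <- plan_planted_effects(config)
  n <- nrow(sites)
  closed <- sites$mode == "closed"
  w <- config$words_per_list
  L <- config$n_lists
  nb <- config$n_baseline_lists
  L_elig <- L - nb
  L_s <- L_elig %/% 2L
  with_seed(seed, {
    u_b <- stats::rnorm(n)
    delta_t <- numeric(n)
    if (any(closed)) {
      u_d <- normal_scores(sites$congruence[closed])
      a <- plan$a; b <- plan$b
      z <- a * u_d + b * u_b[closed] +
        sqrt(1 - a^2 - b^2) * stats::rnorm(sum(closed))
      delta_t[closed] <- config$delta_mean + config$noise_sd * z
    }
    delta_t[!closed] <- config$noise_sd * stats::rnorm(sum(!closed))
    p_base <- clip(plan$p_bar + plan$sigma_p * u_b, 0.15, 0.80)
    p_stim <- clip(p_base * (1 + delta_t / 100), 0.02, 0.95)

    out <- vector("list", n)
    for (i in seq_len(n)) {
      stim <- c(rep(FALSE, nb),
                sample(rep(c(TRUE, FALSE), c(L_s, L_elig - L_s))))
      p_list <- ifelse(stim, p_stim[i], p_base[i])
      elig_ns <- !stim & seq_len(L) > nb
      # redraw until the baseline inclusion rule holds by construction
      for (try in 1:200) {
        rec <- stats::rbinom(L, w, p_list)
        if (mean(rec[elig_ns]) / w >= 1 / w) break
      }
      out[[i]] <- data.frame(site_id = sites$site_id[i],
                             list_index = seq_len(L),
                             stimulated_flag = stim,
                             n_words = w, n_recalled = rec,
                             stringsAsFactors = FALSE)
    }
    sessions <- do.call(rbind, out)
    rownames(sessions) <- NULL
    attr(sessions, "truth") <- list(delta_target = delta_t, p_base = p_base,
                                    copula = plan)
    sessions
  })
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper: [generate_sites()] followed by
#' [generate_behavior()], both seeded from `config$seed`.
#'
#' @inheritParams generate_sites
#' @return `list(sites = <data frame>, sessions = <data frame>)`.
#' @export
generate_cohort <- function(atlas, tract, encoding_weights, config) {
  sites <- generate_sites(atlas, tract, encoding_weights, config)
  sessions <- generate_behavior(sites, config)
  list(sites = sites, sessions = sessions)
}
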