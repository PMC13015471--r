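# Minimum average baseline recall (in %) required for inclusion:
# one word out of twelve per list.
MIN_BASELINE_PCT <- 100 / 12

#' Stimulation-related memory change per site
#'
#' For each site the percent memory change is
#' \deqn{\Delta = (R_S - R_{NS}) / R_{NS} \times 100}
#' where \eqn{R_S} is average recall (%) over stimulated lists and
#' \eqn{R_{NS}} average recall over non-stimulated lists, excluding the
#' first three lists of the session (always non-stimulated, used for
#' classifier normalization, and therefore a temporal-order confound).
#' Sites with \eqn{R_{NS}} below 8.33% (one word per twelve-word list) are
#' excluded with an explicit exclusion code.
#'
#' @param sessions data frame with columns `site_id`, `list_index`,
#'   `stimulated_flag`, `n_words`, `n_recalled` (and optionally `mode`).
#' @param sites optional sites data frame; if given, `mode` is joined onto
#'   the result.
#' @param n_excluded_lists number of leading lists dropped from the
#'   baseline (default 3).
#' @return data frame `site_id`, `mode` (if available), `r_ns`, `r_s`,
#'   `delta`, `included`, `exclusion_code` (`""` or `"low_baseline"`).
#' @export
memory_change <- function(sessions, sites = NULL, n_excluded_lists = 3) {
  need <- c("site_id", "list_index", "stimulated_flag", "n_words", "n_recalled")
  if (!all(need %in% names(sessions)))
    stop_arg("sessions must have columns: ", paste(need, collapse = ", "))
  if (any(sessions$n_recalled < 0 | sessions$n_recalled > sessions$n_words))
    stop_arg("n_recalled must lie in [0, n_words]")
  out <- lapply(split(sessions, sessions$site_id), function(s) {
    s <- s[order(s$list_index), , drop = FALSE]
    frac <- s$n_recalled / s$n_words
    stim <- s$stimulated_flag
    elig_ns <- !stim & s$list_index > n_excluded_lists
    if (!any(stim) || !any(elig_ns))
      stop_arg("site ", s$site_id[1],
               ": need >= 1 stimulated and >= 1 eligible baseline list")
    r_s <- 100 * mean(frac[stim])
    r_ns <- 100 * mean(frac[elig_ns])
    # tolerance so a session at exactly one word per list is included
    excluded <- r_ns < MIN_BASELINE_PCT - 1e-9
    data.frame(site_id = s$site_id[1],
               r_ns = r_ns, r_s = r_s,
               delta = if (excluded || r_ns == 0) NA_real_
                       else (r_s - r_ns) / r_ns * 100,
               included = !excluded,
               exclusion_code = if (excluded) "low_baseline" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (!is.null(sites) && "mode" %in% names(sites))
    out$mode <- sites$mode[match(out$site_id, sites$site_id)]
  out[order(out$site_id), , drop = FALSE]
}

#' One-sample t test of memory-change scores
#'
#' @param deltas numeric vector (n >= 2, non-constant).
#' @return list with `t`, `df`, `p` (two-tailed), `mean`, `sem`.
#' @export
one_sample_t <- function(deltas) {
  deltas <- deltas[is.finite(deltas)]
  n <- length(deltas)
  if (n < 2) stop_arg("need n >= 2 finite values")
  if (stats::sd(deltas) == 0) stop_arg("zero variance: t undefined")
  sem <- stats::sd(deltas) / sqrt(n)
  t <- mean(deltas) / sem
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1),
       mean = mean(deltas), sem = sem)
}

#' One-sample t statistic from a printed mean and SEM
#'
#' Worked-example arithmetic for published group summaries: `t = mean/sem`,
#' with the two-tailed p from the t distribution at the given df.
#'
#' @param mean,sem group mean and standard error of the mean.
#' @param df degrees of freedom (n - 1).
#' @return list with `t`, `df`, `p`.
#' @export
t_from_summary <- function(mean, sem, df) {
  if (sem <= 0) stop_arg("sem must be positive")
  t <- mean / sem
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Two-sample t test
#'
#' Welch's unequal-variance test by default; the pooled-variance test is
#' available for reproducing published tables whose degrees of freedom imply
#' pooling.
#'
#' @param a,b numeric vectors.
#' @param pooled use the pooled-variance (classical) test.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b, pooled = FALSE) {
  ht <- stats::t.test(a, b, var.equal = pooled)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Stratify sites by baseline memory
#'
#' Splits memory outcomes at a baseline-recall threshold (default 30%,
#' the cohort mean). A baseline exactly at the threshold is assigned to the
#' high group (conservative, since the low group is the one expected to
#' benefit).
#'
#' @param outcomes data frame from [memory_change()] (needs `r_ns`).
#' @param threshold baseline recall threshold in %.
#' @return list with `low` and `high` subsets of `outcomes`.
#' @export
stratify_baseline <- function(outcomes, threshold = 30) {
  if (nrow(outcomes) == 0) stop_arg("outcomes is empty")
  low <- outcomes$r_ns < threshold
  list(low = outcomes[low, , drop = FALSE],
       high = outcomes[!low, , drop = FALSE])
}

check_corr_input <- function(x, y) {
  if (length(x) != length(y)) stop_arg("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop_arg("need n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_arg("constant input: correlation undefined")
  list(x = x, y = y)
}

#' Correlation coefficients with two-tailed p values
#'
#' Thin wrappers with consistent input checking. `kendall_tau_b()` uses the
#' tie-corrected tau-b denominator, appropriate for zero-inflated structural
#' connectivity values; p values for tied data use the normal approximation.
#'
#' @param x,y numeric vectors (n >= 3, non-constant after removing
#'   non-finite pairs).
#' @return list with `estimate`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  d <- check_corr_input(x, y)
  ht <- stats::cor.test(d$x, d$y, method = "pearson")
  list(estimate = unname(ht$estimate), p = ht$p.value, n = length(d$x))
}

#' @rdname pearson_r
#' @export
spearman_rho <- function(x, y) {
  d <- check_corr_input(x, y)
  ht <- suppressWarnings(stats::cor.test(d$x, d$y, method = "spearman"))
  list(estimate = unname(ht$estimate), p = ht$p.value, n = length(d$x))
}

#' @rdname pearson_r
#' @export
kendall_tau_b <- function(x, y) {
  d <- check_corr_input(x, y)
  ht <- suppressWarnings(stats::cor.test(d$x, d$y, method = "kendall"))
  list(estimate = unname(ht$estimate), p = ht$p.value, n = length(d$x))
}
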