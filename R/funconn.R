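#' Seed time series of a stimulation site
#'
#' Unweighted mean of the time series of all parcels whose centroid lies
#' inside the stimulation sphere; if no centroid falls inside, the nearest
#' parcel's series is used.
#'
#' @param site one row of a sites data frame (`x`, `y`, `z`, `radius_mm`).
#' @param atlas a `parcel_atlas`.
#' @param ts parcel-by-time numeric matrix for one subject.
#' @return numeric time vector, with attribute `parcels` naming the parcels
#'   averaged.
#' @export
site_timeseries <- function(site, atlas, ts) {
  if (is.null(dim(ts)) || ncol(ts) < 1 || nrow(ts) != nrow(atlas))
    stop_arg("ts must be a parcels x timepoints matrix matching the atlas")
  cent <- as.matrix(atlas[, c("x", "y", "z")])
  d <- sqrt(colSums((t(cent) - c(site$x, site$y, site$z))^2))
  inside <- which(d <= site$radius_mm)
  if (length(inside) == 0) inside <- which.min(d)
  out <- colMeans(ts[inside, , drop = FALSE])
  attr(out, "parcels") <- atlas$id[inside]
  out
}

#' Seed-based functional connectivity profile (one subject)
#'
#' Pearson correlation between the site's seed series and every parcel's
#' series (self-parcels included). Zero-variance parcel series yield r = 0
#' and are flagged.
#'
#' @inheritParams site_timeseries
#' @return object of class `fc_profile`: list with `site_id`, `r` (named
#'   numeric vector), `flagged` (parcel ids with undefined correlation).
#' @export
seed_fc <- function(site, atlas, ts) {
  if (ncol(ts) < 3) stop_arg("need >= 3 timepoints")
  seed <- site_timeseries(site, atlas, ts)
  sds <- apply(ts, 1, stats::sd)
  r <- numeric(nrow(ts))
  ok <- sds > 0 & stats::sd(seed) > 0
  if (any(ok))
    r[ok] <- as.numeric(stats::cor(seed, t(ts[ok, , drop = FALSE])))
  flagged <- atlas$id[!ok]
  if (length(flagged) > 0)
    warning("zero-variance series: r set to 0 for ",
            length(flagged), " parcel(s)")
  names(r) <- atlas$id
  structure(list(site_id = site$site_id %||% NA_character_, r = r,
                 flagged = flagged),
            class = "fc_profile")
}

#' Normative functional connectivity profile of a site
#'
#' Element-wise mean of per-subject seed correlation maps. Raw r values are
#' averaged by default, matching plain averaging of subject maps; Fisher-z
#' averaging (mean of atanh(r), back-transformed) is available as an option.
#'
#' @param site one row of a sites data frame.
#' @param atlas a `parcel_atlas`.
#' @param ts_list list of parcel-by-time matrices, one per subject.
#' @param fisher_z average on the Fisher-z scale instead of raw r.
#' @return an `fc_profile` with the averaged map.
#' @export
normative_fc <- function(site, atlas, ts_list, fisher_z = FALSE) {
  if (length(ts_list) < 1) stop_arg("need >= 1 subject")
  maps <- lapply(ts_list, function(ts) seed_fc(site, atlas, ts)$r)
  m <- do.call(rbind, maps)
  r <- if (fisher_z) {
    z <- atanh(clip(m, -1 + 1e-12, 1 - 1e-12))
    tanh(colMeans(z))
  } else {
    colMeans(m)
  }
  names(r) <- atlas$id
  structure(list(site_id = site$site_id %||% NA_character_, r = r,
                 flagged = character(0)),
            class = "fc_profile")
}
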