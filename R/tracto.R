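#' Does a streamline intersect a sphere?
#'
#' Exact segment-wise test: the polyline intersects the sphere iff the
#' minimum point-to-segment distance from the sphere center to any of its
#' segments is at most the radius. This is a resolution-free geometric
#' analogue of voxelized mask intersection.
#'
#' @param vertices numeric matrix of ordered 3-D vertices (mm), >= 2 rows.
#' @param center sphere center, length-3 numeric.
#' @param radius sphere radius (mm), > 0.
#' @return logical scalar.
#' @export
#' @examples
#' v <- rbind(c(-10, 0, 0), c(10, 0, 0))
#' streamline_intersects_sphere(v, c(0, 0, 0), 5)
streamline_intersects_sphere <- function(vertices, center, radius) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2) stop_arg("invalid streamline: need >= 2 vertices")
  if (radius <= 0) stop_arg("radius must be > 0")
  s <- vertices[-nrow(vertices), , drop = FALSE]
  e <- vertices[-1, , drop = FALSE]
  min_segment_dist2(s, e, center) <= radius^2
}

# Squared point-to-segment distances for a block of segments; returns the
# minimum over the block.
min_segment_dist2 <- function(s, e, center) {
  d <- e - s
  w <- sweep(s, 2, center)
  dd <- rowSums(d * d)
  t_par <- ifelse(dd > 0, -rowSums(w * d) / dd, 0)
  t_par <- clip(t_par, 0, 1)
  p <- w + d * t_par
  min(rowSums(p * p))
}

# Per-streamline hit flags for a whole tractogram against one sphere.
# Vectorized over the precomputed segment table.
streamline_hits <- function(tract, center, radius) {
  if (length(tract$vertices) == 0) return(logical(0))
  s <- tract$seg_start; e <- tract$seg_end
  d <- e - s
  w <- sweep(s, 2, as.numeric(center))
  dd <- rowSums(d * d)
  t_par <- ifelse(dd > 0, -rowSums(w * d) / dd, 0)
  t_par <- clip(t_par, 0, 1)
  p <- w + d * t_par
  seg_hit <- rowSums(p * p) <= radius^2
  hits <- logical(length(tract$vertices))
  if (any(seg_hit))
    hits[unique(tract$seg_stream[seg_hit])] <- TRUE
  hits
}

#' Pairwise ChaCo ratios of a stimulation sphere
#'
#' For every parcel pair connected by at least one streamline, the ChaCo
#' (Change in Connectivity) ratio is the proportion of that pair's
#' streamlines that intersect the stimulation sphere. Pairs with no
#' streamlines have ratio zero by convention and are omitted from the table;
#' [cumulative_chaco()] restores the full parcel universe. The zero-inflated
#' distribution this convention creates is why downstream association maps
#' default to Kendall's tau-b.
#'
#' @param tract a [tractogram()].
#' @param center sphere center (mm), length-3.
#' @param radius sphere radius (mm).
#' @return data frame `parcel_a`, `parcel_b` (a < b), `n_total`, `n_hit`,
#'   `ratio`, with attribute `n_parcels`.
#' @export
pairwise_chaco <- function(tract, center, radius) {
  stopifnot(inherits(tract, "tractogram"))
  if (length(tract$vertices) == 0) stop_arg("tractogram is empty")
  hits <- streamline_hits(tract, center, radius)
  a <- pmin(tract$parcel_a, tract$parcel_b)
  b <- pmax(tract$parcel_a, tract$parcel_b)
  key <- paste(a, b)
  n_total <- tapply(hits, key, length)
  n_hit <- tapply(hits, key, sum)
  ab <- do.call(rbind, strsplit(names(n_total), " ", fixed = TRUE))
  out <- data.frame(parcel_a = as.integer(ab[, 1]),
                    parcel_b = as.integer(ab[, 2]),
                    n_total = as.integer(n_total),
                    n_hit = as.integer(n_hit),
                    ratio = as.numeric(n_hit / n_total))
  out <- out[order(out$parcel_a, out$parcel_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_parcels") <- tract$n_parcels
  out
}

#' Cumulative ChaCo score per parcel
#'
#' Sums each parcel's pairwise ChaCo ratios over all partner parcels. Values
#' are non-negative and may exceed 1 (a parcel can have many partners).
#'
#' @param pairwise pairwise table from [pairwise_chaco()] (or with the same
#'   columns, plus the full set of zero pairs implied).
#' @param atlas a `parcel_atlas` defining the parcel universe.
#' @return named numeric vector, one score per parcel (names = ids).
#' @export
cumulative_chaco <- function(pairwise, atlas) {
  np <- nrow(atlas)
  cum <- numeric(np)
  if (nrow(pairwise) > 0) {
    add_a <- tapply(pairwise$ratio, pairwise$parcel_a, sum)
    add_b <- tapply(pairwise$ratio, pairwise$parcel_b, sum)
    cum[as.integer(names(add_a))] <- cum[as.integer(names(add_a))] + add_a
    cum[as.integer(names(add_b))] <- cum[as.integer(names(add_b))] + add_b
  }
  names(cum) <- atlas$id
  cum
}

#' ChaCo profile of a stimulation site
#'
#' Convenience wrapper computing both the pairwise table and the cumulative
#' score vector for one site.
#'
#' @param tract a [tractogram()].
#' @param site one row of a sites data frame (needs `x`, `y`, `z`,
#'   `radius_mm`, and optionally `site_id`).
#' @param atlas a `parcel_atlas`.
#' @return object of class `chaco_profile`: list with `site_id`, `pairwise`,
#'   `cumulative`.
#' @export
chaco_profile <- function(tract, site, atlas) {
  pw <- pairwise_chaco(tract, c(site$x, site$y, site$z), site$radius_mm)
  structure(list(site_id = site$site_id %||% NA_character_,
                 pairwise = pw,
                 cumulative = cumulative_chaco(pw, atlas)),
            class = "chaco_profile")
}

#' Average ChaCo profiles across normative subjects
#'
#' Element-wise mean of pairwise ratios across profiles of the same site
#' computed against different tractograms (one per normative subject); the
#' cumulative scores are recomputed from the averaged pairwise table. Pairs
#' absent from a profile contribute ratio 0 for that profile.
#'
#' @param profiles list of `chaco_profile` objects on the same atlas.
#' @param atlas a `parcel_atlas`.
#' @return a `chaco_profile` with averaged ratios.
#' @export
normative_average <- function(profiles, atlas) {
  if (length(profiles) < 1) stop_arg("need at least one profile")
  sizes <- vapply(profiles, function(p) length(p$cumulative), integer(1))
  if (length(unique(sizes)) != 1 || sizes[1] != nrow(atlas))
    stop_arg("profiles computed against mismatched atlases")
  k <- length(profiles)
  acc <- new.env(parent = emptyenv())
  for (p in profiles) {
    pw <- p$pairwise
    keys <- paste(pw$parcel_a, pw$parcel_b)
    for (j in seq_along(keys)) {
      prev <- acc[[keys[j]]] %||% c(0, 0, 0)
      acc[[keys[j]]] <- prev + c(pw$ratio[j], pw$n_total[j], pw$n_hit[j])
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0) {
    avg <- data.frame(parcel_a = integer(0), parcel_b = integer(0),
                      n_total = integer(0), n_hit = integer(0),
                      ratio = numeric(0))
  } else {
    ab <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
    vals <- t(vapply(keys, function(k2) acc[[k2]], numeric(3)))
    avg <- data.frame(parcel_a = as.integer(ab[, 1]),
                      parcel_b = as.integer(ab[, 2]),
                      n_total = as.integer(vals[, 2]),
                      n_hit = as.integer(vals[, 3]),
                      ratio = vals[, 1] / k)
    avg <- avg[order(avg$parcel_a, avg$parcel_b), , drop = FALSE]
    rownames(avg) <- NULL
  }
  attr(avg, "n_parcels") <- nrow(atlas)
  structure(list(site_id = profiles[[1]]$site_id,
                 pairwise = avg,
                 cumulative = cumulative_chaco(avg, atlas)),
            class = "chaco_profile")
}
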