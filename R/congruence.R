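#' Binary encoding-network mask from a weight map
#'
#' Among parcels with strictly positive weight, selects the
#' `ceiling(top_fraction * count)` highest-weighted; ties are broken by
#' parcel order (lower id first) for determinism.
#'
#' @param weights numeric parcel weight vector.
#' @param top_fraction fraction in (0, 1] of positive-weight parcels to
#'   keep.
#' @return logical parcel mask (attribute `flagged = TRUE` when there are no
#'   positive weights).
#' @export
threshold_network <- function(weights, top_fraction) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop_arg("top_fraction must lie in (0, 1]")
  w <- as.numeric(weights)
  mask <- logical(length(w))
  names(mask) <- names(weights)
  pos <- which(w > 0)
  if (length(pos) == 0) {
    attr(mask, "flagged") <- TRUE
    return(mask)
  }
  k <- ceiling(top_fraction * length(pos))
  sel <- pos[order(-w[pos], pos)][seq_len(k)]
  mask[sel] <- TRUE
  mask
}

#' Binary structural-connectivity mask
#'
#' Parcels whose cumulative ChaCo score strictly exceeds `tau`.
#'
#' @param cumulative numeric cumulative ChaCo vector.
#' @param tau threshold (>= 0).
#' @return logical parcel mask.
#' @export
threshold_sc <- function(cumulative, tau) {
  if (tau < 0) stop_arg("tau must be >= 0")
  mask <- as.numeric(cumulative) > tau
  names(mask) <- names(cumulative)
  mask
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`. Two empty masks give 0 with a
#' degenerate flag.
#'
#' @param a,b logical masks over the same parcel universe.
#' @return numeric in `[0, 1]`.
#' @export
#' @examples
#' dice(c(TRUE, TRUE, FALSE), c(FALSE, TRUE, TRUE))  # 0.5
dice <- function(a, b) {
  if (length(a) != length(b))
    stop_arg("masks must share the same parcel universe")
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  2 * sum(a & b) / denom
}

#' Structure-function congruence association with memory change
#'
#' Computes each site's Dice overlap between its thresholded structural
#' connectivity mask and the thresholded encoding-network mask, then the
#' Spearman correlation between Dice values and memory change.
#'
#' @param sc_profiles sites-by-parcels cumulative ChaCo matrix.
#' @param encoding_weights parcel weight vector.
#' @param top_fraction encoding-network threshold (fraction of positive
#'   weights).
#' @param tau structural connectivity threshold.
#' @param deltas memory-change vector aligned with the rows of
#'   `sc_profiles`.
#' @return list with `rho`, `p`, `n`, `dice` (per-site values), and
#'   `degenerate` (TRUE when the Dice values carry no variance).
#' @export
congruence_association <- function(sc_profiles, encoding_weights,
                                   top_fraction, tau, deltas) {
  sc_profiles <- as.matrix(sc_profiles)
  if (nrow(sc_profiles) < 5) stop_arg("need >= 5 sites")
  if (nrow(sc_profiles) != length(deltas))
    stop_arg("rows of sc_profiles must align with deltas")
  net <- threshold_network(encoding_weights, top_fraction)
  d <- apply(sc_profiles, 1, function(cum)
    as.numeric(dice(net, threshold_sc(cum, tau))))
  if (isTRUE(attr(net, "flagged")) || stats::sd(d) == 0 ||
      stats::sd(deltas) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = length(d), dice = d,
                degenerate = TRUE))
  }
  ct <- spearman_rho(d, deltas)
  list(rho = ct$estimate, p = ct$p, n = ct$n, dice = d, degenerate = FALSE)
}

#' Congruence threshold-grid sweep with FDR control
#'
#' Repeats [congruence_association()] over a two-dimensional threshold grid
#' (by default ten encoding-network fractions 0.1..1.0 by six structural
#' thresholds spaced log-like over 0.001..50, which includes the
#' representative pair 0.3 / 1) and controls the grid-wise multiplicity with
#' Benjamini-Hochberg FDR. Degenerate cells (empty or constant masks) are
#' flagged and excluded from the FDR family.
#'
#' @inheritParams congruence_association
#' @param net_thresholds encoding-network threshold levels.
#' @param sc_thresholds structural connectivity threshold levels.
#' @return data frame `net_thr`, `sc_thr`, `rho`, `p`, `q`, `n_sites`,
#'   `degenerate`, one row per grid cell.
#' @export
grid_sweep <- function(sc_profiles, encoding_weights, deltas,
                       net_thresholds = (1:10) / 10,
                       sc_thresholds = c(0.001, 0.01, 0.1, 1, 10, 50)) {
  grid <- expand.grid(net_thr = net_thresholds, sc_thr = sc_thresholds,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ca <- congruence_association(sc_profiles, encoding_weights,
                                 grid$net_thr[i], grid$sc_thr[i], deltas)
    data.frame(net_thr = grid$net_thr[i], sc_thr = grid$sc_thr[i],
               rho = ca$rho, p = ca$p, n_sites = ca$n,
               degenerate = ca$degenerate)
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  fam <- !out$degenerate & !is.na(out$p)
  out$q[fam] <- stats::p.adjust(out$p[fam], method = "BH")
  out[, c("net_thr", "sc_thr", "rho", "p", "q", "n_sites", "degenerate")]
}
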