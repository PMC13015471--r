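# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

small_cfg <- function(...) {
  synth_config(n_parcels = 20, n_closed = 12, n_random = 8,
               seed = 42L, ...)
}

# A small world: atlas + tractogram + encoding weights at test scale.
small_world <- function() {
  if (is.null(.fx$world)) {
    cfg <- small_cfg()
    atlas <- generate_atlas(cfg$n_parcels, cfg$seed)
    tract <- generate_tractogram(atlas, cfg, cfg$seed + 10L)
    weights <- generate_encoding_network(atlas, seed = cfg$seed + 20L)
    .fx$world <- list(cfg = cfg, atlas = atlas, tract = tract,
                      weights = weights)
  }
  .fx$world
}

# Full-size study world (60 parcels, 39 + 22 sites) with site profiles;
# expensive, shared by the permutation/congruence/model tests.
study_world <- function() {
  if (is.null(.fx$study)) {
    cfg <- synth_config()
    atlas <- generate_atlas(cfg$n_parcels, cfg$seed)
    tract <- generate_tractogram(atlas, cfg, cfg$seed + 10L)
    weights <- generate_encoding_network(atlas, seed = cfg$seed + 20L)
    sites <- generate_sites(atlas, tract, weights, cfg)
    prof <- attr(sites, "sc_profiles")
    rownames(prof) <- sites$site_id
    .fx$study <- list(cfg = cfg, atlas = atlas, tract = tract,
                      weights = weights, sites = sites, prof = prof)
  }
  .fx$study
}

# One random curved polyline for geometry tests.
random_polyline <- function(n_vertices = sample(2:8, 1), scale = 40) {
  matrix(stats::runif(3 * n_vertices, -scale, scale), ncol = 3)
}

# Hand-built tiny tractogram: n streamlines between parcels 1 and 2, the
# first `k_through` passing through the origin, the rest far away.
two_parcel_tract <- function(n = 4, k_through = 1) {
  verts <- c(
    replicate(k_through,
              rbind(c(-30, 0, 0), c(0, 0, 0), c(30, 0, 0)),
              simplify = FALSE),
    replicate(n - k_through,
              rbind(c(-30, 200, 0), c(0, 200, 0), c(30, 200, 0)),
              simplify = FALSE)
  )
  tractogram(rep(1L, n), rep(2L, n), verts, n_parcels = 2L)
}
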