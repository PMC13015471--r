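#' Default pipeline configuration
#'
#' Assembles the full configuration consumed by [run_pipeline()]: the
#' synthetic-study parameters plus method choices and iteration counts for
#' the statistical stages.
#'
#' @param synth a [synth_config()].
#' @param n_subjects,n_timepoints normative task-fMRI panel: subjects and
#'   time points per subject.
#' @param sc_method,fc_method association statistic for structural
#'   (`"kendall"`) and functional (`"pearson"`) maps.
#' @param n_perm permutations for the max-statistic correction.
#' @param n_boot bootstrap resamples for the path models.
#' @param n_top parcels entering each connectivity block of the path
#'   models.
#' @param fisher_z average functional connectivity on the Fisher-z scale.
#' @param seed base seed; stage seeds are derived as small offsets.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            n_subjects = 34, n_timepoints = 750,
                            sc_method = "kendall", fc_method = "pearson",
                            n_perm = 5000, n_boot = 5000, n_top = 5,
                            fisher_z = FALSE, seed = synth$seed) {
  structure(list(synth = synth, n_subjects = n_subjects,
                 n_timepoints = n_timepoints, sc_method = sc_method,
                 fc_method = fc_method, n_perm = n_perm, n_boot = n_boot,
                 n_top = n_top, fisher_z = fisher_z,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Select the parcels most associated with memory change
#'
#' Ranks parcels by the absolute value of their connectivity-memory
#' association (computed on the closed-loop sites, mirroring how indicator
#' regions are chosen for the path models) and returns the top `k` column
#' indices.
#'
#' @param conn sites-by-parcels connectivity matrix (closed-loop rows).
#' @param deltas memory-change vector aligned with `conn` rows.
#' @param k number of parcels.
#' @param method association statistic.
#' @return integer vector of column indices, strongest first.
#' @export
select_top_parcels <- function(conn, deltas, k = 5,
                               method = c("kendall", "pearson")) {
  stat <- parcelwise_association(conn, deltas, match.arg(method))
  order(-abs(stat))[seq_len(k)]
}

#' Build the indicator table for the path models
#'
#' Joins per-site structural and functional connectivity indicators (the
#' `k` parcels most associated with closed-loop memory change, per
#' modality), white-matter proximity, stimulation mode (closed = 1), and
#' the behavioral outcomes into one observation-per-site table. Only
#' included sites (baseline rule satisfied) are kept.
#'
#' @param sc_profiles,fc_profiles sites-by-parcels matrices (rownames =
#'   site ids).
#' @param sites sites data frame.
#' @param outcomes data frame from [memory_change()].
#' @param k indicator parcels per modality.
#' @return data frame with columns `sc1..sck`, `fc1..fck`, `wmp`, `mode`,
#'   `baseline`, `delta`; attribute `parcels` records the selected parcel
#'   columns.
#' @export
build_indicator_table <- function(sc_profiles, fc_profiles, sites, outcomes,
                                  k = 5) {
  keep <- outcomes$included
  out <- outcomes[keep, , drop = FALSE]
  m <- match(out$site_id, sites$site_id)
  if (anyNA(m)) stop_arg("outcomes reference unknown sites")
  sc <- sc_profiles[match(out$site_id, rownames(sc_profiles)), , drop = FALSE]
  fc <- fc_profiles[match(out$site_id, rownames(fc_profiles)), , drop = FALSE]
  mode_closed <- as.numeric(sites$mode[m] == "closed")
  cl <- mode_closed == 1
  sc_sel <- select_top_parcels(sc[cl, , drop = FALSE], out$delta[cl], k,
                               "kendall")
  fc_sel <- select_top_parcels(fc[cl, , drop = FALSE], out$delta[cl], k,
                               "pearson")
  ind <- data.frame(sc[, sc_sel, drop = FALSE], fc[, fc_sel, drop = FALSE])
  names(ind) <- c(paste0("sc", seq_len(k)), paste0("fc", seq_len(k)))
  ind$wmp <- sites$wmp_mm[m]
  ind$mode <- mode_closed
  ind$baseline <- out$r_ns
  ind$delta <- out$delta
  rownames(ind) <- out$site_id
  attr(ind, "parcels") <- list(sc = colnames(sc_profiles)[sc_sel],
                               fc = colnames(fc_profiles)[fc_sel])
  ind
}

ind_cols <- function(ind, prefix) grep(paste0("^", prefix, "[0-9]+$"),
                                       names(ind), value = TRUE)

#' Canonical stimulation path models
#'
#' Fits the three path models of the analysis with bootstrap inference:
#'
#' * `run_moderation_model()`: connectivity latent -> memory change,
#'   moderated by stimulation mode (two-stage interaction of latent
#'   scores).
#' * `run_mediation_model()`: white-matter proximity -> connectivity ->
#'   memory change, with the direct path retained; reports the indirect
#'   effect, the proportion mediated, and the BIC improvement of the
#'   mediating model over proximity alone.
#' * `run_multivariate_model()`: structural profile latent (connectivity
#'   indicators jointly decomposed with proximity), functional latent,
#'   stimulation mode and baseline memory as simultaneous predictors of
#'   memory change.
#'
#' Structural connectivity indicators are zero-replaced and
#' log-transformed before standardization; all other columns are
#' standardized only.
#'
#' @param ind indicator table from [build_indicator_table()].
#' @param type connectivity modality for the moderation and mediation
#'   models.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @return list: `boot` (a `pls_boot`) plus model-specific summaries
#'   (`interaction` row for moderation; `mediation` decomposition,
#'   `bic_base`, `bic_extended`, `delta_bic` for mediation; `r2` for the
#'   multivariate model).
#' @export
run_moderation_model <- function(ind, type = c("sc", "fc"), n_boot = 5000,
                                 seed = 1L) {
  type <- match.arg(type)
  cols <- ind_cols(ind, type)
  dat <- preprocess_indicators(ind[, c(cols, "mode", "delta")],
                               log_columns = if (type == "sc") cols)
  spec <- pls_model_spec(
    blocks = stats::setNames(list(cols, "mode", "delta"),
                             c("CONN", "MODE", "DELTA")),
    paths = data.frame(from = c("CONN", "MODE"), to = c("DELTA", "DELTA")),
    moderations = list(c("MODE", "CONN", "DELTA")),
    n_boot = n_boot, seed = seed)
  boot <- bootstrap_inference(spec, dat, n_boot, seed)
  list(boot = boot,
       conn_effect = boot$paths[boot$paths$from == "CONN", ],
       interaction = moderation_effect(boot, "MODE", "CONN", "DELTA"))
}

#' @rdname run_moderation_model
#' @export
run_mediation_model <- function(ind, type = c("sc", "fc"), n_boot = 5000,
                                seed = 1L) {
  type <- match.arg(type)
  cols <- ind_cols(ind, type)
  dat <- preprocess_indicators(ind[, c(cols, "wmp", "delta")],
                               log_columns = if (type == "sc") cols)
  spec <- pls_model_spec(
    blocks = stats::setNames(list("wmp", cols, "delta"),
                             c("WMP", "CONN", "DELTA")),
    paths = data.frame(from = c("WMP", "CONN", "WMP"),
                       to = c("CONN", "DELTA", "DELTA")),
    n_boot = n_boot, seed = seed)
  boot <- bootstrap_inference(spec, dat, n_boot, seed)
  med <- mediation(boot, "WMP", "CONN", "DELTA")
  # proximity-only baseline model for the BIC comparison
  spec0 <- pls_model_spec(
    blocks = list(WMP = "wmp", DELTA = "delta"),
    paths = data.frame(from = "WMP", to = "DELTA"),
    n_boot = n_boot, seed = seed)
  fit0 <- fit_pls(spec0, dat)
  bic0 <- model_bic(fit0, "DELTA")
  bic1 <- model_bic(boot$fit, "DELTA")
  list(boot = boot, mediation = med,
       bic_base = bic0, bic_extended = bic1, delta_bic = bic0 - bic1)
}

#' @rdname run_moderation_model
#' @export
run_multivariate_model <- function(ind, n_boot = 5000, seed = 1L) {
  sc <- ind_cols(ind, "sc")
  fc <- ind_cols(ind, "fc")
  dat <- preprocess_indicators(
    ind[, c(sc, fc, "wmp", "mode", "baseline", "delta")],
    log_columns = sc)
  spec <- pls_model_spec(
    blocks = stats::setNames(
      list(c(sc, "wmp"), fc, "mode", "baseline", "delta"),
      c("STRUCT", "FC", "MODE", "BASE", "DELTA")),
    paths = data.frame(from = c("STRUCT", "FC", "MODE", "BASE"),
                       to = rep("DELTA", 4)),
    n_boot = n_boot, seed = seed)
  boot <- bootstrap_inference(spec, dat, n_boot, seed)
  list(boot = boot, r2 = boot$fit$r2[["DELTA"]])
}

read_stage <- function(path, producer, reader) {
  if (!file.exists(path))
    stop_arg("missing upstream artifact ", path,
             ": run the '", producer, "' stage first")
  reader(path)
}

write_manifest <- function(out_dir, stage, params, files) {
  manifest <- list(
    package = "stimnet",
    version = as.character(utils::packageVersion("stimnet")),
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params,
    outputs = lapply(stats::setNames(files, basename(files)), function(f)
      list(md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages end to end over flat-file artifacts in
#' `out_dir`. Stages: `simulate` (synthetic atlas, tractogram, encoding
#' network, task time series, cohort), `chaco` (structural profiles),
#' `fc` (functional profiles), `behavior` (memory outcomes), `map`
#' (max-statistic association maps), `congruence` (representative cell and
#' threshold grid), `plsem` (moderation, mediation and multivariate path
#' models), or `all`. Each stage writes TSV/CSV outputs plus a JSON
#' manifest recording parameters, seeds and output checksums; a missing
#' upstream artifact raises an error naming the stage that produces it.
#'
#' @param stage one of `simulate`, `chaco`, `fc`, `behavior`, `map`,
#'   `congruence`, `plsem`, `all`.
#' @param config a [pipeline_config()] (or a YAML/JSON file path holding
#'   the scalar fields of one).
#' @param out_dir artifact directory (created if absent).
#' @param quiet suppress progress messages.
#' @return invisibly, the paths written by the stage(s).
#' @export
run_pipeline <- function(stage = "all", config = pipeline_config(),
                         out_dir = "stimnet_out", quiet = FALSE) {
  stages <- c("simulate", "chaco", "fc", "behavior", "map", "congruence",
              "plsem")
  stage <- match.arg(stage, c(stages, "all"))
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  todo <- if (stage == "all") stages else stage
  say <- function(...) if (!quiet) message(...)
  p <- function(...) file.path(out_dir, ...)
  written <- character(0)

  for (st in todo) {
    say("[stimnet] stage: ", st)
    files <- switch(st,
      simulate = {
        cfg <- config$synth
        atlas <- generate_atlas(cfg$n_parcels, cfg$seed)
        tract <- generate_tractogram(atlas, cfg, cfg$seed + 10L)
        w <- generate_encoding_network(atlas, seed = cfg$seed + 20L)
        ts <- generate_timeseries(atlas, config$n_subjects,
                                  config$n_timepoints, encoding_weights = w,
                                  seed = cfg$seed + 30L)
        cohort <- generate_cohort(atlas, tract, w, cfg)
        write_atlas(atlas, p("atlas.tsv"))
        write_tractogram(tract, p("tractogram.jsonl"))
        utils::write.table(data.frame(parcel_id = atlas$id,
                                      weight = as.numeric(w)),
                           p("encoding_network.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        write_timeseries(ts, p("timeseries"))
        write_sites(cohort$sites, p("sites.csv"))
        write_sessions(cohort$sessions, p("sessions.csv"))
        c(p("atlas.tsv"), p("tractogram.jsonl"), p("encoding_network.tsv"),
          p("sites.csv"), p("sessions.csv"))
      },
      chaco = {
        atlas <- read_stage(p("atlas.tsv"), "simulate", read_atlas)
        sites <- read_stage(p("sites.csv"), "simulate", read_sites)
        tract <- read_stage(p("tractogram.jsonl"), "simulate",
                            function(f) read_tractogram(f, nrow(atlas)))
        prof <- matrix(0, nrow(sites), nrow(atlas),
                       dimnames = list(sites$site_id, atlas$id))
        pw_all <- NULL
        for (i in seq_len(nrow(sites))) {
          pw <- pairwise_chaco(tract, c(sites$x[i], sites$y[i], sites$z[i]),
                               sites$radius_mm[i])
          prof[i, ] <- cumulative_chaco(pw, atlas)
          nz <- pw[pw$ratio > 0, , drop = FALSE]
          if (nrow(nz) > 0)
            pw_all <- rbind(pw_all,
                            cbind(site_id = sites$site_id[i], nz))
        }
        write_profile_matrix(prof, p("sc_profiles.tsv"))
        utils::write.table(pw_all, p("pairwise_chaco.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        c(p("sc_profiles.tsv"), p("pairwise_chaco.tsv"))
      },
      fc = {
        atlas <- read_stage(p("atlas.tsv"), "simulate", read_atlas)
        sites <- read_stage(p("sites.csv"), "simulate", read_sites)
        ts <- read_stage(p("timeseries"), "simulate", read_timeseries)
        prof <- matrix(0, nrow(sites), nrow(atlas),
                       dimnames = list(sites$site_id, atlas$id))
        for (i in seq_len(nrow(sites)))
          prof[i, ] <- normative_fc(sites[i, ], atlas, ts,
                                    fisher_z = config$fisher_z)$r
        write_profile_matrix(prof, p("fc_profiles.tsv"))
        p("fc_profiles.tsv")
      },
      behavior = {
        sessions <- read_stage(p("sessions.csv"), "simulate", read_sessions)
        sites <- read_stage(p("sites.csv"), "simulate", read_sites)
        out <- memory_change(sessions, sites)
        utils::write.csv(out, p("outcomes.csv"), row.names = FALSE)
        p("outcomes.csv")
      },
      map = {
        sc <- read_stage(p("sc_profiles.tsv"), "chaco", read_profile_matrix)
        fc <- read_stage(p("fc_profiles.tsv"), "fc", read_profile_matrix)
        out <- read_stage(p("outcomes.csv"), "behavior",
                          function(f) utils::read.csv(f))
        cl <- out$included & out$mode == "closed"
        ids <- out$site_id[cl]
        m_sc <- maxstat_correct(sc[ids, , drop = FALSE], out$delta[cl],
                                config$sc_method, config$n_perm,
                                seed = config$seed + 40L)
        m_fc <- maxstat_correct(fc[ids, , drop = FALSE], out$delta[cl],
                                config$fc_method, config$n_perm,
                                seed = config$seed + 41L)
        utils::write.table(m_sc, p("map_structural.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(m_fc, p("map_functional.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        c(p("map_structural.tsv"), p("map_functional.tsv"))
      },
      congruence = {
        sc <- read_stage(p("sc_profiles.tsv"), "chaco", read_profile_matrix)
        out <- read_stage(p("outcomes.csv"), "behavior",
                          function(f) utils::read.csv(f))
        wtab <- read_stage(p("encoding_network.tsv"), "simulate",
                           function(f) utils::read.delim(f))
        w <- stats::setNames(wtab$weight, wtab$parcel_id)
        cl <- out$included & out$mode == "closed"
        ids <- out$site_id[cl]
        rep_cell <- congruence_association(sc[ids, , drop = FALSE], w,
                                           0.3, 1, out$delta[cl])
        grid <- grid_sweep(sc[ids, , drop = FALSE], w, out$delta[cl])
        utils::write.table(grid, p("congruence_grid.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.csv(data.frame(site_id = ids, dice = rep_cell$dice,
                                    delta = out$delta[cl]),
                         p("congruence_sites.csv"), row.names = FALSE)
        c(p("congruence_grid.tsv"), p("congruence_sites.csv"))
      },
      plsem = {
        sc <- read_stage(p("sc_profiles.tsv"), "chaco", read_profile_matrix)
        fc <- read_stage(p("fc_profiles.tsv"), "fc", read_profile_matrix)
        out <- read_stage(p("outcomes.csv"), "behavior",
                          function(f) utils::read.csv(f))
        sites <- read_stage(p("sites.csv"), "simulate", read_sites)
        ind <- build_indicator_table(sc, fc, sites, out, k = config$n_top)
        mods <- list(
          moderation_sc = run_moderation_model(ind, "sc", config$n_boot,
                                               config$seed + 50L),
          mediation_sc = run_mediation_model(ind, "sc", config$n_boot,
                                             config$seed + 51L),
          multivariate = run_multivariate_model(ind, config$n_boot,
                                                config$seed + 52L))
        paths <- do.call(rbind, lapply(names(mods), function(nm)
          cbind(model = nm, mods[[nm]]$boot$paths)))
        utils::write.table(paths, p("pls_paths.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        med <- mods$mediation_sc
        summ <- data.frame(
          quantity = c("moderation_interaction_beta",
                       "moderation_interaction_p",
                       "mediation_indirect_beta", "mediation_indirect_p",
                       "proportion_mediated_pct", "delta_bic",
                       "multivariate_r2"),
          value = c(mods$moderation_sc$interaction$beta,
                    mods$moderation_sc$interaction$p,
                    med$mediation$indirect,
                    med$boot$indirect$p[1],
                    med$mediation$proportion_mediated,
                    med$delta_bic,
                    mods$multivariate$r2))
        utils::write.table(summ, p("pls_summary.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        q <- quality_diagnostics(mods$multivariate$boot$fit)
        utils::write.table(
          data.frame(block = names(q$ave), ave = q$ave,
                     composite_reliability = q$composite_reliability),
          p("pls_quality.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
        c(p("pls_paths.tsv"), p("pls_summary.tsv"), p("pls_quality.tsv"))
      })
    params <- config
    params$synth <- unclass(config$synth)
    write_manifest(out_dir, st, unclass(params), files)
    written <- c(written, files)
  }
  invisible(written)
}

#' @rdname run_pipeline
#' @param path YAML or JSON file with scalar `pipeline_config()` /
#'   `synth_config()` fields (top-level pipeline fields plus an optional
#'   `synth` mapping).
#' @export
load_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_arg("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  synth <- do.call(synth_config, cfg$synth %||% list())
  cfg$synth <- NULL
  do.call(pipeline_config, c(list(synth = synth), cfg))
}
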