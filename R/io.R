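# Flat-file interchange formats: TSV for tables and matrices, CSV for sites
# and sessions, JSON-lines for streamlines. All inspectable plain text.

#' Read and write pipeline artifacts
#'
#' Plain-text interchange used between pipeline stages: the atlas as TSV
#' (`id`, `name`, `x`, `y`, `z`, `hemisphere`), the tractogram as JSON-lines
#' (one streamline per line with `parcel_a`, `parcel_b` and `vertices` as
#' mm triplets), time series as one TSV matrix per subject, sites and
#' sessions as CSV, and profile matrices as TSV with a leading `site_id`
#' column.
#'
#' @param atlas,tract,ts_list,sites,sessions,mat objects to write.
#' @param path,dir file or directory paths.
#' @param n_parcels parcel universe for a tractogram being read.
#' @name stimnet-io
NULL

#' @rdname stimnet-io
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(as.data.frame(atlas), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname stimnet-io
#' @export
read_atlas <- function(path) {
  atlas <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "name", "x", "y", "z", "hemisphere")
  if (!all(need %in% names(atlas)))
    stop_arg("atlas file lacks columns: ",
             paste(setdiff(need, names(atlas)), collapse = ", "))
  if (any(atlas$id != seq_len(nrow(atlas))))
    stop_arg("atlas ids must be contiguous from 1")
  class(atlas) <- c("parcel_atlas", "data.frame")
  atlas
}

#' @rdname stimnet-io
#' @export
write_tractogram <- function(tract, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(tract$vertices)) {
    line <- jsonlite::toJSON(list(parcel_a = tract$parcel_a[i],
                                  parcel_b = tract$parcel_b[i],
                                  vertices = round(tract$vertices[[i]], 4)),
                             auto_unbox = TRUE, digits = NA)
    writeLines(line, con)
  }
  invisible(path)
}

#' @rdname stimnet-io
#' @export
read_tractogram <- function(path, n_parcels) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  tractogram(
    parcel_a = vapply(recs, function(r) as.integer(r$parcel_a), integer(1)),
    parcel_b = vapply(recs, function(r) as.integer(r$parcel_b), integer(1)),
    vertices = lapply(recs, function(r) matrix(as.numeric(r$vertices),
                                               ncol = 3)),
    n_parcels = n_parcels
  )
}

#' @rdname stimnet-io
#' @export
write_timeseries <- function(ts_list, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(ts_list)) {
    utils::write.table(ts_list[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = FALSE,
                       row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname stimnet-io
#' @export
read_timeseries <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0) stop_arg("no time-series files in ", dir)
  out <- lapply(files, function(f)
    as.matrix(utils::read.delim(f, header = FALSE)))
  names(out) <- sub("\\.tsv$", "", basename(files))
  out
}

#' @rdname stimnet-io
#' @export
write_sites <- function(sites, path) {
  utils::write.csv(as.data.frame(sites), path, row.names = FALSE)
  invisible(path)
}

#' @rdname stimnet-io
#' @export
read_sites <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' @rdname stimnet-io
#' @export
write_sessions <- function(sessions, path) {
  utils::write.csv(as.data.frame(sessions), path, row.names = FALSE)
  invisible(path)
}

#' @rdname stimnet-io
#' @export
read_sessions <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' @rdname stimnet-io
#' @export
write_profile_matrix <- function(mat, path) {
  df <- data.frame(site_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
                   as.data.frame(mat, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname stimnet-io
#' @export
read_profile_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
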