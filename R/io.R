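subject_csv_header <- c("subject_id", "age", "sex", "race", "education",
                        "cirs_g", "madrs", "hars", "pswq", "pss", "rsq", "neo_ffi")
annotation_csv_header <- c("node_id", "label", "network", "region_group", "hemisphere")

#' Read and write subject tables
#'
#' CSV with header exactly
#' `subject_id,age,sex,race,education,cirs_g,madrs,hars,pswq,pss,rsq,neo_ffi`.
#'
#' @param subjects A `subject_table`.
#' @param path File path.
#' @return `read_subjects_csv` returns a `subject_table`;
#'   `write_subjects_csv` returns `path` invisibly.
#' @export
write_subjects_csv <- function(subjects, path) {
  out <- as.data.frame(subjects)[subject_csv_header]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_subjects_csv
#' @export
read_subjects_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(out), subject_csv_header)) {
    stopf("unexpected subject CSV header; expected: %s",
          paste(subject_csv_header, collapse = ","))
  }
  out$sex <- factor(out$sex, levels = c("F", "M"))
  out$race <- factor(out$race)
  out$subject_id <- as.character(out$subject_id)
  class(out) <- c("subject_table", class(out))
  out
}

#' Read and write node annotation tables
#'
#' CSV with header exactly `node_id,label,network,region_group,hemisphere`.
#'
#' @param annotation A `node_annotation`.
#' @param path File path.
#' @return `read_annotation_csv` returns a `node_annotation`;
#'   `write_annotation_csv` returns `path` invisibly.
#' @export
write_annotation_csv <- function(annotation, path) {
  out <- as.data.frame(annotation)[annotation_csv_header]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotation_csv
#' @export
read_annotation_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(out), annotation_csv_header)) {
    stopf("unexpected annotation CSV header; expected: %s",
          paste(annotation_csv_header, collapse = ","))
  }
  if (anyDuplicated(out$node_id) || !identical(sort(out$node_id), 0:(nrow(out) - 1L))) {
    stopf("node ids must be unique and contiguous from 0")
  }
  out$network <- factor(out$network)
  out$region_group <- factor(out$region_group, levels = region_groups)
  out$hemisphere <- factor(out$hemisphere, levels = c("L", "R", "bilateral"))
  class(out) <- c("node_annotation", class(out))
  out
}

#' Read and write connectivity panels
#'
#' CSV with one row per subject: a `subject_id` column followed by edge
#' columns `e0, e1, ...` in canonical order.
#'
#' @param panel A [connectivity_panel()].
#' @param path File path.
#' @param m Node count (required on read; checked against the column count).
#' @return `read_panel_csv` returns a [connectivity_panel()];
#'   `write_panel_csv` returns `path` invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "connectivity_panel"))
  dt <- data.table::as.data.table(panel$z)
  dt <- cbind(data.table::data.table(subject_id = panel$subject_id), dt)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path, m) {
  dt <- data.table::fread(path)
  if (names(dt)[1] != "subject_id") stopf("panel CSV must start with a subject_id column")
  ids <- as.character(dt[["subject_id"]])
  z <- as.matrix(dt[, -1])
  connectivity_panel(z, m = m, subject_id = ids)
}

#' Write the edge index sidecar
#'
#' CSV with header `edge_id,node_i,node_j` mapping canonical edge ids to
#' 0-based node pairs.
#'
#' @param m Node count.
#' @param path File path.
#' @export
write_edge_index_csv <- function(m, path) {
  utils::write.csv(as.data.frame(edge_index(m)), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write time-series panels
#'
#' One tab-separated `T x m` file per subject plus a JSON manifest with
#' `tr`, `band`, `T`, `m`, and the per-subject file names.
#'
#' @param ts_panel A `timeseries_panel`.
#' @param dir Directory for the manifest (`timeseries_manifest.json`) and
#'   the per-subject TSV files.
#' @return `write_timeseries` returns the manifest path invisibly;
#'   `read_timeseries` returns a `timeseries_panel`.
#' @export
write_timeseries <- function(ts_panel, dir) {
  stopifnot(inherits(ts_panel, "timeseries_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- paste0(names(ts_panel$series), ".tsv")
  for (s in seq_along(ts_panel$series)) {
    utils::write.table(ts_panel$series[[s]], file.path(dir, files[s]),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  manifest <- list(tr = ts_panel$tr, band = ts_panel$band, T = ts_panel$T,
                   m = ts_panel$m,
                   subjects = setNames(as.list(files), names(ts_panel$series)))
  path <- file.path(dir, "timeseries_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_timeseries
#' @param manifest Path to a `timeseries_manifest.json`.
#' @export
read_timeseries <- function(manifest) {
  info <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  series <- lapply(info$subjects, function(f) {
    as.matrix(utils::read.table(file.path(dir, f), sep = "\t"))
  })
  series <- lapply(series, function(x) { dimnames(x) <- NULL; x })
  structure(list(series = series, tr = info$tr, band = unlist(info$band),
                 T = info$T, m = info$m),
            class = "timeseries_panel")
}
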