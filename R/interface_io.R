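#' Write a matrix to a container file
#'
#' Two containers are supported: delimited text (`.tsv`/`.csv`/`.txt`,
#' '.' decimal, 17 significant digits so the round trip is lossless to
#' double precision for all practical purposes) and the R-native binary
#' container (`.rds`, bit-exact round trip). An optional JSON sidecar
#' (`<path>.json`) records shape, axis names, and any grid metadata.
#'
#' @param m numeric matrix.
#' @param path output path; format is chosen by extension.
#' @param sidecar optional named list of metadata (e.g. a serialized grid
#'   from [grid_to_sidecar()]).
#' @return invisibly, `path`.
#' @export
write_matrix <- function(m, path, sidecar = NULL) {
  m <- as.matrix(m)
  check_finite_matrix(m, "matrix")
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    saveRDS(m, path)
  } else if (ext %in% c("tsv", "txt", "csv")) {
    sep <- if (ext == "csv") "," else "\t"
    utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                       path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    stop_invalid("unsupported matrix container extension: .", ext,
                 class = "popkernel_format_error")
  }
  if (!is.null(sidecar)) {
    sidecar$shape <- dim(m)
    jsonlite::write_json(sidecar, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a matrix from a container file
#'
#' Text containers sniff the delimiter (tab or comma) from the first line;
#' comma-decimal numbers are rejected with a line/field diagnostic. If a
#' JSON sidecar exists its shape is checked against the parsed matrix.
#'
#' @param path file written by [write_matrix()] (or compatible).
#' @return list with `matrix` and `sidecar` (a list, or `NULL`).
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path,
                                       class = "popkernel_format_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    m <- readRDS(path)
  } else {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    rows <- strsplit(readLines(path), sep, fixed = TRUE)
    ncols <- lengths(rows)
    if (length(unique(ncols)) != 1) {
      stop_invalid("ragged rows in ", path, ": line ", which(ncols != ncols[1])[1],
                   " has ", ncols[which(ncols != ncols[1])[1]], " fields, expected ",
                   ncols[1], class = "popkernel_format_error")
    }
    start <- 1L
    vals1 <- suppressWarnings(as.numeric(rows[[1]]))
    if (anyNA(vals1) && length(rows) > 1) start <- 2L     # header row
    m <- matrix(NA_real_, length(rows) - start + 1L, ncols[1])
    for (i in start:length(rows)) {
      v <- suppressWarnings(as.numeric(rows[[i]]))
      if (anyNA(v)) {
        bad <- which(is.na(v))[1]
        stop_invalid("cannot parse line ", i, " field ", bad, " of ", path,
                     " ('", rows[[i]][bad], "'): use '.' as the decimal mark",
                     class = "popkernel_format_error")
      }
      m[i - start + 1L, ] <- v
    }
  }
  sidecar_path <- paste0(path, ".json")
  sidecar <- NULL
  if (file.exists(sidecar_path)) {
    sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (!is.null(sidecar$shape) && !all(sidecar$shape == dim(m))) {
      stop_invalid("sidecar shape ", paste(sidecar$shape, collapse = "x"),
                   " does not match matrix ", paste(dim(m), collapse = "x"),
                   class = "popkernel_format_error")
    }
  }
  list(matrix = m, sidecar = sidecar)
}

#' Serialize / reconstruct a stimulus grid for a sidecar
#'
#' @param grid a [stimulus_grid()].
#' @return `grid_to_sidecar`: a plain list; `grid_from_sidecar`: a
#'   [stimulus_grid()] rebuilt from such a list.
#' @export
grid_to_sidecar <- function(grid) {
  list(grid = list(values = grid$values, probabilities = grid$probabilities,
                   period = grid$period))
}

#' @rdname grid_to_sidecar
#' @param sidecar list read back from a sidecar JSON.
#' @export
grid_from_sidecar <- function(sidecar) {
  g <- sidecar$grid
  vals <- if (is.matrix(g$values)) g$values else as.numeric(g$values)
  period <- if (is.null(g$period)) NA_real_ else as.numeric(g$period)
  gr <- stimulus_grid(vals, as.numeric(g$probabilities), period = period[1])
  gr$period <- period
  gr
}

#' Read / write an experiment configuration
#'
#' Configurations are nested key-value YAML with sections for the
#' generator, task, theory, and simulation, each carrying explicit seeds;
#' the round trip through serialization is lossless.
#'
#' @param path YAML file path.
#' @return a named list (class `experiment_config`).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "experiment_config")
}

#' @rdname read_config
#' @param config named list to write.
#' @return invisibly, `path`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

# Run manifest written beside every CLI output: enough to regenerate the run.
write_manifest <- function(out_dir, name, seed, config_path = NULL, outputs = NULL,
                           started = Sys.time()) {
  manifest <- list(
    command = name,
    seed = seed,
    config = if (!is.null(config_path)) {
      list(path = config_path, md5 = unname(tools::md5sum(config_path)))
    },
    outputs = outputs,
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("popkernel")),
    wall_clock_s = as.numeric(difftime(Sys.time(), started, units = "secs")),
    timestamp = format(started, "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
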