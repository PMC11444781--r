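#' Load a simulation configuration from a YAML file
#'
#' Reads a flat key-value YAML file and builds a [sim_config()], applying
#' the package defaults (`L = 40`, `beta = 10`, `gamma = 5`, `dt = 0.001`,
#' `n_steps = 10000`, `n_runs = 10`, ...) for keys that are absent.  Unknown
#' keys are rejected with an error naming them.  The string `"Inf"` (or
#' `"sis"`) is accepted for `zeta` to request the SIS limit.
#'
#' @param path path to a YAML config file (an empty file yields the full
#'   defaults).
#' @return A [sim_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(raw$zeta) && is.character(raw$zeta)) {
    if (tolower(raw$zeta) %in% c("inf", "sis")) raw$zeta <- Inf
    else stop("`zeta` must be a number, \"Inf\" or \"sis\"", call. = FALSE)
  }
  do.call(sim_config, raw)
}

#' Write a simulation configuration to YAML
#'
#' @param config a [sim_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  lst <- unclass(config)
  if (is.infinite(lst$zeta)) lst$zeta <- "Inf"
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Write a lattice field to CSV
#'
#' Writes an `L x L` (or rectangular) field as comma-separated rows at full
#' double precision, preceded by a header line recording the dimensions and
#' the periodic flag.  The decimal separator is always the dot, regardless
#' of locale, and [read_grid_csv()] round-trips the values exactly.
#'
#' @param field numeric matrix.
#' @param path output path.
#' @param periodic periodic flag recorded in the header.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(field, path, periodic = TRUE) {
  if (!is.matrix(field)) stop("`field` must be a matrix", call. = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# nrow=%d ncol=%d periodic=%s",
                     nrow(field), ncol(field), periodic), con)
  lines <- apply(field, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, con)
  invisible(path)
}

#' Read a lattice field written by [write_grid_csv()]
#'
#' @param path path to the CSV file.
#' @return Numeric matrix with attribute `periodic` taken from the header.
#' @export
read_grid_csv <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#")) {
    stop("missing grid header line", call. = FALSE)
  }
  hdr <- lines[1]
  get_num <- function(key) as.numeric(sub(sprintf(".*%s=([^ ]+).*", key), "\\1", hdr))
  nr <- get_num("nrow"); nc <- get_num("ncol")
  periodic <- grepl("periodic=TRUE", hdr)
  rows <- strsplit(lines[-1], ",", fixed = TRUE)
  lens <- lengths(rows)
  if (length(rows) != nr || any(lens != nc)) {
    stop("ragged or truncated grid rows", call. = FALSE)
  }
  field <- matrix(as.numeric(unlist(rows)), nrow = nr, byrow = TRUE)
  attr(field, "periodic") <- periodic
  field
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a command's outputs: the resolved
#' configuration, the seed (and derived schedule parameters), the package
#' version, a timestamp and the list of files written.
#'
#' @param path output JSON path.
#' @param config the resolved configuration (a list or [sim_config()]).
#' @param seed the base seed used.
#' @param outputs character vector of output file paths.
#' @param extra optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, seed, outputs, extra = list()) {
  lst <- unclass(config)
  lst <- lapply(lst, function(v) if (is.numeric(v) && any(is.infinite(v))) "Inf" else v)
  manifest <- c(list(package = "sirscape",
                     version = as.character(packageVersion("sirscape")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     seed = seed, config = lst, outputs = outputs),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
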