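#' Write / read spike trains as CSV
#'
#' Long format with columns `unit_id`, `t_spike_s`; the time grid metadata
#' (`dt`, `t0`) is carried in commented header lines so a file round-trips
#' with its sampling context.
#'
#' @param spikes List of per-unit spike-time vectors (s).
#' @param path Output CSV path.
#' @param dt,t0 Grid metadata (s).
#' @return `write_spike_trains` returns `path` invisibly;
#'   `read_spike_trains` returns a list with `spikes`, `dt`, `t0`.
#' @export
write_spike_trains <- function(spikes, path, dt = NA_real_, t0 = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dt_s=%.17g", dt), sprintf("# t0_s=%.17g", t0),
               "unit_id,t_spike_s"), con)
  for (u in seq_along(spikes)) {
    if (length(spikes[[u]]))
      writeLines(sprintf("%d,%.17g", u, spikes[[u]]), con)
  }
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    m <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (length(m)) as.numeric(sub(paste0("^# ", key, "="), "", m[1])) else NA_real_
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 1L || body[1] != "unit_id,t_spike_s")
    stop("not a spike-train CSV (missing unit_id,t_spike_s header): ", path)
  if (length(body) == 1L)
    stop("spike-train file contains no spikes: ", path)
  d <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  units <- sort(unique(d$unit_id))
  spikes <- lapply(units, function(u) sort(d$t_spike_s[d$unit_id == u]))
  list(spikes = spikes, dt = getv("dt_s"), t0 = getv("t0_s"))
}

#' Write signal blocks as a wide CSV
#'
#' One row per sample: a `t_s` column followed by one column per unit.
#'
#' @param block Numeric matrix (units x samples).
#' @param grid The block's [time_grid()].
#' @param path Output CSV path.
#' @param prefix Column-name prefix for units.
#' @return `path`, invisibly.
#' @export
write_signal_block <- function(block, grid, path, prefix = "unit") {
  d <- data.frame(t_s = grid_times(grid), t(block))
  names(d)[-1] <- paste0(prefix, seq_len(nrow(block)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration file (YAML or JSON)
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be a .yaml/.yml or .json file: ", path)
}

# Manifest describing a reproducible run: config echo, seeds, versions and
# md5 hashes of the produced files.
write_manifest <- function(path, config, files) {
  files <- files[file.exists(files)]
  manifest <- list(
    package = "tactsim",
    version = as.character(utils::packageVersion("tactsim")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config,
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files)))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
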