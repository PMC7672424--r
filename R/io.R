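#' Write a photon stream to CSV
#'
#' Flat table with columns \code{timestamp_s}, \code{channel},
#' \code{excitation}; acquisition metadata is carried in \code{#}-prefixed
#' header comments so the reader can round-trip it.
#'
#' @param stream a \code{photon_stream}.
#' @param path output file.
#' @export
write_photon_stream <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# duration_s=%.17g", attr(stream, "duration")),
               sprintf("# sync_rate_hz=%.17g", attr(stream, "sync_rate_hz"))),
             con)
  utils::write.csv(as.data.frame(stream)[c("timestamp_s", "channel",
                                           "excitation")],
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a photon stream
#'
#' @param path input file.
#' @param format \code{"csv"} (the flat format written by
#'   \code{\link{write_photon_stream}}). \code{"h5"} is reserved for
#'   photon-HDF5 containers and is not available in this build.
#' @return A \code{photon_stream}.
#' @export
read_photon_stream <- function(path, format = c("csv", "h5")) {
  format <- match.arg(format)
  if (format == "h5")
    stop_domain("HDF5 photon containers are not supported in this build; use CSV",
                "gqfret_format_error")
  if (!file.exists(path))
    stop_domain(paste("no such file:", path), "gqfret_format_error")
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  get_meta <- function(key, default) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(m)) as.numeric(sub(paste0("^# ", key, "="), "", m[1])) else default
  }
  if (!length(lines) || all(grepl("^#", lines))) {
    warning("empty photon file: returning empty stream", call. = FALSE)
    return(photon_stream(numeric(0), character(0), character(0),
                         duration = get_meta("duration_s", 0),
                         sync_rate_hz = get_meta("sync_rate_hz", 32e6)))
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("timestamp_s", "channel", "excitation")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop_domain(paste("photon CSV missing column(s):",
                      paste(missing, collapse = ", ")),
                "gqfret_format_error")
  photon_stream(df$timestamp_s, df$channel, df$excitation,
                duration = get_meta("duration_s", max(df$timestamp_s, 0)),
                sync_rate_hz = get_meta("sync_rate_hz", 32e6))
}

#' Write a burst table to CSV
#'
#' Columns: burst_id, start_s, stop_s, n_dd, n_da, n_aa, duration_s.
#'
#' @param bursts a \code{burst_table}.
#' @param path output file.
#' @param config_hash optional run-metadata hash written as a header comment.
#' @export
write_burst_table <- function(bursts, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(sprintf("# config_hash=%s", config_hash), con)
  utils::write.csv(as.data.frame(bursts)[c("burst_id", "start_s", "stop_s",
                                           "n_dd", "n_da", "n_aa",
                                           "duration_s")],
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a FRET histogram to CSV
#'
#' @param hist a \code{fret_histogram}.
#' @param path output file.
#' @param config_hash optional run-metadata hash.
#' @export
write_histogram <- function(hist, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(sprintf("# config_hash=%s", config_hash), con)
  utils::write.csv(as.data.frame(hist), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fitted mixture to JSON
#'
#' @param model a \code{fret_mixture}.
#' @param path output file.
#' @param config_hash optional run-metadata hash.
#' @export
write_mixture_json <- function(model, path, config_hash = NULL) {
  obj <- list(k = model$k, means = model$means, sigmas = model$sigmas,
              weights = model$weights,
              log_likelihood = model$log_likelihood, bic = model$bic,
              n_points = model$n_points, flags = as.list(model$flags))
  if (!is.null(config_hash)) obj$config_hash <- config_hash
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a titration series to CSV
#'
#' @param series a \code{titration_series}.
#' @param path output file.
#' @param config_hash optional run-metadata hash.
#' @export
write_titration <- function(series, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(sprintf("# config_hash=%s", config_hash), con)
  utils::write.csv(as.data.frame(series), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Serialize a binding fit to JSON
#'
#' @param fit a \code{binding_fit}.
#' @param path output file.
#' @param config_hash optional run-metadata hash.
#' @export
write_binding_json <- function(fit, path, config_hash = NULL) {
  obj <- list(kd_uM = fit$kd, f0 = fit$f0, f_inf = fit$f_inf,
              se_kd = unname(fit$se["kd"]), rss = fit$rss,
              model = fit$model, n_points = fit$n_points)
  if (!is.null(config_hash)) obj$config_hash <- config_hash
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a melting curve from CSV
#'
#' Expects columns \code{temperature_C}, \code{signal}.
#'
#' @param path input file.
#' @param label curve label (defaults to the file name).
#' @return A \code{melting_curve}.
#' @export
read_melting_curve <- function(path, label = basename(path)) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("temperature_C", "signal") %in% names(df)))
    stop_domain("melting CSV needs columns temperature_C, signal",
                "gqfret_format_error")
  melting_curve(df$temperature_C, df$signal, label = label)
}

#' Read or write simulation/binding configuration as YAML or JSON
#'
#' @param x a \code{sim_config} or \code{binding_params} (for writing).
#' @param path file path; extension selects YAML (\code{.yml}/\code{.yaml})
#'   or JSON.
#' @export
write_config <- function(x, path) {
  obj <- unclass(x)
  obj$.class <- class(x)[1]
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @return \code{read_config} returns the restored object.
#' @export
read_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.class
  obj$.class <- NULL
  switch(cls,
         sim_config = do.call(sim_config, c(
           obj[setdiff(names(obj), "states")],
           list(states = as.data.frame(obj$states)))),
         binding_params = do.call(binding_params, obj),
         stop_domain(paste("unknown config class:", cls),
                     "gqfret_format_error"))
}
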