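# File formats are plain text throughout: traces and spike times carry
# "# key=value" header lines followed by one number per line; result
# records are flat key=value files. Numbers are written with %.17g so every
# reader/writer pair round-trips at full double precision.

.fmt_num <- function(x) sprintf("%.17g", x)

.parse_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    h <- sub("^#\\s*", "", h)
    if (!nzchar(h) || !grepl("=", h, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", h))
    val <- trimws(sub("^[^=]*=", "", h))
    if (key %in% names(kv) && !identical(kv[[key]], val))
      stop("contradictory header values for '", key, "'", call. = FALSE)
    kv[[key]] <- val
  }
  kv
}

#' Read a trace file
#'
#' Trace files are delimited text: `# key=value` header lines declaring at
#' least `dt` (ms), `kind` and `units` (optionally `t0`), followed by one
#' sample per line.
#'
#' @param path Path to an existing trace file.
#' @return A [trace()].
#' @seealso [write_trace()]
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  kv <- .parse_header(lines)
  for (req in c("dt", "kind"))
    if (is.null(kv[[req]]))
      stop("trace header missing '", req, "'", call. = FALSE)
  body <- lines[!grepl("^#", lines)]
  body <- trimws(body)
  body <- body[nzchar(body)]
  if (length(body) == 0L) stop("no samples in ", path, call. = FALSE)
  samples <- suppressWarnings(as.numeric(body))
  if (anyNA(samples)) {
    bad <- which(is.na(samples))[1L]
    stop(sprintf("non-numeric sample '%s' at body line %d of %s",
                 body[bad], bad, path), call. = FALSE)
  }
  trace(samples, dt = as.numeric(kv$dt), kind = kv$kind,
        units = kv$units,
        t0 = if (is.null(kv$t0)) 0 else as.numeric(kv$t0))
}

#' Write a trace file
#'
#' @param x A [trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "trace"))
  con <- try(suppressWarnings(file(path, "w")), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("cannot write to ", path, call. = FALSE)
  on.exit(close(con))
  writeLines(c(sprintf("# dt=%s", .fmt_num(x$dt)),
               sprintf("# t0=%s", .fmt_num(x$t0)),
               sprintf("# kind=%s", x$kind),
               sprintf("# units=%s", x$units),
               .fmt_num(x$samples)), con)
  invisible(path)
}

#' Read a spike-time file
#'
#' One spike time (ms) per line; an optional `# record_duration=<ms>` header.
#' Without the header the record duration defaults to the last spike time.
#'
#' @param path Path to an existing spike-time file.
#' @return A [spike_train()] (without a stimulus descriptor).
#' @export
read_spike_times <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  kv <- .parse_header(lines)
  body <- trimws(lines[!grepl("^#", lines)])
  body <- body[nzchar(body)]
  times <- suppressWarnings(as.numeric(body))
  if (anyNA(times)) {
    bad <- which(is.na(times))[1L]
    stop(sprintf("non-numeric spike time '%s' at body line %d", body[bad], bad),
         call. = FALSE)
  }
  spike_train(times,
              record_duration = if (is.null(kv$record_duration)) NULL
                                else as.numeric(kv$record_duration))
}

#' Write a spike-time file
#'
#' @param x A [spike_train()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spike_times <- function(x, path) {
  stopifnot(inherits(x, "spike_train"))
  con <- try(suppressWarnings(file(path, "w")), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("cannot write to ", path, call. = FALSE)
  on.exit(close(con))
  writeLines(c(sprintf("# record_duration=%s", .fmt_num(x$record_duration)),
               .fmt_num(x$times)), con)
  invisible(path)
}

# Result-record classes that write_results() knows how to serialize.
.result_classes <- c("phase_lock_stats", "polar_summary", "boltzmann_fit",
                     "dose_response_fit", "biexp_fit", "iv_fit",
                     "latency_result")

.serialize_value <- function(v) {
  if (is.character(v)) paste(v, collapse = ",")
  else if (is.logical(v)) paste(ifelse(v, "TRUE", "FALSE"), collapse = ",")
  else paste(.fmt_num(as.numeric(v)), collapse = ",")
}

#' Write a result record to a key/value text file
#'
#' Serializes any of the package's flat result records (phase-lock stats,
#' polar summaries, the four fit results, latency results) as
#' human-readable `key=value` lines that [read_results()] reproduces
#' field-for-field.
#'
#' @param record A result record.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(record, path) {
  cls <- intersect(class(record), .result_classes)
  if (length(cls) == 0L)
    stop("unknown record type: ", paste(class(record), collapse = "/"),
         call. = FALSE)
  con <- try(suppressWarnings(file(path, "w")), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("cannot write to ", path, call. = FALSE)
  on.exit(close(con))
  lines <- sprintf("type=%s", cls[1L])
  for (nm in names(record)) {
    v <- record[[nm]]
    if (is.null(v)) next
    if (is.list(v)) {
      for (sub in names(v))
        lines <- c(lines, sprintf("%s.%s=%s", nm, sub,
                                  .serialize_value(v[[sub]])))
    } else {
      lines <- c(lines, sprintf("%s=%s", nm, .serialize_value(v)))
    }
  }
  writeLines(lines, con)
  invisible(path)
}

.deserialize_value <- function(s, proto) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1L]]
  if (is.character(proto)) parts
  else if (is.logical(proto)) as.logical(parts)
  else if (is.integer(proto)) as.integer(as.numeric(parts))
  else as.numeric(parts)
}

#' Read a result record written by [write_results()]
#'
#' @param path Path to a result file.
#' @return The reconstructed record, with its original class.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  keys <- sub("=.*$", "", lines)
  vals <- sub("^[^=]*=", "", lines)
  if (keys[1L] != "type" || !(vals[1L] %in% .result_classes))
    stop("not a recognized result record: ", path, call. = FALSE)
  type <- vals[1L]
  out <- list()
  for (i in seq_along(keys)[-1L]) {
    k <- keys[i]
    parts <- strsplit(k, ".", fixed = TRUE)[[1L]]
    # Guess the field type from its serialized form.
    v <- vals[i]
    proto <- if (grepl("^(TRUE|FALSE)(,(TRUE|FALSE))*$", v)) logical()
             else if (suppressWarnings(!anyNA(as.numeric(
               strsplit(v, ",", fixed = TRUE)[[1L]])))) numeric()
             else character()
    parsed <- .deserialize_value(v, proto)
    if (length(parts) == 2L) {
      if (is.null(out[[parts[1L]]])) out[[parts[1L]]] <- list()
      out[[parts[1L]]][[parts[2L]]] <- parsed
    } else {
      out[[k]] <- parsed
    }
  }
  class(out) <- type
  out
}

#' Read an analysis configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [analysis_config()]; unknown
#' keys are an error so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML config file.
#' @return An [analysis_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  kv <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  extra <- setdiff(names(kv), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  do.call(analysis_config, kv)
}
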