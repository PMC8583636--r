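#' Validate an acceleration stream
#'
#' An acceleration stream is a plain data frame with columns `t` (seconds),
#' `ax`, `ay`, `az` (m/s^2), uniformly sampled. The device x axis is aligned
#' with the trunk-longitudinal axis when standing, so at upright rest
#' `ax` is close to gravity and `ay`, `az` to zero.
#'
#' @param stream data frame with columns `t, ax, ay, az`.
#' @return the stream as a tibble (invisibly validated).
#' @export
as_accel_stream <- function(stream) {
  stream <- validate_stream(stream, c("t", "ax", "ay", "az"), "accel stream")
  stream
}

#' Validate a respiratory stream
#'
#' A respiratory stream is a data frame with columns `t` (seconds) and
#' `amplitude` (dimensionless, proportional to thoraco-abdominal expansion;
#' rising amplitude is inspiration).
#'
#' @param resp data frame with columns `t, amplitude`.
#' @return the stream as a tibble.
#' @export
as_resp_stream <- function(resp) {
  validate_stream(resp, c("t", "amplitude"), "respiratory stream")
}

validate_stream <- function(stream, cols, what) {
  if (!is.data.frame(stream)) {
    stop("invalid ", what, ": expected a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(cols, names(stream))
  if (length(missing_cols) > 0) {
    stop("invalid ", what, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(stream) == 0) {
    stop("invalid ", what, ": stream is empty", call. = FALSE)
  }
  dt <- diff(stream$t)
  if (length(dt) > 0 && (any(dt <= 0) || diff(range(dt)) > 1e-6)) {
    stop("invalid ", what, ": `t` must be strictly increasing and uniform",
         call. = FALSE)
  }
  tibble::as_tibble(stream)
}

#' Sampling rate of a stream
#'
#' @param stream data frame with a `t` column.
#' @return sampling rate in Hz.
#' @export
stream_fs <- function(stream) {
  if (nrow(stream) < 2) return(NA_real_)
  1 / stats::median(diff(stream$t))
}

stream_magnitude <- function(stream) {
  sqrt(stream$ax^2 + stream$ay^2 + stream$az^2)
}

# ---- labeled streams (generator output) -------------------------------------

new_labeled_stream <- function(stream, channel, kind, labels, truth, seed) {
  structure(
    list(stream = tibble::as_tibble(stream), channel = channel, kind = kind,
         labels = tibble::as_tibble(labels), truth = truth, seed = seed,
         fs = stream_fs(stream)),
    class = "labeled_stream"
  )
}

#' @export
print.labeled_stream <- function(x, ...) {
  span <- range(x$stream$t)
  cat(sprintf("<labeled_stream> %s (%s), %.1f s at %g Hz, seed %s\n",
              x$kind, x$channel, diff(span) + 1 / x$fs, x$fs,
              format(x$seed)))
  cat(sprintf("  labels: %d segment(s); truth: %s\n", nrow(x$labels),
              paste(names(x$truth), collapse = ", ")))
  invisible(x)
}

#' Extract the ground truth of a generated stream
#'
#' @param x a `labeled_stream`.
#' @return the truth list (fall times, repetition counts, breath boundaries,
#'   depending on the generator).
#' @export
stream_truth <- function(x) {
  stopifnot(inherits(x, "labeled_stream"))
  x$truth
}

# ---- file IO ----------------------------------------------------------------

#' Read and write signal streams
#'
#' CSV streams use the headers `t,ax,ay,az` (acceleration, m/s^2) and
#' `t,amplitude` (respiration, arbitrary units). JSONL streams hold one
#' sample object per line with the same fields. `write_truth_sidecar()`
#' stores a generated stream's labels and ground truth as a JSON sidecar
#' next to the signal file.
#'
#' @param path file path.
#' @param stream a stream data frame.
#' @return read functions return a validated tibble; write functions return
#'   `path` invisibly.
#' @name stream_io
NULL

#' @rdname stream_io
#' @export
read_accel_csv <- function(path) {
  as_accel_stream(utils::read.csv(path))
}

#' @rdname stream_io
#' @export
read_resp_csv <- function(path) {
  as_resp_stream(utils::read.csv(path))
}

#' @rdname stream_io
#' @export
write_stream_csv <- function(stream, path) {
  utils::write.csv(stream, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname stream_io
#' @export
read_stream_jsonl <- function(path) {
  df <- jsonlite::stream_in(file(path), verbose = FALSE)
  if ("amplitude" %in% names(df)) as_resp_stream(df) else as_accel_stream(df)
}

#' @rdname stream_io
#' @export
write_stream_jsonl <- function(stream, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  jsonlite::stream_out(as.data.frame(stream), con, verbose = FALSE,
                       digits = NA)
  invisible(path)
}

#' @param x a `labeled_stream`.
#' @rdname stream_io
#' @export
write_truth_sidecar <- function(x, path) {
  stopifnot(inherits(x, "labeled_stream"))
  payload <- list(kind = x$kind, channel = x$channel, seed = x$seed,
                  labels = x$labels, truth = x$truth)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname stream_io
#' @export
read_truth_sidecar <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
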