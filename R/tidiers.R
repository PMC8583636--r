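# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a protocol evaluation
#'
#' @param x a `protocol_eval` from [evaluate_protocol()].
#' @param ... unused.
#' @return `tidy()`: the per-stream scoring tibble. `glance()`: a one-row
#'   tibble with `sensitivity`, `specificity`, `n_falls`, `n_fall_free`.
#' @export
tidy.protocol_eval <- function(x, ...) {
  x$per_stream
}

#' @rdname tidy.protocol_eval
#' @export
glance.protocol_eval <- function(x, ...) {
  tibble::tibble(sensitivity = x$sensitivity, specificity = x$specificity,
                 n_falls = x$n_falls, n_fall_free = x$n_fall_free)
}

#' Tidy a repetition count
#'
#' @param x a `rep_count` from [count_repetitions()].
#' @param ... unused.
#' @return `tidy()`: the accepted cycles tibble. `glance()`: a one-row
#'   summary with the count and rejection diagnostics.
#' @export
tidy.rep_count <- function(x, ...) {
  x$cycles
}

#' @rdname tidy.rep_count
#' @export
glance.rep_count <- function(x, ...) {
  tibble::tibble(exercise = x$exercise, n_repetitions = x$n_repetitions,
                 n_rejected_period = x$n_rejected_period,
                 n_rejected_rest = x$n_rejected_rest)
}

#' Tidy a metabolic expenditure report
#'
#' @param x a `met_report` from [estimate_met()].
#' @param ... unused.
#' @return `tidy()`: the per-epoch tibble. `glance()`: one row with the
#'   cumulative expenditure and epoch count.
#' @export
tidy.met_report <- function(x, ...) {
  x$epochs
}

#' @rdname tidy.met_report
#' @export
glance.met_report <- function(x, ...) {
  tibble::tibble(n_epochs = nrow(x$epochs),
                 cumulative_kcal = x$cumulative_kcal,
                 mean_met = if (nrow(x$epochs)) mean(x$epochs$met) else NA_real_,
                 weight = x$weight)
}

#' Tidy a labeled stream
#'
#' @param x a `labeled_stream`.
#' @param ... unused.
#' @return `tidy()`: the signal samples with an attached `label` column.
#'   `glance()`: one row of stream metadata.
#' @export
tidy.labeled_stream <- function(x, ...) {
  s <- x$stream
  s$label <- NA_character_
  for (i in seq_len(nrow(x$labels))) {
    sel <- s$t >= x$labels$start[i] & s$t < x$labels$end[i]
    s$label[sel] <- x$labels$label[i]
  }
  s
}

#' @rdname tidy.labeled_stream
#' @export
glance.labeled_stream <- function(x, ...) {
  tibble::tibble(kind = x$kind, channel = x$channel, fs = x$fs,
                 duration = max(x$stream$t) - min(x$stream$t) + 1 / x$fs,
                 n_labels = nrow(x$labels), seed = x$seed)
}
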