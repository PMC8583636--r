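# Stage-1 processing, as performed on the wearable impact detector: a
# windowed-energy statistic on the acceleration magnitude, candidate impact
# extraction with 2 s of context on each side, and the 20-byte block framing
# used to ship excerpts over the BLE attribute channel.

IMPACT_ENERGY_WINDOW <- 21L   # 0.5 s at 40 Hz, spans one impact transient
IMPACT_CONTEXT_S <- 2         # excerpt context before/after the impact
IMPACT_REFRACTORY_S <- 4      # no two impacts closer than the window length

#' Windowed signal energy of an acceleration stream
#'
#' For every sample, the variance (in m^2/s^4) of the acceleration magnitude
#' over a centered window of `window_len` samples; at the stream edges the
#' window shrinks to the available samples. The variance removes the DC
#' (gravity) component, so the series is invariant under adding a constant
#' vector to every sample.
#'
#' @param stream an acceleration stream (`t, ax, ay, az`).
#' @param window_len window length in samples; odd, >= 3. The default (21,
#'   i.e. 0.5 s at 40 Hz) spans an impact transient.
#' @return A numeric vector, one energy value per sample, non-negative.
#' @examples
#' s <- tibble::tibble(t = (0:99) / 40, ax = 9.81, ay = 0, az = 0)
#' all(signal_energy(s) == 0)
#' @export
signal_energy <- function(stream, window_len = IMPACT_ENERGY_WINDOW) {
  stream <- as_accel_stream(stream)
  if (window_len < 3 || window_len %% 2 == 0) {
    stop("signal_energy: `window_len` must be odd and >= 3", call. = FALSE)
  }
  mag <- stream_magnitude(stream)
  moving_var(mag, window_len)
}

# centered moving sample variance with shrinking edge windows; the series is
# centered first so the prefix-sum arithmetic stays well conditioned around
# the 9.81 m/s^2 gravity offset
moving_var <- function(x, window_len) {
  n <- length(x)
  x <- x - mean(x)
  h <- (window_len - 1L) %/% 2L
  s1 <- cumsum(c(0, x))
  s2 <- cumsum(c(0, x^2))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  nw <- hi - lo + 1
  sm <- s1[hi + 1] - s1[lo]
  sq <- s2[hi + 1] - s2[lo]
  v <- (sq - sm^2 / nw) / (nw - 1)
  v[nw < 2] <- 0
  pmax(v, 0)
}

#' Detect candidate impacts (stage 1)
#'
#' Scans the 40 Hz stream for local maxima of the windowed energy series
#' exceeding the fall energy threshold and emits one excerpt window per
#' candidate, carrying the samples from 2 s before to 2 s after the impact
#' (161 samples; shorter and flagged `truncated` when the impact lies within
#' 2 s of a stream boundary). A refractory period suppresses secondary
#' bounces: of any two candidates closer than 4 s, only the higher-energy
#' one is kept.
#'
#' @param stream an acceleration stream (`t, ax, ay, az`).
#' @param config a [detector_config()].
#' @return A tibble of impact windows: `impact_index`, `impact_time`,
#'   `peak_energy`, `truncated`, and a `window` list-column holding each
#'   excerpt as a tibble. Zero rows when no exceedance occurs (including for
#'   streams shorter than one energy window).
#' @examples
#' ls <- gen_fall("fall_knees", 10, noise_sd = 0, seed = 3)
#' nrow(detect_impacts(ls$stream, detector_config()))
#' @export
detect_impacts <- function(stream, config = detector_config()) {
  stream <- as_accel_stream(stream)
  n <- nrow(stream)
  empty <- tibble::tibble(impact_index = integer(0), impact_time = numeric(0),
                          peak_energy = numeric(0), truncated = logical(0),
                          window = list())
  if (n < IMPACT_ENERGY_WINDOW) return(empty)
  fs <- stream_fs(stream)
  e <- signal_energy(stream)
  above <- which(e >= config$fall_energy_threshold)
  if (length(above) == 0) return(empty)
  # local maxima of the energy series (plateaus: first sample of the run)
  is_max <- vapply(above, function(i) {
    left <- if (i > 1) e[i - 1] else -Inf
    right <- if (i < n) e[i + 1] else -Inf
    e[i] > left && e[i] >= right
  }, TRUE)
  cand <- above[is_max]
  if (length(cand) == 0) return(empty)
  # refractory suppression, strongest candidate first
  cand <- cand[order(e[cand], decreasing = TRUE)]
  keep <- integer(0)
  min_gap <- IMPACT_REFRACTORY_S * fs
  for (i in cand) {
    if (all(abs(i - keep) >= min_gap)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  half <- round(IMPACT_CONTEXT_S * fs)
  rows <- purrr::map(keep, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    tibble::tibble(
      impact_index = i,
      impact_time = stream$t[i],
      peak_energy = e[i],
      truncated = (hi - lo) < 2L * half,
      window = list(stream[lo:hi, ])
    )
  })
  dplyr::bind_rows(rows)
}

# ---- 20-byte block framing codec --------------------------------------------

CODEC_BLOCK_BYTES <- 20L
CODEC_FULL_SCALE <- 16 * 9.80665          # +/- 16 g, signed 16-bit
CODEC_QUANTUM <- CODEC_FULL_SCALE / 32767

#' Serialize an impact window into 20-byte transfer blocks
#'
#' Emulates the BLE attribute framing used to ship an impact excerpt to the
#' gateway: a 20-byte header block (impact index, impact time, sample count,
#' truncation flag, peak energy) followed by the samples packed as signed
#' 16-bit little-endian fixed point (+/- 16 g full scale, three axes per
#' sample, 6 bytes) into consecutive 20-byte blocks, zero-padded at the tail.
#' `unpack_frames()` inverts the framing; the round trip reproduces every
#' sample to within one codec quantum (~0.0048 m/s^2).
#'
#' @param window one row of the tibble returned by [detect_impacts()] (or a
#'   list with fields `impact_index`, `impact_time`, `truncated`,
#'   `peak_energy`, `window`).
#' @return `pack_frames()`: a list of raw vectors, each of length 20.
#' @examples
#' w <- detect_impacts(gen_fall("fall_knees", 10, 0, 3)$stream)[1, ]
#' length(pack_frames(w))
#' @export
pack_frames <- function(window) {
  w <- normalize_window(window)
  samples <- w$window
  vals <- c(t(as.matrix(samples[, c("ax", "ay", "az")])))
  if (any(abs(vals) > CODEC_FULL_SCALE)) {
    stop("pack_frames: sample outside the +/- 16 g codec range", call. = FALSE)
  }
  q <- as.integer(round(vals / CODEC_QUANTUM))
  header <- c(
    writeBin(as.integer(w$impact_index), raw(), size = 4, endian = "little"),
    writeBin(as.double(w$impact_time), raw(), size = 8, endian = "little"),
    writeBin(as.integer(nrow(samples)), raw(), size = 2, endian = "little"),
    as.raw(as.integer(isTRUE(w$truncated))),
    as.raw(0L),
    writeBin(as.double(w$peak_energy), raw(), size = 4, endian = "little")
  )
  body <- writeBin(q, raw(), size = 2, endian = "little")
  payload <- c(header, body)
  pad <- (-length(payload)) %% CODEC_BLOCK_BYTES
  payload <- c(payload, raw(pad))
  split(payload, ceiling(seq_along(payload) / CODEC_BLOCK_BYTES))
}

#' @param blocks a list of 20-byte raw vectors from [pack_frames()].
#' @rdname pack_frames
#' @return `unpack_frames()`: a one-row tibble in the [detect_impacts()]
#'   layout (sample times reconstructed from the impact time at 40 Hz).
#' @export
unpack_frames <- function(blocks) {
  if (!is.list(blocks) || length(blocks) < 1) {
    stop("unpack_frames: framing error (no blocks)", call. = FALSE)
  }
  sizes <- lengths(blocks)
  if (any(sizes != CODEC_BLOCK_BYTES)) {
    stop("unpack_frames: framing error (block of ",
         sizes[which(sizes != CODEC_BLOCK_BYTES)[1]], " bytes, expected 20)",
         call. = FALSE)
  }
  payload <- do.call(c, blocks)
  impact_index <- readBin(payload[1:4], "integer", size = 4, endian = "little")
  impact_time <- readBin(payload[5:12], "double", size = 8, endian = "little")
  n_samples <- readBin(payload[13:14], "integer", size = 2, endian = "little",
                       signed = FALSE)
  truncated <- as.integer(payload[15]) == 1L
  peak_energy <- readBin(payload[17:20], "double", size = 4, endian = "little")
  need <- 20L + 6L * n_samples
  if (length(payload) < need) {
    stop("unpack_frames: framing error (payload shorter than sample count)",
         call. = FALSE)
  }
  q <- readBin(payload[21:need], "integer", n = 3L * n_samples, size = 2,
               endian = "little")
  m <- matrix(q * CODEC_QUANTUM, ncol = 3, byrow = TRUE)
  fs <- FW_FS
  # the impact sample sits 2 s in, unless the head was truncated
  pre <- min(round(IMPACT_CONTEXT_S * fs), impact_index - 1L)
  t0 <- impact_time - pre / fs
  samples <- tibble::tibble(t = t0 + (seq_len(n_samples) - 1) / fs,
                            ax = m[, 1], ay = m[, 2], az = m[, 3])
  tibble::tibble(impact_index = impact_index, impact_time = impact_time,
                 peak_energy = peak_energy, truncated = truncated,
                 window = list(samples))
}

normalize_window <- function(window) {
  if (is.data.frame(window)) {
    if (nrow(window) != 1) {
      stop("expected a single impact window (got ", nrow(window), " rows)",
           call. = FALSE)
    }
    list(impact_index = window$impact_index, impact_time = window$impact_time,
         peak_energy = window$peak_energy, truncated = window$truncated,
         window = window$window[[1]])
  } else if (is.list(window) && !is.null(window$window)) {
    w <- window
    if (is.list(w$window) && is.data.frame(w$window[[1]])) {
      w$window <- w$window[[1]]
    }
    w
  } else {
    stop("expected an impact window", call. = FALSE)
  }
}
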