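# shared fixture builders (all fixtures are generated in code)

FS <- 40
G <- 9.81

const_stream <- function(n = 200, ax = G, ay = 0, az = 0) {
  tibble::tibble(t = (seq_len(n) - 1) / FS, ax = ax, ay = ay, az = az)
}

# a 161-sample impact window around a prescribed vertical acceleration
# profile (m/s^2 deviation from gravity), gravity on the z axis
make_window <- function(av, impact_time, truncated = FALSE, peak_energy = 1) {
  t <- (0:160) / FS
  list(impact_index = round(impact_time * FS) + 1L,
       impact_time = impact_time,
       truncated = truncated,
       peak_energy = peak_energy,
       window = tibble::tibble(t = t, ax = 0, ay = 0, az = G + av))
}

# smooth partial free-fall profile: full-weightlessness hann dip of
# duration td followed by a braking spike of duration ti that returns the
# velocity to zero; closed-form net displacement -(A*td^2/4 + A*td*ti/4)
free_fall_profile <- function(td = 0.4, ti = 0.12, t_start = 1.9,
                              A = G, t = (0:160) / FS) {
  vi <- A * td / 2
  spike <- 2 * vi / ti
  dip <- ifelse(t >= t_start & t < t_start + td,
                sin(pi * (t - t_start) / td)^2, 0)
  brake <- ifelse(t >= t_start + td & t < t_start + td + ti,
                  sin(pi * (t - t_start - td) / ti)^2, 0)
  list(av = -A * dip + spike * brake,
       impact_time = t_start + td + ti / 2,
       closed_form = -(A * td^2 / 4 + A * td * ti / 4))
}

# independent brute-force impact scan: per-sample window variance computed
# directly with stats::var, then thresholding, local maxima and greedy
# refractory suppression written as plain loops
brute_force_impacts <- function(stream, threshold, window_len = 21,
                                refractory_s = 4) {
  mag <- sqrt(stream$ax^2 + stream$ay^2 + stream$az^2)
  n <- length(mag)
  h <- (window_len - 1) / 2
  e <- vapply(seq_len(n), function(i) {
    w <- mag[max(1, i - h):min(n, i + h)]
    if (length(w) < 2) 0 else stats::var(w)
  }, numeric(1))
  cand <- integer(0)
  for (i in seq_len(n)) {
    if (e[i] < threshold) next
    left <- if (i > 1) e[i - 1] else -Inf
    right <- if (i < n) e[i + 1] else -Inf
    if (e[i] > left && e[i] >= right) cand <- c(cand, i)
  }
  cand <- cand[order(e[cand], decreasing = TRUE)]
  keep <- integer(0)
  fs <- 1 / stats::median(diff(stream$t))
  for (i in cand) {
    if (all(abs(i - keep) >= refractory_s * fs)) keep <- c(keep, i)
  }
  sort(stream$t[keep])
}
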