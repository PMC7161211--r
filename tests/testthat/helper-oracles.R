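# Independent reference implementations used to cross-check the package's
# peak primitives. These work directly from the definitions (set-based
# exhaustive contour search rather than the package's outward walk) and are
# deliberately O(n^2)-ish: clarity over speed.

# Brute-force local maxima: enumerate every equal-valued plateau and keep
# those strictly above both neighbours, reporting the (lower) middle index.
oracle_local_maxima <- function(y) {
  n <- length(y)
  out <- integer(0)
  for (i in seq_len(n)) {
    l <- i
    while (l > 1 && y[l - 1] == y[i]) l <- l - 1
    r <- i
    while (r < n && y[r + 1] == y[i]) r <- r + 1
    if (l > 1 && r < n && y[l - 1] < y[i] && y[r + 1] < y[i] &&
        i == (l + r) %/% 2) {
      out <- c(out, i)
    }
  }
  out
}

# Exhaustive contour search for topographic prominence: on each side the
# stretch runs from the apex to the nearest strictly higher sample (or the
# signal end); the base is the lowest sample of the stretch, ties resolved
# towards the apex. Prominence is the apex above the higher of the two
# stretch minima.
oracle_prominence <- function(y, i) {
  n <- length(y)
  higher_l <- which(y[seq_len(i - 1)] > y[i])
  lstretch <- (if (length(higher_l)) max(higher_l) + 1L else 1L):(i - 1L)
  lmin <- min(y[lstretch])
  left_base <- max(lstretch[y[lstretch] == lmin])
  higher_r <- which(y[(i + 1):n] > y[i]) + i
  rstretch <- (i + 1L):(if (length(higher_r)) min(higher_r) - 1L else n)
  rmin <- min(y[rstretch])
  right_base <- min(rstretch[y[rstretch] == rmin])
  list(prominence = y[i] - max(lmin, rmin),
       left_base = left_base, right_base = right_base)
}

# Width at relative height from the piecewise-linear interpolant: on each
# side the crossing nearest the apex where the interpolant reaches the
# evaluation height, bounded by the bases.
oracle_width <- function(y, i, prominence, left_base, right_base,
                         rel_height = 0.5) {
  h <- y[i] - rel_height * prominence
  left_ip <- left_base
  for (j in seq(i, left_base)) {
    if (y[j] <= h) {
      left_ip <- if (y[j] == h) j else j + (h - y[j]) / (y[j + 1] - y[j])
      break
    }
  }
  right_ip <- right_base
  for (j in seq(i, right_base)) {
    if (y[j] <= h) {
      right_ip <- if (y[j] == h) j else j - (h - y[j]) / (y[j - 1] - y[j])
      break
    }
  }
  right_ip - left_ip
}

# Small, fast simulation profile for module tests: 8-minute run, 10 peaks.
small_test_profile <- function(noise_sd = 0, ...) {
  base <- list(
    duration_min = 8, dt_min = 0.005,
    peak_rt = seq(0.6, 7.4, length.out = 10),
    peak_height = c(6000, 9000, 12000, 5000, 20000,
                    8000, 15000, 7000, 10000, 6500),
    peak_sigma = rep(0.04, 10),
    baseline_level = 1000, baseline_drift = 10,
    noise_sd = noise_sd, rt_jitter_sd = 0.01, height_cv = 0.1,
    n_subjects = 3)
  args <- utils::modifyList(base, list(...))
  do.call(sim_profile, args)
}

random_test_signal <- function(n) {
  sample(0:9, n, replace = TRUE)
}
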