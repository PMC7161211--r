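#' Retention windows of interest
#'
#' The three retention ranges in which exposure-related intensity changes are
#' summarized: readily volatile compounds elute early (`[0, 4)` min),
#' semi-volatile compounds in the mid window (`[16, 19]` min), and hardly
#' volatile compounds late (`(30, duration]` min).
#'
#' @param duration_min Run length in minutes (upper edge of the late window).
#' @return A tibble with columns `window`, `lo`, `hi`, `lo_closed`,
#'   `hi_closed`.
#' @export
rt_windows <- function(duration_min = 45) {
  tibble::tibble(
    window = c("early", "mid", "late"),
    lo = c(0, 16, 30),
    hi = c(4, 19, duration_min),
    lo_closed = c(TRUE, TRUE, FALSE),
    hi_closed = c(FALSE, TRUE, TRUE))
}

# Logical membership of retention times in one window row.
in_window <- function(rt, w) {
  lo_ok <- if (w$lo_closed) rt >= w$lo else rt > w$lo
  hi_ok <- if (w$hi_closed) rt <= w$hi else rt < w$hi
  lo_ok & hi_ok
}

#' Construct a simulation profile
#'
#' All parameters of the synthetic breath-chromatogram generator: a library
#' of Gaussian (optionally exponentially modified) peaks, a linear baseline,
#' additive Gaussian noise, subject-level variation, and per-condition
#' exposure effects acting inside the three retention windows of
#' [rt_windows()]. Condition `A` is the pre-exposure reference: its effect
#' factors are fixed at 1 and its baseline elevations at 0.
#'
#' @param duration_min Run length, minutes.
#' @param dt_min Sampling interval, minutes.
#' @param peak_rt,peak_height,peak_sigma Per-peak apex positions (min),
#'   heights above local baseline (intensity units) and Gaussian widths (min).
#' @param peak_tau Optional per-peak exponential tail constants (min); `NA`
#'   entries stay pure Gaussian.
#' @param baseline_level Constant baseline offset, intensity units.
#' @param baseline_drift Linear baseline slope, intensity units per minute.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param rt_jitter_sd Per-subject apex jitter, minutes.
#' @param height_cv Log-normal coefficient of variation of peak heights
#'   across subjects.
#' @param effect Named list `list(A = , B = , C = )`; each element a list
#'   with `factor` and `elevation`, numeric vectors named
#'   `early`/`mid`/`late`: multiplicative height factors for peaks whose apex
#'   falls in the window, and additive baseline elevation inside the window.
#' @param n_subjects Cohort size; each subject contributes one sample per
#'   condition.
#' @return A validated object of class `sim_profile`.
#' @export
sim_profile <- function(duration_min = 45, dt_min = 0.005,
                        peak_rt = numeric(0), peak_height = numeric(0),
                        peak_sigma = numeric(0), peak_tau = NULL,
                        baseline_level = 0, baseline_drift = 0,
                        noise_sd = 0, rt_jitter_sd = 0, height_cv = 0,
                        effect = null_effect(), n_subjects = 16) {
  p <- structure(list(
    duration_min = duration_min, dt_min = dt_min,
    peak_rt = peak_rt, peak_height = peak_height, peak_sigma = peak_sigma,
    peak_tau = peak_tau,
    baseline_level = baseline_level, baseline_drift = baseline_drift,
    noise_sd = noise_sd, rt_jitter_sd = rt_jitter_sd, height_cv = height_cv,
    effect = effect, n_subjects = n_subjects), class = "sim_profile")
  validate_sim_profile(p)
}

#' Null (no exposure effect) condition configuration
#' @return Effect list with all factors 1 and all elevations 0.
#' @export
null_effect <- function() {
  one <- c(early = 1, mid = 1, late = 1)
  zero <- c(early = 0, mid = 0, late = 0)
  list(A = list(factor = one, elevation = zero),
       B = list(factor = one, elevation = zero),
       C = list(factor = one, elevation = zero))
}

validate_sim_profile <- function(p) {
  if (p$duration_min <= 0 || p$dt_min <= 0) {
    abort_validation("duration_min and dt_min must be positive")
  }
  np <- length(p$peak_rt)
  if (length(p$peak_height) != np || length(p$peak_sigma) != np) {
    abort_validation("peak_rt, peak_height, peak_sigma must have equal length")
  }
  if (np > 0) {
    if (any(p$peak_rt < 0 | p$peak_rt > p$duration_min)) {
      abort_validation("all peak_rt must lie within [0, duration_min]")
    }
    if (any(p$peak_height <= 0)) abort_validation("all peak heights must be positive")
    if (any(p$peak_sigma <= 0)) abort_validation("all peak sigmas must be positive")
  }
  if (p$noise_sd < 0) abort_validation("noise_sd must be non-negative")
  for (cn in c("A", "B", "C")) {
    e <- p$effect[[cn]]
    if (is.null(e) || !all(c("early", "mid", "late") %in% names(e$factor)) ||
        !all(c("early", "mid", "late") %in% names(e$elevation))) {
      abort_validation(sprintf(
        "effect$%s must supply factor and elevation for early/mid/late", cn))
    }
  }
  if (any(p$effect$A$factor != 1) || any(p$effect$A$elevation != 0)) {
    abort_validation("condition A is the reference: factors 1, elevations 0")
  }
  if (p$n_subjects < 1) abort_validation("n_subjects must be at least 1")
  p
}

#' Default breath-study simulation profile
#'
#' The package's documented preset for a synthetic breath cohort: a 45-minute
#' run sampled every 0.005 min (0.3 s, 9001 scans), a frozen library of 125
#' peaks spread over 0.5-44 min with log-normal heights (truncated below at
#' 4500 intensity units) and widths of 0.025-0.06 min, a gently drifting
#' baseline, additive noise of sd 300, and a 16-subject three-condition
#' design. The library is drawn once from a fixed internal random stream and
#' is therefore a constant of the package. Under the default detection
#' parameters (prominence 3000, width 8 samples) the simulated signals carry
#' 100-150 detectable peaks.
#'
#' Exposure effects: condition B (immediately post-exposure) raises peak
#' heights and baseline in all three windows, strongest in the mid
#' (semi-volatile, 16-19 min) window; condition C (2 h post) sits between A
#' and B.
#'
#' @return A `sim_profile`.
#' @export
default_breath_profile <- function() {
  lib <- withr::with_seed(74120L, {
    n <- 125L
    rt <- 0.5 + (seq_len(n) - 1) * (43.5 / (n - 1)) +
      stats::runif(n, -0.04, 0.04)
    list(rt = rt,
         height = pmax(stats::rlnorm(n, log(12000), 0.6), 4500),
         sigma = stats::runif(n, 0.025, 0.06))
  })
  sim_profile(
    duration_min = 45, dt_min = 0.005,
    peak_rt = lib$rt, peak_height = lib$height, peak_sigma = lib$sigma,
    baseline_level = 2000, baseline_drift = 20,
    noise_sd = 300, rt_jitter_sd = 0.02, height_cv = 0.2,
    effect = list(
      A = list(factor = c(early = 1, mid = 1, late = 1),
               elevation = c(early = 0, mid = 0, late = 0)),
      B = list(factor = c(early = 1.25, mid = 1.8, late = 1.6),
               elevation = c(early = 150, mid = 600, late = 450)),
      C = list(factor = c(early = 1.1, mid = 1.4, late = 1.3),
               elevation = c(early = 75, mid = 300, late = 225))),
    n_subjects = 16)
}

# Unit-height peak shape evaluated on grid t; Gaussian, or exponentially
# modified Gaussian when tau is finite and positive.
peak_shape <- function(t, mu, sigma, tau = NA) {
  if (is.na(tau) || tau <= 0) {
    return(exp(-(t - mu)^2 / (2 * sigma^2)))
  }
  z <- sigma / (sqrt(2) * tau) - (t - mu) / (sqrt(2) * sigma)
  g <- exp(sigma^2 / (2 * tau^2) - (t - mu) / tau) * pracma::erfc(z)
  g / max(g)
}

# Noiseless expected signal for a per-sample peak configuration.
expected_signal <- function(t, p, rt, height, elevation_fun = NULL) {
  y <- p$baseline_level + p$baseline_drift * t
  dt <- p$dt_min
  tau <- p$peak_tau
  for (k in seq_along(rt)) {
    tk <- if (is.null(tau)) NA else tau[k]
    half <- 8 * p$peak_sigma[k] + if (is.na(tk) || tk <= 0) 0 else 8 * tk
    i0 <- max(1L, floor((rt[k] - half) / dt) + 1L)
    i1 <- min(length(t), ceiling((rt[k] + half) / dt) + 1L)
    idx <- i0:i1
    y[idx] <- y[idx] + height[k] * peak_shape(t[idx], rt[k], p$peak_sigma[k], tk)
  }
  if (!is.null(elevation_fun)) y <- y + elevation_fun(t)
  y
}

#' Simulate one breath chromatogram
#'
#' The signal is `baseline_level + baseline_drift * t` plus a sum of
#' unit-height Gaussian (or exponentially modified Gaussian) peaks scaled by
#' their heights, plus i.i.d. Gaussian noise of sd `noise_sd`. When a
#' `condition` other than `A` is given, the profile's exposure effect is
#' applied: peak heights are multiplied by the window factor of the window
#' their apex falls in, and the window baseline elevations are added. The
#' output is a pure function of `(profile, seed, condition)`.
#'
#' @param profile A [sim_profile()].
#' @param seed Integer seed for the noise draw; the global RNG state is left
#'   untouched.
#' @param condition `"A"` (default, no effect), `"B"` or `"C"`.
#' @param sample_id Sample identifier for the returned chromatogram.
#' @return A list with `chromatogram` (a [chromatogram()]) and `truth`, a
#'   tibble of per-peak ground truth: `peak`, `apex_rt`, `height` (above
#'   local baseline, after any condition factor), `sigma`, and `width_samples`
#'   (full width at half maximum in grid steps).
#' @export
simulate_chromatogram <- function(profile, seed, condition = "A",
                                  sample_id = paste0("sim", seed)) {
  p <- validate_sim_profile(profile)
  condition <- match.arg(condition, c("A", "B", "C"))
  t <- seq(0, p$duration_min, by = p$dt_min)
  wins <- rt_windows(p$duration_min)
  eff <- p$effect[[condition]]
  height <- p$peak_height
  if (length(height) > 0) {
    for (k in seq_len(nrow(wins))) {
      w <- wins[k, ]
      height[in_window(p$peak_rt, w)] <-
        height[in_window(p$peak_rt, w)] * eff$factor[[w$window]]
    }
  }
  elev <- function(t) {
    e <- numeric(length(t))
    for (k in seq_len(nrow(wins))) {
      w <- wins[k, ]
      e[in_window(t, w)] <- e[in_window(t, w)] + eff$elevation[[w$window]]
    }
    e
  }
  y <- expected_signal(t, p, p$peak_rt, height, elev)
  if (p$noise_sd > 0) {
    y <- y + withr::with_seed(as.integer(seed),
                              stats::rnorm(length(t), 0, p$noise_sd))
  }
  truth <- tibble::tibble(
    peak = seq_along(p$peak_rt),
    apex_rt = p$peak_rt,
    height = height,
    sigma = p$peak_sigma,
    width_samples = 2 * sqrt(2 * log(2)) * p$peak_sigma / p$dt_min)
  list(chromatogram = chromatogram(t, y, sample_id = sample_id),
       truth = truth)
}

#' Simulate a full exposure study
#'
#' Generates `n_subjects` x 3 samples with a repeated-measures structure:
#' each subject draws one set of apex-position jitters (sd `rt_jitter_sd`)
#' and one set of log-normal peak-height multipliers (mean 1, CV
#' `height_cv`), shared across that subject's three condition samples, so
#' that within-subject condition contrasts isolate the exposure effect.
#' Conditions B and C then apply the profile's window effects on top. All
#' randomness derives from the single `seed`.
#'
#' @param profile A [sim_profile()].
#' @param seed Integer master seed.
#' @return A list with `study` (a `study_set` of `n_subjects * 3` rows) and
#'   `truth`, a tibble of per-sample per-peak ground truth (`sample_id`,
#'   `subject_id`, `condition`, `peak`, `apex_rt`, `height`, `sigma`,
#'   `width_samples`).
#' @export
simulate_study <- function(profile, seed) {
  p <- validate_sim_profile(profile)
  np <- length(p$peak_rt)
  ns <- p$n_subjects
  sdlog <- sqrt(log(1 + p$height_cv^2))
  draws <- withr::with_seed(as.integer(seed), {
    list(
      jitter = matrix(stats::rnorm(ns * np, 0, p$rt_jitter_sd), nrow = ns),
      hmult = matrix(stats::rlnorm(ns * np, -sdlog^2 / 2, sdlog), nrow = ns),
      sample_seed = matrix(sample.int(.Machine$integer.max, ns * 3), nrow = ns))
  })
  subjects <- sprintf("s%02d", seq_len(ns))
  grid_df <- tidyr::expand_grid(subject = seq_len(ns),
                                condition = c("A", "B", "C"))
  sims <- purrr::pmap(grid_df, function(subject, condition) {
    ps <- p
    ps$peak_rt <- pmin(pmax(p$peak_rt + draws$jitter[subject, ], 0),
                       p$duration_min)
    ps$peak_height <- p$peak_height * draws$hmult[subject, ]
    sid <- paste0(subjects[subject], "_", condition)
    ci <- match(condition, c("A", "B", "C"))
    sim <- simulate_chromatogram(ps, draws$sample_seed[subject, ci],
                                 condition = condition, sample_id = sid)
    sim$truth$sample_id <- sid
    sim$truth$subject_id <- subjects[subject]
    sim$truth$condition <- condition
    sim
  })
  study <- new_study_set(tibble::tibble(
    sample_id = paste0(subjects[grid_df$subject], "_", grid_df$condition),
    subject_id = subjects[grid_df$subject],
    condition = factor(grid_df$condition, levels = c("A", "B", "C")),
    qc_pass = TRUE,
    qc_reason = NA_character_,
    chromatogram = purrr::map(sims, "chromatogram")))
  truth <- dplyr::bind_rows(purrr::map(sims, "truth"))
  truth <- truth[c("sample_id", "subject_id", "condition", "peak",
                   "apex_rt", "height", "sigma", "width_samples")]
  list(study = study, truth = truth)
}

#' Serialize / restore a simulation profile
#'
#' Profiles round-trip through a plain YAML key/value file so that a study
#' configuration can be archived next to its outputs and re-run exactly.
#'
#' @param profile A [sim_profile()].
#' @param path File path.
#' @return `write_sim_profile()` returns `path` invisibly;
#'   `read_sim_profile()` returns the restored `sim_profile`.
#' @export
write_sim_profile <- function(profile, path) {
  raw <- unclass(profile)
  # named atomic vectors serialize as YAML maps, not bare sequences
  raw$effect <- lapply(raw$effect, function(e) {
    list(factor = as.list(e$factor), elevation = as.list(e$elevation))
  })
  yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_profile
#' @export
read_sim_profile <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  raw <- yaml::read_yaml(path)
  eff <- lapply(raw$effect, function(e) {
    list(factor = unlist(e$factor), elevation = unlist(e$elevation))
  })
  sim_profile(
    duration_min = raw$duration_min, dt_min = raw$dt_min,
    peak_rt = as.numeric(raw$peak_rt),
    peak_height = as.numeric(raw$peak_height),
    peak_sigma = as.numeric(raw$peak_sigma),
    peak_tau = if (is.null(raw$peak_tau)) NULL else as.numeric(raw$peak_tau),
    baseline_level = raw$baseline_level, baseline_drift = raw$baseline_drift,
    noise_sd = raw$noise_sd, rt_jitter_sd = raw$rt_jitter_sd,
    height_cv = raw$height_cv, effect = eff, n_subjects = raw$n_subjects)
}
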