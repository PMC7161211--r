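test_that("resampling onto a grid is identity/linear where expected", {
  ch <- chromatogram(c(0, 1), c(0, 10))
  expect_equal(resample_to_grid(ch, 0.5), 5)
  ch2 <- chromatogram(seq(0, 2, by = 0.1), sin(seq(0, 2, by = 0.1)))
  expect_equal(resample_to_grid(ch2, ch2$rt), ch2$intensity)
  expect_warning(out <- resample_to_grid(ch, c(-1, 0.5, 2)), "outside")
  expect_equal(out, c(0, 5, 0))
  expect_error(resample_to_grid(ch, c(5, 6)), "overlap")
})

test_that("resampling a refined signal back reproduces the original closely", {
  prof <- small_test_profile(noise_sd = 0)
  ch <- simulate_chromatogram(prof, 0)$chromatogram
  fine <- seq(min(ch$rt), max(ch$rt), by = prof$dt_min / 2)
  refined <- chromatogram(fine, resample_to_grid(ch, fine))
  back <- resample_to_grid(refined, ch$rt)
  expect_equal(back, ch$intensity, tolerance = 0.01)
})

test_that("group means average resampled signals and respect QC", {
  t <- seq(0, 2, by = 0.1)
  mk <- function(level, sid, cond) {
    tibble::tibble(sample_id = sid, subject_id = sub("_.*", "", sid),
                   condition = factor(cond, levels = c("A", "B", "C")),
                   qc_pass = TRUE, qc_reason = NA_character_,
                   chromatogram = list(chromatogram(t, rep(level, length(t)),
                                                    sample_id = sid)))
  }
  study <- breathgc:::new_study_set(dplyr::bind_rows(
    mk(10, "s1_A", "A"), mk(20, "s2_A", "A"), mk(99, "s3_A", "A"),
    mk(40, "s1_B", "B")))
  study$qc_pass[3] <- FALSE
  expect_equal(group_mean(study, "A"), rep(15, length(t)))  # failed sample skipped
  expect_equal(group_mean(study, "B"), rep(40, length(t)))  # mean of one
  expect_error(group_mean(study, "C"), "condition C")
})

test_that("windowed summaries match closed forms and window conventions", {
  grid <- seq(0, 45, by = 0.005)
  const <- windowed_summary(rep(100, length(grid)), grid)
  expect_equal(const$mean, rep(100, 3))
  expect_equal(const$baseline, rep(100, 3))

  ramp <- windowed_summary(grid, grid)  # signal equal to retention time
  # half-open window: the mean over grid points 0 .. 4 - dt sits half a
  # grid step below the continuous midpoint
  expect_equal(ramp$mean[ramp$window == "early"], 2.0, tolerance = 2e-3)
  expect_equal(ramp$mean[ramp$window == "mid"], 17.5, tolerance = 1e-3)
  # late window is open at 30: its first contributing point is just above 30
  w <- rt_windows(45)
  sel <- breathgc:::in_window(grid, w[w$window == "late", ])
  expect_equal(min(grid[sel]), 30.005)
  expect_error(windowed_summary(grid, grid, tibble::tibble(
    window = "x", lo = 50, hi = 60, lo_closed = TRUE, hi_closed = TRUE)),
    "no grid points")
})

test_that("averaging and moving-average filtering commute", {
  prof <- small_test_profile(noise_sd = 150)
  sim <- simulate_study(prof, 9)
  grid <- common_grid(sim$study)
  spec <- filter_spec(51)
  filtered_then_mean <- group_mean(sim$study, "A", filter = spec, grid = grid)
  mean_then_filtered <- moving_average(group_mean(sim$study, "A", grid = grid),
                                       spec)
  expect_equal(filtered_then_mean, mean_then_filtered, tolerance = 1e-10)
})

test_that("group summary is internally consistent and window stats recompute", {
  prof <- small_test_profile(noise_sd = 100)
  sim <- simulate_study(prof, 12)
  wins <- tibble::tibble(window = c("lo", "hi"), lo = c(0.5, 4),
                         hi = c(3, 7), lo_closed = TRUE, hi_closed = TRUE)
  gs <- compare_groups(sim$study, filter = filter_spec(31), windows = wins)
  expect_equal(nrow(gs$means), 3 * length(gs$grid))
  expect_equal(nrow(gs$diff_curves), 3 * length(gs$grid))
  # diff curves really are differences of the means
  wide <- tidyr::pivot_wider(gs$means[c("rt", "condition", "raw")],
                             names_from = "condition", values_from = "raw")
  ba <- gs$diff_curves[gs$diff_curves$comparison == "B-A", ]
  expect_equal(ba$raw, wide$B - wide$A)
  # window stats equal the windowed summary of the stored mean signals
  for (cn in c("A", "B", "C")) {
    m <- gs$means[gs$means$condition == cn, ]
    ws <- windowed_summary(m$raw, m$rt, wins)
    got <- gs$window_stats[gs$window_stats$condition == cn, ]
    expect_equal(got$mean, ws$mean)
    expect_equal(got$baseline, ws$baseline)
  }
  expect_true(all(gs$window_stats$n_samples <= prof$n_subjects))
})

test_that("identical samples in all conditions give identically zero differences", {
  t <- seq(0, 10, by = 0.01)
  y <- 500 + 100 * sin(t) + 3000 * exp(-(t - 5)^2 / 0.1)
  rows <- purrr::map(c("A", "B", "C"), function(cond) {
    tibble::tibble(sample_id = paste0("s1_", cond), subject_id = "s1",
                   condition = factor(cond, levels = c("A", "B", "C")),
                   qc_pass = TRUE, qc_reason = NA_character_,
                   chromatogram = list(chromatogram(t, y)))
  })
  study <- breathgc:::new_study_set(dplyr::bind_rows(rows))
  gs <- compare_groups(study, filter = filter_spec(21),
                       windows = tibble::tibble(
                         window = "w", lo = 1, hi = 9,
                         lo_closed = TRUE, hi_closed = TRUE))
  expect_true(all(gs$diff_curves$raw == 0))
  expect_true(all(gs$diff_curves$filtered == 0))
})

test_that("tidy, glance and autoplot expose the comparison results", {
  prof <- small_test_profile(noise_sd = 100)
  sim <- simulate_study(prof, 2)
  wins <- tibble::tibble(window = "w", lo = 1, hi = 7,
                         lo_closed = TRUE, hi_closed = TRUE)
  gs <- compare_groups(sim$study, filter = filter_spec(31), windows = wins)
  td <- generics::tidy(gs)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  gl <- generics::glance(gs)
  expect_equal(gl$n_A, prof$n_subjects)
  expect_equal(gl$filter_window, 31L)
  expect_s3_class(ggplot2::autoplot(gs), "ggplot")
  expect_s3_class(plot_diff_curves(gs, "raw"), "ggplot")

  tab <- detect_peaks(sim$study$chromatogram[[1]], 2000, 5)
  expect_s3_class(ggplot2::autoplot(sim$study$chromatogram[[1]], peaks = tab),
                  "ggplot")
  expect_equal(generics::glance(tab)$n_peaks, nrow(tab))
  expect_named(generics::tidy(tab),
               c("sample_id", "apex_rt_min", "height", "prominence",
                 "width_samples", "width_min", "area", "left_base_rt",
                 "right_base_rt"))
})
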