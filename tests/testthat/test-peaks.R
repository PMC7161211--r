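test_that("local maxima follow the strict-neighbour and plateau conventions", {
  expect_equal(find_local_maxima(c(0, 1, 0)), 2L)
  expect_equal(find_local_maxima(c(0, 1, 2, 3)), integer(0))
  expect_equal(find_local_maxima(c(0, 2, 2, 2, 0)), 3L)
  expect_equal(find_local_maxima(c(0, 2, 2, 0)), 2L)   # lower middle of even plateau
  expect_equal(find_local_maxima(c(3, 1)), integer(0)) # too short
  expect_equal(find_local_maxima(c(0, 1, 0, 2, 0)), c(2L, 4L))
  # endpoints never count, even when largest
  expect_equal(find_local_maxima(c(5, 1, 4, 1, 6)), 3L)
})

test_that("local maxima agree with brute-force plateau enumeration", {
  withr::local_seed(421)
  for (rep in 1:300) {
    y <- random_test_signal(sample(3:40, 1))
    expect_identical(find_local_maxima(y), oracle_local_maxima(y))
  }
})

test_that("prominence matches hand-worked contour examples", {
  p <- peak_prominence(c(0, 5, 0), 2)
  expect_equal(p$prominence, 5)
  expect_equal(c(p$left_base, p$right_base), c(1L, 3L))

  y <- c(1, 3, 2, 4, 1)
  p <- peak_prominence(y, 4)
  expect_equal(p$prominence, 3)
  p <- peak_prominence(y, 2)
  expect_equal(p$prominence, 1)
  expect_equal(c(p$left_base, p$right_base), c(1L, 3L))

  expect_error(peak_prominence(c(0, 1, 2), 2), class = "breathgc_contract_error")
  expect_error(peak_prominence(c(2, 1, 2), 1), class = "breathgc_contract_error")
})

test_that("widths follow exact linear geometry at every relative height", {
  y <- c(0, 2, 4, 2, 0)
  p <- peak_prominence(y, 3)
  expect_equal(p$prominence, 4)
  w <- peak_width(y, 3, p$prominence, p$left_base, p$right_base, 0.5)
  expect_equal(w$eval_height, 2)
  expect_equal(c(w$left_ip, w$right_ip), c(2, 4))
  expect_equal(w$width_samples, 2)
  w0 <- peak_width(y, 3, p$prominence, p$left_base, p$right_base, 0)
  expect_equal(w0$width_samples, 0)
  w1 <- peak_width(y, 3, p$prominence, p$left_base, p$right_base, 1)
  expect_equal(w1$width_samples, 4)
  expect_error(peak_width(y, 3, p$prominence, p$left_base, p$right_base, 1.2),
               class = "breathgc_parameter_error")
})

test_that("chord-subtracted area matches closed forms", {
  expect_equal(peak_area(c(0, 4, 0), c(0, 1, 2), 1, 3), 4)
  expect_equal(peak_area(c(3, 3, 3), c(0, 1, 2), 1, 3), 0)
  # Gaussian peak area ~ h * sigma * sqrt(2*pi)
  prof <- small_test_profile(
    peak_rt = 4, peak_height = 5000, peak_sigma = 0.05,
    baseline_level = 0, baseline_drift = 0, noise_sd = 0)
  ch <- simulate_chromatogram(prof, 1)$chromatogram
  tab <- detect_peaks(ch)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$area, 5000 * 0.05 * sqrt(2 * pi), tolerance = 0.01)
})

test_that("prominence, bases and width equal the exhaustive contour oracle", {
  withr::local_seed(99)
  n_checked <- 0L
  for (rep in 1:400) {
    y <- random_test_signal(sample(5:64, 1))
    for (i in find_local_maxima(y)) {
      got <- peak_prominence(y, i)
      ref <- oracle_prominence(y, i)
      expect_identical(got$prominence, ref$prominence)
      expect_identical(got$left_base, ref$left_base)
      expect_identical(got$right_base, ref$right_base)
      w <- peak_width(y, i, got$prominence, got$left_base, got$right_base)
      expect_equal(w$width_samples,
                   oracle_width(y, i, got$prominence, got$left_base,
                                got$right_base), tolerance = 1e-12)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 500)
})

test_that("peak features agree with an external reference detector", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  prof <- small_test_profile(noise_sd = 200)
  ch <- simulate_chromatogram(prof, 17)$chromatogram
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(format(ch$intensity, digits = 17), f)
  out <- tryCatch(system2("python", c("-c", shQuote(paste0(
    "import numpy as np\n",
    "from scipy.signal import find_peaks\n",
    "y = np.loadtxt('", f, "')\n",
    "idx, props = find_peaks(y, prominence=2000, width=5)\n",
    "for i, p, l, r, w in zip(idx, props['prominences'], props['left_bases'],",
    " props['right_bases'], props['widths']):\n",
    "    print(i + 1, p, l + 1, r + 1, w)\n"))),
    stdout = TRUE, stderr = TRUE), warning = function(w) character(0))
  skip_if(length(out) == 0 || any(grepl("Error|Trace", out)),
          "scipy unavailable")
  ref <- read.table(text = out,
                    col.names = c("i", "prom", "lb", "rb", "width"))
  tab <- detect_peaks(ch, prominence_min = 2000, width_min = 5)
  expect_equal(tab$apex_index, ref$i)
  expect_equal(tab$prominence, ref$prom, tolerance = 1e-9)
  expect_equal(tab$left_base, ref$lb)
  expect_equal(tab$right_base, ref$rb)
  expect_equal(tab$width_samples, ref$width, tolerance = 1e-9)
})

test_that("detection is shift-invariant and scale-equivariant", {
  prof <- small_test_profile(noise_sd = 150)
  ch <- simulate_chromatogram(prof, 23)$chromatogram
  tab <- detect_peaks(ch, prominence_min = 2000, width_min = 5)
  expect_gt(nrow(tab), 3)

  shifted <- chromatogram(ch$rt, ch$intensity + 5000)
  tab_s <- detect_peaks(shifted, prominence_min = 2000, width_min = 5)
  expect_equal(tab_s$prominence, tab$prominence)
  expect_equal(tab_s$width_samples, tab$width_samples)
  expect_equal(tab_s$area, tab$area, tolerance = 1e-9)
  expect_equal(tab_s$height, tab$height + 5000)

  scaled <- chromatogram(ch$rt, ch$intensity * 2.5)
  tab_c <- detect_peaks(scaled, prominence_min = 2000 * 2.5, width_min = 5)
  expect_equal(tab_c$prominence, tab$prominence * 2.5, tolerance = 1e-12)
  expect_equal(tab_c$width_samples, tab$width_samples, tolerance = 1e-12)
  expect_equal(tab_c$area, tab$area * 2.5, tolerance = 1e-9)
})

test_that("raising either threshold never increases the peak count", {
  prof <- small_test_profile(noise_sd = 250)
  ch <- simulate_chromatogram(prof, 31)$chromatogram
  n_prom <- sapply(c(500, 1000, 2000, 4000, 8000), function(p) {
    nrow(detect_peaks(ch, prominence_min = p, width_min = 5))
  })
  expect_true(all(diff(n_prom) <= 0))
  n_wid <- sapply(c(2, 5, 8, 12, 20), function(w) {
    nrow(detect_peaks(ch, prominence_min = 1000, width_min = w))
  })
  expect_true(all(diff(n_wid) <= 0))
})

test_that("detector recovers an isolated injected peak at its true position", {
  prof <- small_test_profile(
    peak_rt = 4, peak_height = 30000, peak_sigma = 0.12,
    baseline_level = 500, baseline_drift = 0, noise_sd = 0)
  ch <- simulate_chromatogram(prof, 1)$chromatogram
  tab <- detect_peaks(ch, prominence_min = 3000, width_min = 8)
  expect_equal(nrow(tab), 1)
  expect_lt(abs(tab$apex_rt_min - 4), prof$dt_min + 1e-12)
  expect_equal(tab$height, max(ch$intensity))

  flat <- chromatogram(seq(0, 1, by = 0.01), rep(100, 101))
  expect_equal(nrow(detect_peaks(flat)), 0)
  expect_error(detect_peaks(ch, prominence_min = -1),
               class = "breathgc_parameter_error")
})
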