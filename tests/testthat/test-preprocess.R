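# R-level oracle for the despiking rule: windowed median / MAD, point by
# point, independent of the compiled implementation.
despike_oracle <- function(y, half, factor) {
  n <- length(y)
  out <- y
  for (i in seq_len(n)) {
    win <- y[max(1, i - half):min(n, i + half)]
    med <- median(win)
    thr <- factor * mad(win, center = med) +
      1e-12 * max(1, abs(med))
    if (abs(y[i] - med) > thr) out[i] <- med
  }
  out
}

test_that("despiking removes spikes and leaves smooth structure untouched", {
  grid <- seq(300, 500, by = 1)
  flat <- tibble::tibble(wavenumber = grid, intensity = rep(10, length(grid)))
  flat$intensity[77] <- 10000
  fixed <- despike(flat, 4, 6)
  expect_equal(fixed$intensity[77], 10)
  expect_equal(fixed$intensity[-77], rep(10, length(grid) - 1))
  expect_equal(attr(fixed, "spikes"), 77L)

  smooth <- gauss_spectrum(400, 20, grid)
  expect_equal(despike(smooth, 4, 6)$intensity, smooth$intensity)
  # brute-force check that no smooth point exceeds the threshold
  expect_equal(despike_oracle(smooth$intensity, 4, 6), smooth$intensity)
})

test_that("despiking matches the windowed-median oracle on noisy data", {
  withr::with_seed(4, {
    y <- 5 + sin(seq(0, 6, length.out = 400)) + rnorm(400, 0, 0.1)
    spikes <- sample(400, 6)
    y[spikes] <- y[spikes] + runif(6, 5, 50)
  })
  s <- tibble::tibble(wavenumber = seq_along(y), intensity = y)
  expect_equal(despike(s, 4, 6)$intensity, despike_oracle(y, 4, 6))
})

test_that("adjacent spikes are removed and despiking is idempotent", {
  withr::with_seed(8, {
    truth <- gauss_spectrum(400, 30, seq(300, 500, 1), amplitude = 3)
    noisy <- truth
    noisy$intensity <- noisy$intensity + rnorm(nrow(noisy), 0, 0.02)
    spiked <- noisy
    spiked$intensity[100:101] <- spiked$intensity[100:101] + c(40, 25)
  })
  fixed <- despike(spiked, 4, 6)
  expect_lt(sqrt(mean((fixed$intensity - truth$intensity)^2)), 0.02 * 2)
  expect_equal(despike(fixed, 4, 6)$intensity, fixed$intensity)
  expect_error(despike(truth[1:5, ], 4, 6), "at least")
})

test_that("truncation and resampling produce the uniform target grid", {
  s <- gauss_spectrum(1000, 10, seq(250, 3450, by = 0.7))
  out <- truncate_resample(s, c(300, 3400), 1)
  expect_equal(nrow(out), 3101)
  expect_equal(out$wavenumber, seq(300, 3400, 1))

  on_grid <- gauss_spectrum(1000, 10, seq(300, 3400, 1))
  expect_equal(truncate_resample(on_grid, c(300, 3400), 1)$intensity,
               on_grid$intensity)

  ramp <- tibble::tibble(wavenumber = seq(300, 3400, 2),
                         intensity = 2 * seq(300, 3400, 2) + 5)
  res <- truncate_resample(ramp, c(300, 3400), 1)
  expect_equal(res$intensity, 2 * res$wavenumber + 5)

  expect_error(truncate_resample(gauss_spectrum(500, 5, seq(400, 3400, 1)),
                                 c(300, 3400), 1), "lower end")
  expect_error(truncate_resample(gauss_spectrum(500, 5, seq(300, 2000, 1)),
                                 c(300, 3400), 1), "upper end")
})

test_that("AsLS reproduces a peak-free baseline and recovers a known line", {
  grid <- seq(300, 1300, by = 1)
  line <- tibble::tibble(wavenumber = grid, intensity = 0.01 * grid + 4)
  res <- asls_baseline(line, lambda = 1e5, p = 0.01, iters = 10)
  expect_lt(max(abs(res$corrected$intensity)), 1e-6 * max(line$intensity))

  peaky <- line
  peaky$intensity <- peaky$intensity +
    8 * exp(-(grid - 800)^2 / (2 * 8^2))
  res2 <- asls_baseline(peaky, lambda = 1e5, p = 0.01, iters = 10)
  off_peak <- abs(grid - 800) > 50
  rel_err <- abs(res2$baseline$intensity - line$intensity) / line$intensity
  expect_lt(max(rel_err[off_peak]), 0.02)
})

test_that("AsLS at p = 0.5 equals the symmetric Whittaker smoother", {
  withr::with_seed(11, {
    y <- sin(seq(0, 4, length.out = 300)) + rnorm(300, 0, 0.05)
  })
  s <- tibble::tibble(wavenumber = seq_along(y), intensity = y)
  got <- asls_baseline(s, lambda = 100, p = 0.5, iters = 50)$baseline$intensity
  # fixed-weight weighted-least-squares oracle via a dense solve
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  z <- solve(0.5 * diag(n) + 100 * crossprod(D), 0.5 * y)
  expect_equal(got, as.numeric(z), tolerance = 1e-8)
})

test_that("Savitzky-Golay smoothing is exact on cubics and shrinks noise", {
  x <- seq(300, 600, by = 1)
  cubic <- tibble::tibble(wavenumber = x,
                          intensity = 2 + 0.5 * x - 3e-3 * x^2 + 1e-5 * x^3)
  sm <- sg_smooth(cubic, 11, 3)
  expect_equal(sm$intensity, cubic$intensity, tolerance = 1e-8)

  withr::with_seed(3, {
    noise <- tibble::tibble(wavenumber = x, intensity = rnorm(length(x)))
  })
  out <- sg_smooth(noise, 11, 3)
  inner <- 20:(length(x) - 20)
  expect_lt(var(out$intensity[inner]), var(noise$intensity[inner]))

  impulse <- tibble::tibble(wavenumber = seq_len(51),
                            intensity = c(rep(0, 25), 1, rep(0, 25)))
  kern <- sg_smooth(impulse, 11, 3)$intensity[21:31]
  expect_equal(kern, signal::sgolay(p = 3, n = 11)[6, ], tolerance = 1e-8)

  expect_error(sg_smooth(cubic, 10, 3), "use 11")
})

test_that("area normalization scales the summed intensity to the target", {
  s <- tibble::tibble(wavenumber = 1:3, intensity = c(2, 2, 4))
  expect_equal(area_normalize(s, 100)$intensity, c(25, 25, 50))
  done <- area_normalize(s, 100)
  expect_equal(area_normalize(done, 100)$intensity, done$intensity)
  # scale invariance
  s2 <- s; s2$intensity <- s$intensity * 7.3
  expect_equal(area_normalize(s2, 100)$intensity,
               area_normalize(s, 100)$intensity)
  bad <- tibble::tibble(wavenumber = 1:3, intensity = c(-1, 0.5, 0.5))
  expect_error(area_normalize(bad, 100), "non-positive")
})

test_that("QC keeps clean spectra, drops pure noise, and snr_min 0 keeps all", {
  clean <- generate_dataset(generator_config(
    group_sizes = c(A = 1, B = 1, C = 1), spectra_per_sample = c(2, 2),
    grid = c(300, 3400, 2), seed = 21))
  withr::with_seed(2, {
    noise_rows <- clean[1:2, ]
    noise_rows$sample_id <- c("N1", "N2")
    noise_rows$intensity <- lapply(noise_rows$intensity,
                                   function(y) rnorm(length(y), 0, 1))
  })
  mixed <- dplyr::bind_rows(clean, noise_rows)
  res <- qc_filter(mixed, 3)
  expect_setequal(res$excluded$sample_id, c("N1", "N2"))
  expect_equal(nrow(res$kept) + nrow(res$excluded), nrow(mixed))
  expect_equal(nrow(qc_filter(mixed, 0)$excluded), 0)
  # a spectrum not covering the silent region is excluded with a reason
  short <- clean[1, ]
  short$wavenumber <- list(seq(300, 1500, 2))
  short$intensity <- list(short$intensity[[1]][1:601])
  res2 <- qc_filter(dplyr::bind_rows(clean, short), 3)
  expect_true("missing_silent_region" %in% res2$excluded$reason)
})

test_that("the full pipeline yields unit-grid, unit-area spectra in order", {
  d <- generate_dataset(generator_config(
    group_sizes = c(A = 2, B = 2, C = 2), spectra_per_sample = c(2, 2),
    grid = c(295, 3405, 1), seed = 17))
  pp <- preprocess_spectra(d)
  expect_true(all(lengths(pp$intensity) == 3101))
  sums <- vapply(pp$intensity, sum, numeric(1))
  expect_equal(sums, rep(100, nrow(pp)), tolerance = 1e-9)
  expect_s3_class(qc_report(pp), "tbl_df")

  # permuting normalization before baseline correction changes the result
  s <- ramanblast:::new_spectrum(d$wavenumber[[1]], d$intensity[[1]])
  s <- truncate_resample(s, c(300, 3400), 1)
  canonical <- area_normalize(
    sg_smooth(asls_baseline(s)$corrected, 11, 3), 100)
  permuted <- sg_smooth(asls_baseline(area_normalize(s, 100))$corrected, 11, 3)
  expect_gt(max(abs(canonical$intensity - permuted$intensity)), 1e-3)

  empty <- d[0, ]
  expect_warning(out <- preprocess_spectra(empty), "empty")
  expect_equal(nrow(out), 0)

  all_out <- preprocess_spectra(d, preprocess_config(snr_min = Inf))
  expect_equal(nrow(all_out), 0)
  expect_equal(nrow(qc_report(all_out)), nrow(d))
})

test_that("preprocessing preserves peak positions on clean input", {
  flatbase <- list(offset = c(0, 0), slope = c(0, 0),
                   hump_amplitude = c(0, 0), hump_center = 1400,
                   hump_width = 600)
  d <- generate_dataset(generator_config(
    group_sizes = c(A = 1, B = 1, C = 1), spectra_per_sample = c(2, 2),
    grid = c(300, 3400, 1), baseline = flatbase, spike_rate = 0,
    noise_sd = 0.005, seed = 23))
  pp <- preprocess_spectra(d, preprocess_config(snr_min = 0))
  pos <- core_peak_positions()
  for (i in seq_len(nrow(pp))) {
    s <- ramanblast:::new_spectrum(pp$wavenumber[[i]], pp$intensity[[i]])
    for (p in pos) {
      win <- s$intensity[abs(s$wavenumber - p) <= 6]
      at <- s$wavenumber[abs(s$wavenumber - p) <= 6][which.max(win)]
      expect_lte(abs(at - p), 1)
    }
  }
})
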