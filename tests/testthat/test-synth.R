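test_that("default templates carry the eighteen core peaks and their patterns", {
  tpl <- default_peak_templates()
  expect_equal(nrow(tpl), 18)
  expect_true(all(tpl$position >= 300 & tpl$position <= 3400))
  expect_true(all(tpl[c("mean_A", "mean_B", "mean_C")] >= 0))
  expect_true(all(tpl$amplitude_cv >= 0))

  at <- function(pos) tpl[tpl$position == pos, ]
  # strictly decreasing A > B > C at 750
  p750 <- at(750)
  expect_true(p750$mean_A > p750$mean_B && p750$mean_B > p750$mean_C)
  # all-tied pattern encoded as exactly equal means at 1120
  p1120 <- at(1120)
  expect_equal(p1120$mean_A, p1120$mean_B)
  expect_equal(p1120$mean_B, p1120$mean_C)
  # tied pair of a two-significant pattern is exactly equal at 642
  p642 <- at(642)
  expect_equal(p642$mean_A, p642$mean_B)
  expect_gt(p642$mean_C, p642$mean_A)
  # separability 0 collapses every group difference
  flat <- default_peak_templates(separability = 0)
  expect_equal(flat$mean_A, flat$mean_B)
  expect_equal(flat$mean_B, flat$mean_C)
})

test_that("noiseless mean spectrum peaks exactly at the template positions", {
  tpl <- default_peak_templates()
  s <- noiseless_mean_spectrum(tpl, "A")
  # brute-force strict local-maximum scan of the analytic curve
  y <- s$intensity
  idx <- which(y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                 y[2:(length(y) - 1)] > y[3:length(y)]) + 1L
  expect_equal(s$wavenumber[idx], tpl$position)

  expect_equal(noiseless_mean_spectrum(tpl[0, ], "A")$intensity,
               rep(0, 3101))
  single <- tibble::tibble(position = 1000, width = 5, mean_A = 2,
                           mean_B = 2, mean_C = 2, amplitude_cv = 0.1)
  sm <- noiseless_mean_spectrum(single, "B")
  expect_equal(sm$wavenumber[which.max(sm$intensity)], 1000)
  expect_error(noiseless_mean_spectrum(tpl, "D"), "must be one of")
})

test_that("generator honours sizes, replicate ranges and determinism", {
  d <- generate_dataset(generator_config(
    group_sizes = c(A = 1, B = 1, C = 1), spectra_per_sample = c(1, 1),
    grid = c(300, 3400, 10)))
  expect_equal(nrow(d), 3)
  expect_equal(sort(unique(d$group)), c("A", "B", "C"))

  cfg <- generator_config(group_sizes = c(A = 3, B = 2, C = 3),
                          spectra_per_sample = c(2, 4),
                          grid = c(300, 3400, 5), seed = 9)
  d1 <- generate_dataset(cfg)
  reps <- table(d1$sample_id)
  expect_true(all(reps >= 2 & reps <= 4))
  d2 <- generate_dataset(cfg)
  expect_identical(d1$intensity, d2$intensity)
  d3 <- generate_dataset(generator_config(
    group_sizes = c(A = 3, B = 2, C = 3), spectra_per_sample = c(2, 4),
    grid = c(300, 3400, 5), seed = 10))
  expect_false(identical(d1$intensity, d3$intensity))
})

test_that("invalid generator configurations name the offending field", {
  expect_error(generator_config(group_sizes = c(A = 0, B = 1, C = 1)),
               "group_sizes")
  expect_error(generator_config(spectra_per_sample = c(5, 2)),
               "spectra_per_sample")
  expect_error(generator_config(grid = c(3400, 300, 1)), "grid")
  expect_error(generator_config(noise_sd = -1), "noise_sd")
})

test_that("cosmic-ray spikes perturb only the spiked grid points", {
  base_cfg <- function(rate) generator_config(
    group_sizes = c(A = 4, B = 4, C = 4), spectra_per_sample = c(1, 1),
    grid = c(300, 3400, 2), spike_rate = rate, seed = 5)
  clean <- generate_dataset(base_cfg(0))
  spiked <- generate_dataset(base_cfg(3))
  n_hit <- 0
  for (i in seq_len(nrow(clean))) {
    diff <- spiked$intensity[[i]] - clean$intensity[[i]]
    hit <- which(diff != 0)
    n_hit <- n_hit + length(hit)
    expect_true(all(diff[hit] > 0))
    expect_lt(length(hit), 20)
  }
  expect_gt(n_hit, 0)  # Poisson(3) over 12 spectra: spikes present
})

test_that("generated group means reproduce the encoded peak orderings", {
  # generator core contract: empirical per-group mean peak intensities,
  # from >= 30 samples per group, follow each template's group_means
  tpl <- default_peak_templates(separability = 2)
  d <- generate_dataset(generator_config(
    group_sizes = c(A = 30, B = 30, C = 30), spectra_per_sample = c(2, 2),
    grid = c(300, 3400, 2), seed = 13,
    baseline = list(offset = c(0, 0), slope = c(0, 0),
                    hump_amplitude = c(0, 0), hump_center = 1400,
                    hump_width = 600),
    spike_rate = 0), tpl)
  X <- spectra_matrix(d)
  w <- attr(X, "wavenumber")
  for (j in seq_len(nrow(tpl))) {
    cols <- which(abs(w - tpl$position[j]) <= 4)
    val <- apply(X[, cols, drop = FALSE], 1, max)
    emp <- tapply(val, d$group, mean)
    enc <- unlist(tpl[j, c("mean_A", "mean_B", "mean_C")])
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      if (enc[pair[1]] > enc[pair[2]]) {
        expect_gt(emp[pair[1]], emp[pair[2]])
      } else if (enc[pair[1]] < enc[pair[2]]) {
        expect_lt(emp[pair[1]], emp[pair[2]])
      }
    }
  }
})

test_that("dataset round-trips through the on-disk formats", {
  d <- generate_dataset(generator_config(
    group_sizes = c(A = 2, B = 1, C = 1), spectra_per_sample = c(2, 2),
    grid = c(300, 3400, 50), seed = 3))
  dir <- withr::local_tempdir()
  man <- write_dataset(d, dir)
  back <- read_dataset(man)
  expect_equal(nrow(back), nrow(d))
  expect_equal(back$group, d$group)
  for (i in seq_len(nrow(d))) {
    expect_equal(back$intensity[[i]], d$intensity[[i]], tolerance = 1e-9)
  }
  long <- file.path(dir, "long.csv")
  write_dataset_long(d, long)
  tab <- readr::read_csv(long, show_col_types = FALSE)
  expect_equal(nrow(tab), sum(lengths(d$intensity)))
})
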