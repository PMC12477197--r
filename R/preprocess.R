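# Preprocessing pipeline: QC -> despike -> truncate/resample -> AsLS
# baseline correction -> Savitzky-Golay smoothing -> area normalization.

#' Preprocessing configuration
#'
#' @param spike_filter_size Half-width (points) of the running-median
#'   despiking window.
#' @param spike_dynamic_factor Robust-deviation multiple above which a point
#'   counts as a cosmic-ray spike.
#' @param range Wavenumber range `c(lo, hi)` to truncate to, cm-1.
#' @param step Resampling step, cm-1.
#' @param asls_lambda Smoothness weight of the asymmetric least squares
#'   baseline.
#' @param asls_p Asymmetry weight in (0, 1); small values push the baseline
#'   under the peaks.
#' @param asls_iters Iteration cap for the reweighting loop.
#' @param sg_window Savitzky-Golay window length in points; must be odd
#'   (the classical construction requires a centred window, so an even
#'   published value maps to the nearest odd one).
#' @param sg_order Savitzky-Golay polynomial order.
#' @param norm_total Target total intensity after area normalization.
#' @param snr_min Minimum signal-to-noise ratio for a spectrum to survive
#'   quality control.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(spike_filter_size = 4, spike_dynamic_factor = 6,
                              range = c(300, 3400), step = 1,
                              asls_lambda = 1e5, asls_p = 0.01, asls_iters = 10,
                              sg_window = 11, sg_order = 3,
                              norm_total = 100, snr_min = 3) {
  cfg <- list(spike_filter_size = spike_filter_size,
              spike_dynamic_factor = spike_dynamic_factor,
              range = range, step = step,
              asls_lambda = asls_lambda, asls_p = asls_p,
              asls_iters = asls_iters,
              sg_window = sg_window, sg_order = sg_order,
              norm_total = norm_total, snr_min = snr_min)
  if (sg_window %% 2 == 0) {
    abort(sprintf("`sg_window` must be odd; use %d instead of %d",
                  sg_window + 1, sg_window))
  }
  if (sg_window <= sg_order) abort("`sg_window` must exceed `sg_order`")
  if (asls_p <= 0 || asls_p >= 1) abort("`asls_p` must lie in (0, 1)")
  if (asls_lambda <= 0) abort("`asls_lambda` must be > 0")
  if (norm_total <= 0) abort("`norm_total` must be > 0")
  class(cfg) <- "preprocess_config"
  cfg
}

# Signal-to-noise ratio: peak signal in the fingerprint region over the
# robust noise level in the Raman-silent region. The signal is read off a
# lightly smoothed curve so that single-point noise excursions (whose
# maximum over ~1000 grid points already reaches 3-4 noise SDs) do not
# masquerade as Raman signal.
spectrum_snr <- function(s, signal_region = c(600, 1800),
                         silent_region = c(1800, 2600)) {
  w <- s$wavenumber; y <- s$intensity
  sil <- w >= silent_region[1] & w <= silent_region[2]
  if (sum(sil) < 10) return(list(snr = NA_real_, reason = "missing_silent_region"))
  sig <- w >= signal_region[1] & w <= signal_region[2]
  if (sum(sig) < 10) return(list(snr = NA_real_, reason = "missing_signal_region"))
  fit <- stats::.lm.fit(cbind(1, w[sil]), y[sil])
  noise <- mad(fit$residuals)
  ys <- if (length(y) >= 12) signal::sgolayfilt(y, p = 3, n = 11) else y
  trend <- fit$coefficients[1] + fit$coefficients[2] * w[sig]
  signal <- max(ys[sig] - trend)
  list(snr = if (noise > 0) signal / noise else Inf, reason = NA_character_)
}

#' Quality-control filter for a spectra table
#'
#' Excludes spectra whose signal-to-noise ratio falls below `snr_min`. SNR
#' is the maximum baseline-corrected intensity in the 600-1800 cm-1
#' fingerprint region divided by the robust residual spread in the
#' 1800-2600 cm-1 silent region (after linear detrending). Spectra that do
#' not cover the silent region are excluded with a reason code.
#'
#' @param data A spectra table.
#' @param snr_min QC threshold; 0 keeps everything.
#' @return A list with elements `kept` (spectra table) and `excluded`
#'   (spectra table plus `snr` and `reason` columns); the two partition the
#'   input.
#' @export
qc_filter <- function(data, snr_min = 3) {
  check_dataset(data)
  if (nrow(data) == 0) abort("`data` must contain at least one spectrum")
  res <- purrr::map2(data$wavenumber, data$intensity, function(w, y) {
    spectrum_snr(new_spectrum(w, y))
  })
  snr <- purrr::map_dbl(res, "snr")
  reason <- purrr::map_chr(res, "reason")
  drop <- is.na(snr) | snr < snr_min
  reason[is.na(reason) & drop] <- "low_snr"
  excluded <- data[drop, , drop = FALSE]
  excluded$snr <- snr[drop]
  excluded$reason <- reason[drop]
  list(kept = data[!drop, , drop = FALSE], excluded = excluded)
}

#' Remove cosmic-ray spikes from one spectrum
#'
#' A point is a spike iff its deviation from the running median over
#' `filter_size` points on each side exceeds `dynamic_factor` times the
#' scaled running median absolute deviation; spikes are replaced by the
#' running median, all other points pass through unchanged.
#'
#' @param s A spectrum data frame (`wavenumber`, `intensity`).
#' @param filter_size Window half-width in points.
#' @param dynamic_factor Robust-deviation multiple.
#' @return The despiked spectrum tibble; the 1-based indices of replaced
#'   points are attached as attribute `"spikes"`.
#' @export
despike <- function(s, filter_size = 4, dynamic_factor = 6) {
  check_spectrum(s)
  if (filter_size < 1 || dynamic_factor <= 0) {
    abort("`filter_size` must be >= 1 and `dynamic_factor` > 0")
  }
  if (nrow(s) < 2 * filter_size + 1) {
    abort(sprintf("spectrum has %d points but despiking needs at least %d",
                  nrow(s), 2 * filter_size + 1))
  }
  res <- despike_cpp(s$intensity, as.integer(filter_size), dynamic_factor)
  out <- new_spectrum(s$wavenumber, res$intensity)
  attr(out, "spikes") <- res$spike_index
  out
}

#' Truncate and resample a spectrum onto a uniform grid
#'
#' @param s A spectrum data frame.
#' @param range Target range `c(lo, hi)`, cm-1; the input must span it.
#' @param step Grid step, cm-1.
#' @return The spectrum linearly interpolated onto
#'   `seq(lo, hi, by = step)` (3101 points for the defaults).
#' @export
truncate_resample <- function(s, range = c(300, 3400), step = 1) {
  check_spectrum(s)
  lo <- range[1]; hi <- range[2]
  if (min(s$wavenumber) > lo) {
    abort(sprintf("input grid starts at %.6g and does not cover the lower end %.6g",
                  min(s$wavenumber), lo))
  }
  if (max(s$wavenumber) < hi) {
    abort(sprintf("input grid ends at %.6g and does not cover the upper end %.6g",
                  max(s$wavenumber), hi))
  }
  w <- seq(lo, hi, by = step)
  new_spectrum(w, approx(s$wavenumber, s$intensity, xout = w)$y)
}

#' Asymmetric least squares baseline correction
#'
#' Eilers-Boelens scheme: minimize `sum(w_i (y_i - z_i)^2) +
#' lambda * sum(diff(z, differences = 2)^2)` with asymmetric weights
#' `w_i = p` where `y_i > z_i` and `1 - p` otherwise, iterating the weights
#' to convergence or `iters` rounds.
#'
#' @param s A spectrum data frame.
#' @param lambda Smoothness penalty (> 0).
#' @param p Asymmetry weight in (0, 1).
#' @param iters Iteration cap.
#' @return A list with `baseline` and `corrected` spectrum tibbles.
#' @export
asls_baseline <- function(s, lambda = 1e5, p = 0.01, iters = 10) {
  check_spectrum(s)
  if (lambda <= 0) abort("`lambda` must be > 0")
  if (p <= 0 || p >= 1) abort("`p` must lie in (0, 1)")
  res <- asls_baseline_cpp(s$intensity, lambda, p, as.integer(iters))
  base <- new_spectrum(s$wavenumber, res$baseline)
  list(baseline = base,
       corrected = new_spectrum(s$wavenumber, s$intensity - res$baseline))
}

#' Savitzky-Golay smoothing
#'
#' Standard Savitzky-Golay convolution; any polynomial of degree at most
#' `order` passes through unchanged.
#'
#' @param s A spectrum data frame.
#' @param window Odd window length in points.
#' @param order Polynomial order (< window).
#' @return The smoothed spectrum tibble.
#' @export
sg_smooth <- function(s, window = 11, order = 3) {
  check_spectrum(s)
  if (window %% 2 == 0) {
    abort(sprintf("`window` must be odd; use %d instead of %d", window + 1, window))
  }
  if (window <= order) abort("`window` must exceed `order`")
  new_spectrum(s$wavenumber, signal::sgolayfilt(s$intensity, p = order, n = window))
}

#' Area normalization
#'
#' Scales the spectrum so its total (summed) intensity equals `total`.
#'
#' @param s A spectrum data frame.
#' @param total Target total intensity.
#' @return The scaled spectrum tibble.
#' @export
area_normalize <- function(s, total = 100) {
  check_spectrum(s)
  tot <- sum(s$intensity)
  if (tot <= 0) abort("total intensity is non-positive; cannot area-normalize a degenerate spectrum")
  new_spectrum(s$wavenumber, s$intensity * total / tot)
}

#' Run the full preprocessing pipeline over a spectra table
#'
#' Applies, in order: quality control, despiking, truncation/resampling,
#' AsLS baseline correction, Savitzky-Golay smoothing, area normalization.
#'
#' @param data A spectra table (e.g. from [generate_dataset()] or
#'   [read_dataset()]).
#' @param config A [preprocess_config()].
#' @return The processed spectra table. The QC exclusions are attached as
#'   attribute `"qc_excluded"` and per-step record counts as attribute
#'   `"steps"`; see [qc_report()].
#' @export
preprocess_spectra <- function(data, config = preprocess_config()) {
  check_dataset(data)
  if (nrow(data) == 0) {
    warn("empty spectra table; nothing to preprocess")
    return(data)
  }
  qc <- qc_filter(data, config$snr_min)
  kept <- qc$kept
  steps <- c(input = nrow(data), qc_kept = nrow(kept))
  if (nrow(kept) > 0) {
    processed <- purrr::map2(kept$wavenumber, kept$intensity, function(w, y) {
      s <- new_spectrum(w, y)
      s <- despike(s, config$spike_filter_size, config$spike_dynamic_factor)
      s <- truncate_resample(s, config$range, config$step)
      s <- asls_baseline(s, config$asls_lambda, config$asls_p,
                         config$asls_iters)$corrected
      s <- sg_smooth(s, config$sg_window, config$sg_order)
      area_normalize(s, config$norm_total)
    })
    kept$wavenumber <- purrr::map(processed, "wavenumber")
    kept$intensity <- purrr::map(processed, "intensity")
  }
  steps <- c(steps, output = nrow(kept))
  attr(kept, "qc_excluded") <- qc$excluded
  attr(kept, "steps") <- steps
  kept
}

#' QC report of a preprocessed spectra table
#'
#' @param data Output of [preprocess_spectra()].
#' @return Tibble of excluded spectra with their SNR and reason code.
#' @export
qc_report <- function(data) {
  ex <- attr(data, "qc_excluded")
  if (is.null(ex)) abort("`data` carries no QC information; run preprocess_spectra() first")
  dplyr::select(as_tibble(ex), -dplyr::any_of(c("wavenumber", "intensity")))
}
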