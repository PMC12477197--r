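# Synthetic-dataset generator: hierarchical Gaussian-peak spectra with
# baseline drift, shot noise and cosmic-ray spikes.

#' Configuration for the synthetic-spectrum generator
#'
#' Defaults emulate the study conditions: 58/25/89 samples in outcome groups
#' A/B/C, 30-40 replicate spectra per sample, a 300-3400 cm-1 grid at
#' 1 cm-1 steps, broad baseline drift, additive noise and occasional
#' cosmic-ray spikes.
#'
#' @param group_sizes Named integer vector of samples per outcome group.
#' @param spectra_per_sample Integer range `c(min, max)`; each sample draws
#'   its replicate count uniformly from this range.
#' @param noise_sd Standard deviation of the additive (shot) noise, in the
#'   same arbitrary units as the peak amplitudes.
#' @param baseline List of baseline parameters: `offset`, `slope` ranges
#'   (per cm-1), and a broad Gaussian hump (`hump_amplitude` range,
#'   `hump_center`, `hump_width`); each spectrum draws its own values.
#' @param spike_rate Expected number of cosmic-ray spikes per spectrum
#'   (Poisson mean).
#' @param spike_amplitude Spike height as a multiple of the local signal.
#' @param grid Wavenumber grid `c(start, stop, step)` in cm-1.
#' @param within_cv Within-sample (replicate-to-replicate) coefficient of
#'   variation of peak amplitudes; the between-sample part lives in the
#'   peak templates.
#' @param seed Master seed; every sample derives its own deterministic
#'   substream from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(group_sizes = c(A = 58, B = 25, C = 89),
                             spectra_per_sample = c(30, 40),
                             noise_sd = 0.02,
                             baseline = list(offset = c(1, 3),
                                             slope = c(-3e-4, 3e-4),
                                             hump_amplitude = c(0.5, 2),
                                             hump_center = 1400,
                                             hump_width = 600),
                             spike_rate = 0.2,
                             spike_amplitude = 20,
                             grid = c(300, 3400, 1),
                             within_cv = 0.15,
                             seed = 1L) {
  cfg <- list(group_sizes = group_sizes, spectra_per_sample = spectra_per_sample,
              noise_sd = noise_sd, baseline = baseline, spike_rate = spike_rate,
              spike_amplitude = spike_amplitude, grid = grid,
              within_cv = within_cv, seed = seed)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  bad <- function(field, why) {
    abort(sprintf("invalid generator configuration: `%s` %s", field, why))
  }
  gs <- cfg$group_sizes
  if (length(gs) != 3 || any(gs < 1)) bad("group_sizes", "must give >= 1 sample for each of the three groups")
  if (is.null(names(gs)) || !identical(sort(names(gs)), GROUPS)) {
    names(cfg$group_sizes) <- GROUPS
  }
  sp <- cfg$spectra_per_sample
  if (length(sp) != 2 || sp[1] < 1 || sp[1] > sp[2]) bad("spectra_per_sample", "must be c(min, max) with 1 <= min <= max")
  if (cfg$noise_sd < 0) bad("noise_sd", "must be >= 0")
  if (cfg$spike_rate < 0) bad("spike_rate", "must be >= 0")
  if (cfg$spike_amplitude < 0) bad("spike_amplitude", "must be >= 0")
  g <- cfg$grid
  if (length(g) != 3 || g[3] <= 0 || g[1] >= g[2]) bad("grid", "must be c(start, stop, step) with step > 0 and start < stop")
  if (cfg$within_cv < 0) bad("within_cv", "must be >= 0")
  cfg
}

# Gaussian profile matrix: grid points x peaks.
profile_matrix <- function(w, templates) {
  vapply(seq_len(nrow(templates)), function(j) {
    exp(-((w - templates$position[j])^2) / (2 * templates$width[j]^2))
  }, numeric(length(w)))
}

# Day 3 grade split observed in the study cohort (share of grade I-II
# embryos per outcome group).
GRADE12_SHARE <- c(A = 38 / 58, B = 2 / 25, C = 42 / 89)

#' Generate a labelled synthetic spectra dataset
#'
#' Each spectrum is a baseline plus the sum of Gaussian core peaks plus
#' additive noise and Poisson-count cosmic-ray spikes. Peak amplitudes are
#' hierarchical: group mean x a lognormal per-sample random effect
#' (sd `amplitude_cv` from the template) x a lognormal per-replicate effect
#' (sd `within_cv` from the config), so replicate spectra of one sample are
#' correlated, as in real acquisitions.
#'
#' @param config A [generator_config()].
#' @param templates Peak templates, see [default_peak_templates()].
#' @return A spectra table: one row per spectrum with `sample_id`, `group`,
#'   `grade`, `replicate` and list-columns `wavenumber`, `intensity`.
#' @examples
#' d <- generate_dataset(generator_config(group_sizes = c(A = 2, B = 2, C = 2),
#'                                        spectra_per_sample = c(3, 3)))
#' dplyr::count(d, group)
#' @export
generate_dataset <- function(config = generator_config(),
                             templates = default_peak_templates()) {
  config <- validate_generator_config(config)
  check_templates(templates)
  w <- make_grid(config$grid)
  P <- profile_matrix(w, templates)
  gm <- as.matrix(templates[, c("mean_A", "mean_B", "mean_C")])
  colnames(gm) <- GROUPS
  cvb <- templates$amplitude_cv
  bl <- config$baseline

  rows <- list()
  idx <- 0L
  for (g in GROUPS) {
    n_g <- config$group_sizes[[g]]
    n12 <- round(GRADE12_SHARE[[g]] * n_g)
    for (i in seq_len(n_g)) {
      idx <- idx + 1L
      sid <- sprintf("%s%03d", g, i)
      grade <- if (i <= n12) "I-II" else "III"
      spectra <- with_seed(derive_seed(config$seed, idx), {
        rep_range <- seq(config$spectra_per_sample[1],
                         config$spectra_per_sample[2])
        n_rep <- rep_range[sample.int(length(rep_range), 1)]
        # per-sample random effect, one multiplier per peak
        samp_eff <- rlnorm(nrow(templates), meanlog = -cvb^2 / 2, sdlog = cvb)
        lapply(seq_len(n_rep), function(r) {
          rep_eff <- rlnorm(nrow(templates), meanlog = -config$within_cv^2 / 2,
                            sdlog = config$within_cv)
          amps <- gm[, g] * samp_eff * rep_eff
          base <- runif(1, bl$offset[1], bl$offset[2]) +
            runif(1, bl$slope[1], bl$slope[2]) * (w - w[1]) +
            runif(1, bl$hump_amplitude[1], bl$hump_amplitude[2]) *
              exp(-((w - bl$hump_center)^2) / (2 * bl$hump_width^2))
          y <- base + drop(P %*% amps) + rnorm(length(w), 0, config$noise_sd)
          n_spk <- rpois(1, config$spike_rate)
          if (n_spk > 0) {
            at <- sample(length(w), n_spk)
            y[at] <- y[at] + config$spike_amplitude *
              pmax(abs(y[at]), 0.1) * runif(n_spk, 0.5, 1.5)
          }
          y
        })
      })
      rows[[idx]] <- tibble(
        sample_id = sid, group = g, grade = grade,
        replicate = seq_along(spectra),
        wavenumber = list(w), intensity = spectra
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "grid") <- config$grid
  out
}

#' Noise-free mean spectrum of one outcome group
#'
#' The analytic, baseline-free sum of the template peak profiles at the
#' group's mean amplitudes; the oracle used in peak-recovery checks.
#'
#' @param templates Peak templates (may be empty for an all-zero spectrum
#'   only if given as a zero-row tibble).
#' @param group One of `"A"`, `"B"`, `"C"`.
#' @param grid Wavenumber grid `c(start, stop, step)`.
#' @return A spectrum tibble (`wavenumber`, `intensity`).
#' @export
noiseless_mean_spectrum <- function(templates = default_peak_templates(),
                                    group = "A", grid = c(300, 3400, 1)) {
  if (!is.character(group) || length(group) != 1 || !(group %in% GROUPS)) {
    abort("`group` must be one of \"A\", \"B\", \"C\"")
  }
  w <- make_grid(grid)
  if (nrow(templates) == 0) return(new_spectrum(w, numeric(length(w))))
  check_templates(templates)
  m <- templates[[paste0("mean_", group)]]
  new_spectrum(w, drop(profile_matrix(w, templates) %*% m))
}
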