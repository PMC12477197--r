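# Core peak templates: positions, widths, and group-wise mean amplitudes
# realizing the published intensity patterns.

pattern_offsets <- function() {
  # multipliers of the pattern step applied to the base amplitude per group
  list(
    "A>B>C"  = c(A =  1,   B =  0,   C = -1),
    "A<B<C"  = c(A = -1,   B =  0,   C =  1),
    "B<A<C"  = c(A =  0,   B = -1,   C =  1),
    "A<C<B"  = c(A = -1,   B =  1,   C =  0),
    "A?B<C"  = c(A =  0,   B =  0,   C =  1),
    "A>B?C"  = c(A =  1,   B =  0,   C =  0),
    "A?C>B"  = c(A =  0,   B = -1,   C =  0),
    "B>A"    = c(A = -0.5, B =  0.5, C =  0),
    "C>B"    = c(A =  0,   B = -0.5, C =  0.5),
    "A?B?C"  = c(A =  0,   B =  0,   C =  0)
  )
}

# Replace the placeholder '?' with the approximate-equality sign.
pattern_label <- function(x) gsub("?", APPROX, x, fixed = TRUE)

#' The ten group-wise peak-intensity patterns
#'
#' Pattern labels describe how the mean peak intensity orders across the
#' three extended-culture outcome groups (A good blastocyst, B non-good
#' blastocyst, C non-useful embryo); `r "≈"` marks pairs without a
#' significant difference.
#'
#' @return Character vector of the ten pattern labels.
#' @export
peak_patterns <- function() pattern_label(names(pattern_offsets()))

#' Default core-peak templates
#'
#' Eighteen Gaussian peak templates at the core wavenumbers seen in Raman
#' spectra of dried spent culture medium. Each template carries a mean
#' amplitude per outcome group realizing its published intensity pattern:
#' groups tied in the pattern get exactly equal means, strictly ordered
#' groups are separated by `step` (relative to the base amplitude) times
#' `separability`.
#'
#' @param separability Non-negative scale on all between-group amplitude
#'   differences. 1 reproduces the default (subtle) group structure; 0 makes
#'   all groups identical; large values give well-separated classes for
#'   calibration experiments.
#' @param step Relative amplitude gap between adjacently ordered groups at
#'   `separability = 1`.
#' @param amplitude_cv Between-sample coefficient of variation of peak
#'   amplitudes (lognormal sd on the log scale).
#' @return A tibble with one row per peak: `position`, `width` (Gaussian
#'   sigma, cm-1), `mean_A`, `mean_B`, `mean_C`, `amplitude_cv`, `pattern`.
#' @examples
#' default_peak_templates()
#' @export
default_peak_templates <- function(separability = 1, step = 0.12,
                                   amplitude_cv = 0.10) {
  stopifnot(separability >= 0, step >= 0, amplitude_cv >= 0)
  spec <- dplyr::tribble(
    ~position, ~width, ~base, ~pat,
    506,   5,  0.6, "B>A",
    620,   5,  0.7, "B<A<C",
    642,   5,  0.7, "A?B<C",
    662,   5,  0.7, "A?B<C",
    750,   5,  0.9, "A>B>C",
    850,   5,  0.8, "B<A<C",
    898,   5,  0.7, "A>B?C",
    938,   5,  0.9, "A>B>C",
    1000,  4,  1.2, "A?B<C",
    1030,  5,  0.9, "A?B<C",
    1120,  6,  0.7, "A?B?C",
    1202,  6,  0.8, "A<B<C",
    1332,  7,  1.0, "A>B?C",
    1446,  7,  1.4, "A>B?C",
    1605,  7,  0.9, "A?C>B",
    1654,  8,  1.3, "A?B?C",
    2874, 10,  1.8, "C>B",
    2926, 11,  2.4, "A<C<B"
  )
  off <- pattern_offsets()
  means <- purrr::map2(spec$base, spec$pat, function(b, p) {
    b * (1 + separability * step * off[[p]])
  })
  tibble(
    position = spec$position,
    width = spec$width,
    mean_A = purrr::map_dbl(means, "A"),
    mean_B = purrr::map_dbl(means, "B"),
    mean_C = purrr::map_dbl(means, "C"),
    amplitude_cv = amplitude_cv,
    pattern = pattern_label(spec$pat)
  )
}

#' Core peak positions
#'
#' @param templates A peak-template tibble; defaults to
#'   [default_peak_templates()].
#' @return Numeric vector of peak positions (cm-1).
#' @export
core_peak_positions <- function(templates = default_peak_templates()) {
  templates$position
}

check_templates <- function(templates) {
  need <- c("position", "width", "mean_A", "mean_B", "mean_C", "amplitude_cv")
  if (!is.data.frame(templates) || !all(need %in% names(templates)) ||
      nrow(templates) == 0) {
    abort("`templates` must be a non-empty peak-template tibble; see default_peak_templates()")
  }
  if (any(templates$position < 300 | templates$position > 3400)) {
    abort("template positions must lie within [300, 3400] cm-1")
  }
  m <- as.matrix(templates[, c("mean_A", "mean_B", "mean_C")])
  if (any(m < 0) || any(templates$amplitude_cv < 0) || any(templates$width <= 0)) {
    abort("template group means and amplitude_cv must be >= 0 and widths > 0")
  }
  invisible(templates)
}
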