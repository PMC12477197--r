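# Shared fixtures, memoized so expensive synthetic datasets are built once
# per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# Down-scaled study emulation on a 4 cm-1 grid.
small_config <- function(seed, group_sizes = c(A = 12, B = 10, C = 12),
                         reps = c(5, 5), ...) {
  generator_config(group_sizes = group_sizes, spectra_per_sample = reps,
                   grid = c(300, 3400, 4), seed = seed, ...)
}

small_pp_config <- function(...) {
  preprocess_config(range = c(300, 3400), step = 4, ...)
}

# Preprocessed high-separability dataset (well-separated classes).
fx_highsep <- function() {
  fixture("highsep", function() {
    d <- generate_dataset(small_config(31),
                          default_peak_templates(separability = 4))
    preprocess_spectra(d, small_pp_config())
  })
}

# Preprocessed dataset at the default (subtle) separability.
fx_default <- function() {
  fixture("default_sep", function() {
    d <- generate_dataset(small_config(32, reps = c(6, 6)))
    preprocess_spectra(d, small_pp_config())
  })
}

gauss_spectrum <- function(center, sigma, grid = seq(300, 3400, by = 1),
                           amplitude = 1) {
  tibble::tibble(wavenumber = grid,
                 intensity = amplitude * exp(-(grid - center)^2 / (2 * sigma^2)))
}

# Mean silhouette width of labelled 2-D points.
silhouette_width <- function(xy, labels) {
  D <- as.matrix(dist(xy))
  n <- nrow(D)
  labels <- as.character(labels)
  mean(vapply(seq_len(n), function(i) {
    a <- mean(D[i, labels == labels[i] & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)))
}

PATTERNS <- peak_patterns()
EQ <- substr(PATTERNS[5], 2, 2)  # the approximate-equality character
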