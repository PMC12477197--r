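# Internal helpers shared across modules.

# Validate a single-spectrum data frame (columns wavenumber, intensity).
check_spectrum <- function(s, arg = "s") {
  if (!is.data.frame(s) || !all(c("wavenumber", "intensity") %in% names(s))) {
    abort(sprintf("`%s` must be a data frame with columns `wavenumber` and `intensity`", arg))
  }
  w <- s$wavenumber
  y <- s$intensity
  if (length(w) != length(y)) abort("`wavenumber` and `intensity` differ in length")
  if (anyNA(w) || anyNA(y) || any(!is.finite(y))) abort("spectrum contains non-finite values")
  if (is.unsorted(w, strictly = TRUE)) abort("`wavenumber` must be strictly increasing")
  invisible(s)
}

new_spectrum <- function(wavenumber, intensity) {
  tibble(wavenumber = as.numeric(wavenumber), intensity = as.numeric(intensity))
}

# Validate a spectra table: one row per spectrum, list-columns wavenumber
# and intensity alongside sample metadata.
check_dataset <- function(data, arg = "data") {
  need <- c("sample_id", "group", "wavenumber", "intensity")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    abort(sprintf("`%s` must be a spectra table with columns %s",
                  arg, paste0("`", need, "`", collapse = ", ")))
  }
  invisible(data)
}

# Indices of strict local maxima (both neighbours strictly smaller).
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  which(y[i] > y[i - 1] & y[i] > y[i + 1]) + 1L
}

# Deterministic per-unit substream seed derived from a master seed.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919) %% 2147483629 + 1)
}

# Evaluate code under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Build a wavenumber grid from (start, stop, step).
make_grid <- function(grid) {
  seq(grid[[1]], grid[[2]], by = grid[[3]])
}

# Matrix of spectrum intensities (rows = spectra) from a spectra table,
# assuming a shared grid.
#' Stack the intensities of a spectra table into a matrix
#'
#' Rows are spectra (in table order), columns are the points of the shared
#' wavenumber grid. All spectra must lie on the same grid, which is the case
#' after [preprocess_spectra()] or for freshly generated data.
#'
#' @param data A spectra table (one row per spectrum, list-columns
#'   `wavenumber` and `intensity`).
#' @return A numeric matrix with one row per spectrum and the grid stored in
#'   the `"wavenumber"` attribute.
#' @export
spectra_matrix <- function(data) {
  check_dataset(data)
  grids <- data$wavenumber
  g1 <- grids[[1]]
  same <- vapply(grids, function(g) length(g) == length(g1) && all(g == g1), logical(1))
  if (!all(same)) abort("spectra are not on a shared wavenumber grid; preprocess first")
  X <- do.call(rbind, data$intensity)
  attr(X, "wavenumber") <- g1
  X
}

macro_mean <- function(x) mean(x, na.rm = TRUE)
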