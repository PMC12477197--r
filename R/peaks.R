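# Core-peak statistics: per-peak intensities, group comparisons, and
# assignment of the group-wise intensity pattern labels.

#' Peak intensity of one spectrum at a position
#'
#' The maximum intensity within `position +/- half_window`, which tolerates
#' small peak-position jitter between spectra.
#'
#' @param s A spectrum data frame.
#' @param position Peak position, cm-1.
#' @param half_window Search half-window, cm-1.
#' @return Numeric peak intensity.
#' @export
extract_peak_intensity <- function(s, position, half_window = 5) {
  check_spectrum(s)
  lo <- position - half_window; hi <- position + half_window
  if (lo < min(s$wavenumber) || hi > max(s$wavenumber)) {
    abort(sprintf("window [%.6g, %.6g] lies outside the spectrum grid [%.6g, %.6g]",
                  lo, hi, min(s$wavenumber), max(s$wavenumber)))
  }
  inwin <- s$wavenumber >= lo & s$wavenumber <= hi
  max(s$intensity[inwin])
}

stars_for <- function(p, alpha_levels = c(0.05, 0.01, 0.001)) {
  a <- sort(alpha_levels, decreasing = TRUE)
  dplyr::case_when(p < a[3] ~ "***", p < a[2] ~ "**", p < a[1] ~ "*",
                   TRUE ~ "ns")
}

#' Pairwise group comparisons of peak intensities
#'
#' Two-sided Mann-Whitney U tests (or Welch t-tests) for each pair of
#' groups, with significance stars at 0.05 / 0.01 / 0.001 and no
#' multiplicity correction by default, mirroring per-pair annotation of
#' group differences.
#'
#' @param values_by_group Named list (`A`, `B`, `C`) of numeric intensity
#'   vectors, or a data frame with columns `group` and `value`.
#' @param test `"wilcox"` (default) or `"t"` (Welch).
#' @param alpha_levels Significance thresholds for the star annotation.
#' @param p_adjust Multiplicity correction passed to [stats::p.adjust()];
#'   `"none"` by default.
#' @return Tibble with columns `pair`, `p`, `stars`, `significant`.
#' @export
compare_groups <- function(values_by_group, test = c("wilcox", "t"),
                           alpha_levels = c(0.05, 0.01, 0.001),
                           p_adjust = "none") {
  test <- match.arg(test)
  if (is.data.frame(values_by_group)) {
    values_by_group <- split(values_by_group$value, values_by_group$group)
  }
  groups <- names(values_by_group)
  if (length(groups) < 2) abort("need at least two groups to compare")
  small <- groups[vapply(values_by_group, length, integer(1)) < 2]
  if (length(small) > 0) {
    abort(sprintf("group %s has fewer than 2 observations", small[1]))
  }
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  p <- vapply(pairs, function(pr) {
    x <- values_by_group[[pr[1]]]; y <- values_by_group[[pr[2]]]
    if (test == "wilcox") {
      suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
    } else {
      t.test(x, y)$p.value
    }
  }, numeric(1))
  p <- p.adjust(p, method = p_adjust)
  alpha <- max(alpha_levels)
  tibble(pair = vapply(pairs, paste0, character(1), collapse = ""),
         p = p, stars = stars_for(p, alpha_levels), significant = p < alpha)
}

#' Classify a peak's group-wise intensity pattern
#'
#' Applies the pattern rules in order: full orderings with all three pairs
#' significant; two-significant configurations with one tied pair;
#' single-significant configurations labelled by that pair's direction when
#' the label is one of the ten enumerated patterns; no significant pair
#' gives the all-tied label; anything else is `"other"`.
#'
#' @param means Named numeric vector `c(A = , B = , C = )` of group means.
#' @param significant Named logical vector `c(AB = , AC = , BC = )`.
#' @return A single pattern label (see [peak_patterns()]) or `"other"`.
#' @examples
#' classify_pattern(c(A = 5, B = 4, C = 3),
#'                  c(AB = TRUE, AC = TRUE, BC = TRUE))
#' @export
classify_pattern <- function(means, significant) {
  m <- means[GROUPS]
  if (anyNA(m) || any(!is.finite(m))) abort("`means` must give finite A, B, C values")
  s <- significant[c("AB", "AC", "BC")]
  if (anyNA(s)) abort("`significant` must give logical AB, AC, BC flags")
  nsig <- sum(s)
  eq <- APPROX

  if (nsig == 0) return(paste0("A", eq, "B", eq, "C"))

  if (nsig == 3) {
    if (anyDuplicated(m)) return("other")
    ord <- GROUPS[order(m, decreasing = TRUE)]
    lab <- paste(ord, collapse = ">")
    known <- c("A>B>C" = "A>B>C", "C>B>A" = "A<B<C",
               "C>A>B" = "B<A<C", "B>C>A" = "A<C<B")
    return(if (lab %in% names(known)) unname(known[lab]) else "other")
  }

  if (nsig == 2) {
    tied <- c("AB", "AC", "BC")[!s]
    if (tied == "AB" && m["C"] > m["A"] && m["C"] > m["B"]) {
      return(paste0("A", eq, "B<C"))
    }
    if (tied == "BC" && m["A"] > m["B"] && m["A"] > m["C"]) {
      return(paste0("A>B", eq, "C"))
    }
    if (tied == "AC" && m["B"] < m["A"] && m["B"] < m["C"]) {
      return(paste0("A", eq, "C>B"))
    }
    return("other")
  }

  # exactly one significant pair
  pair <- c("AB", "AC", "BC")[s]
  g1 <- substr(pair, 1, 1); g2 <- substr(pair, 2, 2)
  hi <- if (m[g1] >= m[g2]) g1 else g2
  lo <- setdiff(c(g1, g2), hi)
  lab <- paste0(hi, ">", lo)
  if (lab %in% peak_patterns()) lab else "other"
}

#' Per-peak group statistics and pattern labels
#'
#' Extracts the peak intensity of every spectrum at each position, compares
#' the three outcome groups pairwise, and assigns each peak its intensity
#' pattern.
#'
#' @param data A preprocessed spectra table with at least two samples per
#'   group.
#' @param positions Peak positions to analyse.
#' @param half_window Search half-window for [extract_peak_intensity()].
#' @param unit `"spectrum"` pools all spectra per group; `"sample"` first
#'   averages the spectra of each sample (robust to within-sample
#'   correlation).
#' @param test,alpha_levels,p_adjust Passed to [compare_groups()].
#' @return A tibble of class `peak_stats` with one row per position:
#'   group means/SDs, pairwise p-values and stars, and the pattern label.
#' @export
build_peak_stats <- function(data, positions = core_peak_positions(),
                             half_window = 5,
                             unit = c("spectrum", "sample"),
                             test = c("wilcox", "t"),
                             alpha_levels = c(0.05, 0.01, 0.001),
                             p_adjust = "none") {
  check_dataset(data)
  unit <- match.arg(unit); test <- match.arg(test)
  missing_groups <- setdiff(GROUPS, unique(data$group))
  if (length(missing_groups) > 0) {
    abort(sprintf("group %s is missing from the data", missing_groups[1]))
  }
  X <- tryCatch(spectra_matrix(data), error = function(e) NULL)
  long <- purrr::map_dfr(positions, function(pos) {
    val <- if (!is.null(X)) {
      # shared grid: vectorized window maximum across all spectra
      w <- attr(X, "wavenumber")
      cols <- which(w >= pos - half_window & w <= pos + half_window)
      if (length(cols) == 0 || pos - half_window < min(w) ||
          pos + half_window > max(w)) {
        abort(sprintf("window [%.6g, %.6g] lies outside the spectrum grid",
                      pos - half_window, pos + half_window))
      }
      do.call(pmax, as.data.frame(X[, cols, drop = FALSE]))
    } else {
      purrr::map2_dbl(data$wavenumber, data$intensity, function(w, y) {
        extract_peak_intensity(new_spectrum(w, y), pos, half_window)
      })
    }
    tibble(position = pos, sample_id = data$sample_id,
           group = data$group, value = val)
  })
  if (unit == "sample") {
    long <- dplyr::summarise(
      dplyr::group_by(long, .data$position, .data$sample_id, .data$group),
      value = mean(.data$value), .groups = "drop")
  }
  rows <- lapply(positions, function(pos) {
    d <- long[long$position == pos, ]
    by_g <- split(d$value, d$group)[GROUPS]
    cmp <- compare_groups(by_g, test = test, alpha_levels = alpha_levels,
                          p_adjust = p_adjust)
    sig <- setNames(cmp$significant, cmp$pair)[c("AB", "AC", "BC")]
    mns <- vapply(by_g, mean, numeric(1))
    tibble(
      position = pos,
      mean_A = mns[["A"]], mean_B = mns[["B"]], mean_C = mns[["C"]],
      sd_A = sd(by_g$A), sd_B = sd(by_g$B), sd_C = sd(by_g$C),
      p_AB = cmp$p[cmp$pair == "AB"], p_AC = cmp$p[cmp$pair == "AC"],
      p_BC = cmp$p[cmp$pair == "BC"],
      stars_AB = cmp$stars[cmp$pair == "AB"],
      stars_AC = cmp$stars[cmp$pair == "AC"],
      stars_BC = cmp$stars[cmp$pair == "BC"],
      pattern = classify_pattern(mns, sig)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("peak_stats", class(out))
  out
}
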