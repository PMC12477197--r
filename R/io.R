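# Reading and writing spectra (two-column CSV/TSV, JCAMP-DX), manifests
# and whole datasets.

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         "csv" = "csv", "tsv" = "tsv", "txt" = "tsv",
         "jdx" = "jcamp", "dx" = "jcamp", "jcm" = "jcamp",
         abort(sprintf("cannot guess the spectrum format from extension '.%s'", ext)))
}

#' Read a single spectrum file
#'
#' Supports two-column CSV/TSV (wavenumber, intensity; an optional header
#' is detected) and JCAMP-DX with `##XYDATA=(X++(Y..Y))` or `##XYPOINTS`
#' blocks in plain (AFFN) form. Descending grids are sorted ascending with
#' a warning.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"jcamp"`.
#' @return A spectrum tibble (`wavenumber`, `intensity`).
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "tsv", "jcamp")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  s <- switch(format,
              csv = read_xy(path, ","),
              tsv = read_xy(path, "\t"),
              jcamp = read_jcamp(path))
  if (is.unsorted(s$wavenumber)) {
    warn(sprintf("wavenumbers in '%s' are not ascending; sorting", basename(path)))
    o <- order(s$wavenumber)
    s <- s[o, , drop = FALSE]
  }
  check_spectrum(s, arg = basename(path))
  as_tibble(s)
}

read_xy <- function(path, sep) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("'%s' is empty", path))
  start <- 1L
  first <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  if (any(is.na(suppressWarnings(as.numeric(first))))) start <- 2L
  parse_row <- function(i) {
    cells <- trimws(strsplit(lines[i], sep, fixed = TRUE)[[1]])
    if (length(cells) < 2) {
      abort(sprintf("'%s' line %d: expected two columns", path, i))
    }
    v <- suppressWarnings(as.numeric(cells[1:2]))
    if (anyNA(v)) {
      abort(sprintf("'%s' line %d: non-numeric cell '%s'", path, i,
                    cells[which(is.na(v))[1]]))
    }
    v
  }
  m <- t(vapply(seq(start, length(lines)), parse_row, numeric(2)))
  new_spectrum(m[, 1], m[, 2])
}

jcamp_value <- function(lines, key) {
  hit <- grep(paste0("^##", key, "="), lines, ignore.case = TRUE, value = TRUE)
  if (length(hit) == 0) return(NA_real_)
  suppressWarnings(as.numeric(sub("^##[^=]*=\\s*", "", hit[1])))
}

read_jcamp <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  xy_start <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  pt_start <- grep("^##XYPOINTS=|^##PEAK TABLE=", lines, ignore.case = TRUE)
  end <- grep("^##END", lines, ignore.case = TRUE)
  if (length(end) == 0) end <- length(lines) + 1L
  num_re <- "[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?"
  grab <- function(from) {
    to <- min(end[end > from]) - 1L
    body <- lines[seq(from + 1L, to)]
    body <- body[nzchar(body) & !startsWith(body, "##")]
    if (any(grepl("[A-DF-Za-df-z%@]", gsub("[eE]", "", body)))) {
      abort(sprintf("'%s': compressed (DIF/DUP) JCAMP data is not supported", path))
    }
    lapply(body, function(l) {
      as.numeric(regmatches(l, gregexpr(num_re, l))[[1]])
    })
  }
  if (length(xy_start) > 0) {
    xf <- jcamp_value(lines, "XFACTOR"); if (is.na(xf)) xf <- 1
    yf <- jcamp_value(lines, "YFACTOR"); if (is.na(yf)) yf <- 1
    firstx <- jcamp_value(lines, "FIRSTX")
    deltax <- jcamp_value(lines, "DELTAX")
    if (is.na(deltax)) {
      lastx <- jcamp_value(lines, "LASTX")
      npts <- jcamp_value(lines, "NPOINTS")
      if (is.na(lastx) || is.na(npts)) {
        abort(sprintf("'%s': need DELTAX or LASTX+NPOINTS to reconstruct the grid", path))
      }
      deltax <- (lastx - firstx) / (npts - 1)
    }
    rows <- grab(xy_start[1])
    w <- numeric(0); y <- numeric(0)
    for (r in rows) {
      if (length(r) < 2) abort(sprintf("'%s': malformed XYDATA line", path))
      x0 <- r[1] * xf
      ys <- r[-1] * yf
      w <- c(w, x0 + deltax * (seq_along(ys) - 1))
      y <- c(y, ys)
    }
    return(new_spectrum(w, y))
  }
  if (length(pt_start) > 0) {
    rows <- grab(pt_start[1])
    m <- do.call(rbind, lapply(rows, function(r) {
      matrix(r, ncol = 2, byrow = TRUE)
    }))
    return(new_spectrum(m[, 1], m[, 2]))
  }
  abort(sprintf("'%s': no XYDATA or XYPOINTS block found", path))
}

#' Write a single spectrum file
#'
#' @param s A spectrum data frame.
#' @param path Destination; format from `format` or the file extension.
#' @param format `"auto"`, `"csv"`, `"tsv"` or `"jcamp"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, format = c("auto", "csv", "tsv", "jcamp")) {
  check_spectrum(s)
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    writeLines(c(paste("wavenumber", "intensity", sep = sep),
                 paste(format(s$wavenumber, trim = TRUE, digits = 15),
                       format(s$intensity, trim = TRUE, digits = 15), sep = sep)),
               path)
  } else {
    writeLines(c("##TITLE=ramanblast spectrum",
                 "##JCAMP-DX=4.24",
                 "##DATA TYPE=RAMAN SPECTRUM",
                 "##XUNITS=1/CM", "##YUNITS=ARBITRARY UNITS",
                 sprintf("##NPOINTS=%d", nrow(s)),
                 sprintf("##FIRSTX=%.10g", s$wavenumber[1]),
                 sprintf("##LASTX=%.10g", s$wavenumber[nrow(s)]),
                 "##XFACTOR=1", "##YFACTOR=1",
                 "##XYPOINTS=(XY..XY)",
                 paste(format(s$wavenumber, trim = TRUE, digits = 15),
                       format(s$intensity, trim = TRUE, digits = 15), sep = ", "),
                 "##END="),
               path)
  }
  invisible(path)
}

#' Write a spectra table as a directory of spectrum files plus a manifest
#'
#' @param data A spectra table.
#' @param dir Output directory (created if needed).
#' @param format On-disk spectrum format, `"csv"` or `"tsv"`.
#' @return Path of the written `manifest.csv`, invisibly.
#' @export
write_dataset <- function(data, dir, format = c("csv", "tsv")) {
  check_dataset(data)
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  file <- sprintf("%s_r%02d.%s", data$sample_id, data$replicate, format)
  purrr::pwalk(list(data$wavenumber, data$intensity, file),
               function(w, y, f) {
                 write_spectrum(new_spectrum(w, y), file.path(dir, f), format)
               })
  manifest <- tibble(sample_id = data$sample_id, group = data$group,
                     grade = data$grade, replicate = data$replicate,
                     file = file)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(file.path(dir, "manifest.csv"))
}

#' Write a spectra table as one long-format CSV
#'
#' Columns: sample_id, group, grade, replicate, wavenumber, intensity.
#' @param data A spectra table.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_long <- function(data, path) {
  check_dataset(data)
  long <- tidyr::unnest(
    dplyr::select(data, dplyr::any_of(c("sample_id", "group", "grade",
                                        "replicate", "wavenumber", "intensity"))),
    cols = c("wavenumber", "intensity"))
  readr::write_csv(long, path)
  invisible(path)
}

#' Read a manifest and its referenced spectrum files
#'
#' @param manifest_path Path to a manifest CSV with columns `sample_id`,
#'   `group`, `file` (and optionally `grade`, `replicate`).
#' @return A spectra table.
#' @export
read_dataset <- function(manifest_path) {
  man <- readr::read_csv(manifest_path, show_col_types = FALSE)
  need <- c("sample_id", "group", "file")
  if (!all(need %in% names(man))) {
    abort(sprintf("manifest must contain columns %s",
                  paste0("`", need, "`", collapse = ", ")))
  }
  if (!all(man$group %in% GROUPS)) abort("manifest groups must be A, B or C")
  paths <- file.path(dirname(manifest_path), man$file)
  missing <- !file.exists(paths)
  if (any(missing)) {
    abort(sprintf("manifest references missing file '%s'", man$file[missing][1]))
  }
  spectra <- lapply(paths, read_spectrum)
  tibble(sample_id = man$sample_id, group = man$group,
         grade = if ("grade" %in% names(man)) man$grade else NA_character_,
         replicate = if ("replicate" %in% names(man)) man$replicate else
           stats::ave(seq_len(nrow(man)), man$sample_id, FUN = seq_along),
         wavenumber = purrr::map(spectra, "wavenumber"),
         intensity = purrr::map(spectra, "intensity"))
}
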