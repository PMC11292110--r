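#' Construct a chromatogram
#'
#' A chromatogram is a sampled detector trace: a strictly increasing time
#' grid (minutes) and a finite detector signal (arbitrary absorbance units,
#' e.g. mAU), plus optional acquisition metadata.
#'
#' @param time Numeric vector of sampling times in minutes, strictly
#'   increasing.
#' @param signal Numeric vector of detector response, same length as `time`,
#'   finite everywhere.
#' @param meta Named list of acquisition metadata. Recognised entries:
#'   `analyte` (label), `concentration` (mol/L), `injection_volume` (L),
#'   `flow_rate` (mL/min), `wavelength` (nm). Other entries are carried
#'   along untouched.
#'
#' @return An object of class `chromatogram`: a list with elements `time`,
#'   `signal` and `meta`.
#' @examples
#' tt <- seq(0, 10, by = 0.01)
#' ch <- chromatogram(tt, exp(-(tt - 5)^2 / 0.02), meta = list(analyte = "demo"))
#' @export
chromatogram <- function(time, signal, meta = list()) {
  time <- as.numeric(time)
  signal <- as.numeric(signal)
  if (length(time) != length(signal)) {
    stop("`time` and `signal` must have the same length", call. = FALSE)
  }
  if (length(time) < 2L) {
    stop("a chromatogram needs at least 2 samples", call. = FALSE)
  }
  if (anyNA(time) || any(!is.finite(time))) {
    stop("`time` must be finite", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  if (anyNA(signal) || any(!is.finite(signal))) {
    stop("`signal` must be finite everywhere", call. = FALSE)
  }
  if (!is.list(meta)) stop("`meta` must be a list", call. = FALSE)
  structure(list(time = time, signal = signal, meta = meta),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %d samples, %.4g-%.4g min",
              length(x$time), x$time[1], x$time[length(x$time)]))
  if (!is.null(x$meta$analyte)) cat(sprintf(", analyte: %s", x$meta$analyte))
  cat("\n")
  invisible(x)
}

#' @export
length.chromatogram <- function(x) length(x$time)

#' @export
as.data.frame.chromatogram <- function(x, ...) {
  data.frame(time = x$time, signal = x$signal)
}

#' Read a chromatogram from delimited text
#'
#' Reads a two-column (time, signal) plain-text trace. The delimiter (comma
#' or tab/whitespace) is auto-detected unless given, and a single
#' non-numeric header line is skipped automatically. Times stored in
#' seconds can be declared via `dialect$time_unit` and are converted to
#' minutes on read.
#'
#' @param path Path to the text file.
#' @param dialect List of parsing options: `delim` (`","`, `"\t"`, or `NULL`
#'   to auto-detect), `time_unit` (`"minutes"`, the default, or
#'   `"seconds"`).
#' @param meta Metadata list merged into the returned chromatogram (see
#'   [chromatogram()]); typically one row of the injection table.
#'
#' @return A [chromatogram()].
#' @seealso [write_chromatogram()], [read_injection_table()]
#' @export
read_chromatogram <- function(path, dialect = list(), meta = list()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  time_unit <- dialect$time_unit %||% "minutes"
  if (!time_unit %in% c("minutes", "seconds")) {
    stop("dialect$time_unit must be \"minutes\" or \"seconds\"", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty file: %s", path), call. = FALSE)

  delim <- dialect$delim %||%
    (if (grepl(",", lines[[min(2L, length(lines))]], fixed = TRUE)) "," else "[\t ]+")
  split_row <- function(line) strsplit(trimws(line), delim)[[1]]

  first <- suppressWarnings(as.numeric(split_row(lines[[1]])))
  start <- if (anyNA(first)) 2L else 1L  # single optional header line
  if (start > length(lines)) stop(sprintf("no data rows in %s", path), call. = FALSE)

  n <- length(lines) - start + 1L
  tt <- numeric(n); ss <- numeric(n)
  for (i in seq_len(n)) {
    fields <- suppressWarnings(as.numeric(split_row(lines[[start + i - 1L]])))
    if (length(fields) < 2L || anyNA(fields[1:2])) {
      stop(sprintf("non-numeric row at line %d of %s", start + i - 1L, path),
           call. = FALSE)
    }
    tt[i] <- fields[1]; ss[i] <- fields[2]
  }
  if (time_unit == "seconds") tt <- tt / 60
  chromatogram(tt, ss, meta = meta)
}

#' Write a chromatogram to delimited text
#'
#' Writes `time,signal` CSV with a header line, at full double precision so
#' that a read/write round-trip preserves the stored values exactly.
#'
#' @param chrom A [chromatogram()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time,signal", con)
  writeLines(sprintf("%.17g,%.17g", chrom$time, chrom$signal), con)
  invisible(path)
}

#' Estimate the baseline level of a chromatogram
#'
#' The baseline is the pooled median of the first and last 5% of samples —
#' robust and deterministic, adequate for isocratic traces where the peak
#' sits well inside the acquisition window.
#'
#' @param chrom A [chromatogram()].
#' @param edge_fraction Fraction of samples taken from each end
#'   (default 0.05).
#' @return Baseline level in signal units.
#' @export
estimate_baseline <- function(chrom, edge_fraction = 0.05) {
  stopifnot(inherits(chrom, "chromatogram"))
  stats::median(baseline_windows(chrom, edge_fraction))
}

# pooled edge samples used for both baseline level and noise estimation
baseline_windows <- function(chrom, edge_fraction = 0.05) {
  n <- length(chrom$signal)
  m <- max(1L, floor(edge_fraction * n))
  c(chrom$signal[seq_len(m)], chrom$signal[seq.int(n - m + 1L, n)])
}

#' Locate the analyte peak in a chromatogram
#'
#' Finds the apex of the baseline-subtracted trace. The apex is the global
#' maximum (earliest sample on an exact tie); the peak must clear a
#' signal-to-noise threshold relative to the noise in the pooled
#' baseline windows. Area is trapezoidal above baseline between the first
#' and last samples exceeding 1% of the apex height; asymmetry is the right
#' over left half-width at 10% of the apex height (> 1 for a tailing peak).
#' A centroid retention time (first moment over the integration window) is
#' also reported, for users who prefer centroids to apexes on tailing
#' peaks.
#'
#' @param chrom A [chromatogram()] with at least 50 samples.
#' @param snr_threshold Minimum apex height in units of the baseline-window
#'   noise standard deviation (default 5). When the baseline windows are
#'   exactly constant (noiseless traces) any positive apex is accepted.
#' @param edge_fraction Passed to [estimate_baseline()].
#' @return An object of class `peak_summary`: list with `apex_time`,
#'   `apex_height`, `baseline_level`, `area`, `asymmetry`, `centroid_time`
#'   and `snr`.
#' @export
detect_apex <- function(chrom, snr_threshold = 5, edge_fraction = 0.05) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (length(chrom$time) < 50L) {
    stop("peak detection needs at least 50 samples", call. = FALSE)
  }
  base <- baseline_windows(chrom, edge_fraction)
  baseline <- stats::median(base)
  noise_sd <- stats::sd(base)
  s <- chrom$signal - baseline
  i_apex <- which.max(s)  # which.max returns the first index on ties
  height <- s[i_apex]
  threshold <- snr_threshold * noise_sd
  if (height <= 0 || height <= threshold) {
    stop("no peak detected: apex does not exceed the signal-to-noise threshold",
         call. = FALSE)
  }

  above <- which(s >= 0.01 * height)
  i_lo <- min(above); i_hi <- max(above)
  idx <- seq.int(i_lo, i_hi)
  tt <- chrom$time[idx]; sv <- s[idx]
  area <- sum(diff(tt) * (sv[-length(sv)] + sv[-1]) / 2)
  centroid <- sum(diff(tt) * (tt[-length(tt)] * sv[-length(sv)] +
                                tt[-1] * sv[-1]) / 2) / area

  half <- 0.1 * height
  left <- cross_time(chrom$time, s, i_apex, half, direction = -1L)
  right <- cross_time(chrom$time, s, i_apex, half, direction = +1L)
  asym <- if (is.na(left) || is.na(right)) {
    NA_real_
  } else {
    (right - chrom$time[i_apex]) / (chrom$time[i_apex] - left)
  }

  structure(list(apex_time = chrom$time[i_apex],
                 apex_height = height,
                 baseline_level = baseline,
                 area = area,
                 asymmetry = asym,
                 centroid_time = centroid,
                 snr = if (noise_sd > 0) height / noise_sd else Inf),
            class = "peak_summary")
}

# linearly interpolated time where the baseline-subtracted signal crosses
# `level`, walking from the apex in `direction`
cross_time <- function(time, s, i_apex, level, direction) {
  n <- length(s)
  i <- i_apex
  while (i + direction >= 1L && i + direction <= n) {
    j <- i + direction
    if (s[j] <= level) {
      frac <- (s[i] - level) / (s[i] - s[j])
      return(time[i] + frac * (time[j] - time[i]))
    }
    i <- j
  }
  NA_real_
}

#' @export
print.peak_summary <- function(x, ...) {
  cat(sprintf(paste0("<peak_summary> apex %.4g min, height %.4g, area %.4g, ",
                     "asymmetry %.3g\n"),
              x$apex_time, x$apex_height, x$area, x$asymmetry))
  invisible(x)
}

#' @export
as.data.frame.peak_summary <- function(x, ...) {
  data.frame(apex_time = x$apex_time, apex_height = x$apex_height,
             baseline_level = x$baseline_level, area = x$area,
             asymmetry = x$asymmetry, centroid_time = x$centroid_time,
             snr = x$snr)
}

#' Describe the chromatographic frame of reference
#'
#' Bundles the void time `t0` (elution time of a non-retained marker such
#' as sodium nitrite), the flow rate, and the derived void volume
#' V_m = t0 * F / 1000 (litres). `t0` must be measured at the flow rate of
#' the binding runs.
#'
#' @param t0 Void time in minutes (> 0).
#' @param flow_rate Flow rate in mL/min (> 0).
#' @param column_dims Optional informational string (e.g. "50 x 4.6 mm").
#' @return An object of class `column_system` with elements `t0`,
#'   `flow_rate`, `V_m` and `column_dims`.
#' @examples
#' column_system(t0 = 0.298, flow_rate = 0.6)
#' @export
column_system <- function(t0, flow_rate, column_dims = NULL) {
  stopifnot(is.numeric(t0), length(t0) == 1L, is.numeric(flow_rate),
            length(flow_rate) == 1L)
  if (!(t0 > 0)) stop("`t0` must be > 0", call. = FALSE)
  if (!(flow_rate > 0)) stop("`flow_rate` must be > 0", call. = FALSE)
  structure(list(t0 = as.numeric(t0), flow_rate = as.numeric(flow_rate),
                 V_m = void_volume(t0, flow_rate), column_dims = column_dims),
            class = "column_system")
}

#' @export
print.column_system <- function(x, ...) {
  cat(sprintf("<column_system> t0 = %.4g min, F = %.4g mL/min, V_m = %.4g L\n",
              x$t0, x$flow_rate, x$V_m))
  invisible(x)
}

#' Capacity factor from retention and void times
#'
#' k' = (t_R - t0) / t0. An analyte eluting before the void marker has no
#' meaningful capacity factor for binding analysis; by default this is an
#' error, but QC reports on control columns may legitimately see
#' near-void elution, enabled via `allow_unretained`.
#'
#' @param t_R Retention time(s) in minutes.
#' @param t0 Void time in minutes (> 0).
#' @param allow_unretained If `TRUE`, `t_R < t0` returns a negative k'
#'   (with a warning) instead of an error.
#' @return Dimensionless capacity factor, vectorised over `t_R`.
#' @examples
#' capacity_factor(5.281, 0.298)
#' @export
capacity_factor <- function(t_R, t0, allow_unretained = FALSE) {
  stopifnot(is.numeric(t_R), is.numeric(t0), length(t0) == 1L)
  if (!(t0 > 0)) stop("`t0` must be > 0", call. = FALSE)
  if (any(t_R < t0)) {
    msg <- "analyte elutes before void (t_R < t0): invalid for binding analysis"
    if (allow_unretained) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  }
  (t_R - t0) / t0
}

#' Void volume of the chromatographic system
#'
#' V_m = t0 * F / 1000, in litres (t0 in minutes, F in mL/min).
#'
#' @param t0 Void time in minutes (> 0).
#' @param flow_rate Flow rate in mL/min (> 0).
#' @return Void volume in litres.
#' @examples
#' void_volume(0.298, 0.6)  # 1.788e-4 L
#' @export
void_volume <- function(t0, flow_rate) {
  stopifnot(is.numeric(t0), is.numeric(flow_rate))
  if (any(t0 <= 0)) stop("`t0` must be > 0", call. = FALSE)
  if (any(flow_rate <= 0)) stop("`flow_rate` must be > 0", call. = FALSE)
  t0 * flow_rate / 1000
}

`%||%` <- function(a, b) if (is.null(a)) b else a
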