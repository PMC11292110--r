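#' Moles of analyte per injection
#'
#' n_b = c * V_inj, the molar amount loaded onto the column in one
#' injection.
#'
#' @param concentration Analyte concentration in mol/L (> 0), vectorised.
#' @param injection_volume Injection volume in litres (> 0).
#' @return Injected amount in moles.
#' @examples
#' injected_moles(1e-3, 10e-6)  # 1 mM, 10 uL -> 1e-8 mol
#' @export
injected_moles <- function(concentration, injection_volume) {
  stopifnot(is.numeric(concentration), is.numeric(injection_volume))
  if (any(concentration <= 0)) stop("`concentration` must be > 0", call. = FALSE)
  if (any(injection_volume <= 0)) {
    stop("`injection_volume` must be > 0", call. = FALSE)
  }
  concentration * injection_volume
}

#' Transform a retention observation to linearized binding coordinates
#'
#' Under the injection-amount-dependent model, plotting
#' y = k'n_b/(1 + k') against x = k'V_m linearizes the saturable-binding
#' retention equation as y = n_a - x/K_A, so the line's slope and intercept
#' carry the binding parameters.
#'
#' @param k_prime Capacity factor(s), dimensionless. Non-positive values
#'   are excluded (dropped with a warning): an unretained analyte carries
#'   no binding information.
#' @param n_b Injected amount(s) in moles.
#' @param V_m Void volume in litres.
#' @return A data frame with columns `x` (L) and `y` (mol), one row per
#'   retained injection.
#' @export
transform_point <- function(k_prime, n_b, V_m) {
  stopifnot(is.numeric(k_prime), is.numeric(n_b), is.numeric(V_m),
            length(V_m) == 1L)
  if (length(n_b) == 1L) n_b <- rep(n_b, length(k_prime))
  stopifnot(length(k_prime) == length(n_b))
  keep <- k_prime > 0
  if (any(!keep)) {
    warning(sprintf("%d point(s) with k' <= 0 excluded from binding transform",
                    sum(!keep)), call. = FALSE)
  }
  k <- k_prime[keep]; nb <- n_b[keep]
  data.frame(x = k * V_m, y = k * nb / (1 + k))
}

#' Fit the linearized binding line
#'
#' Unweighted ordinary least squares of y on x over the transformed points.
#' A valid saturable-binding fit has negative slope; then K_A = -1/slope
#' and n_a = intercept. Both the correlation coefficient r and r-squared
#' are reported, along with standard errors and a delta-method standard
#' error and 95% confidence interval for K_A (diagnostics only — they
#' never gate the result).
#'
#' @param points Data frame with numeric columns `x` and `y`
#'   (from [transform_point()]), at least 3 rows, `x` not all equal.
#' @param analyte Optional analyte label carried into the fit.
#' @return An object of class `binding_fit`: list with `slope`,
#'   `intercept`, `r`, `r_squared`, `se_slope`, `se_intercept`, `K_A`,
#'   `n_a`, `se_K_A`, `ci_K_A` (95%), `n_points`, `points` (with `fitted`
#'   and `residual` columns) and `analyte`. When the slope is
#'   non-negative no saturable binding is detected: `K_A` and `n_a` are
#'   `NA` and a warning is raised.
#' @export
fit_binding_line <- function(points, analyte = NA_character_) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  if (nrow(points) < 3L) {
    stop("insufficient data: at least 3 points are required", call. = FALSE)
  }
  if (length(unique(points$x)) < 2L) {
    stop("x values are all equal: cannot fit a line", call. = FALSE)
  }
  fit <- stats::lm(y ~ x, data = points)
  cf <- stats::coef(fit)
  # collinear (noiseless) input triggers summary.lm's perfect-fit warning;
  # the zero standard errors it returns are exactly what we want
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  slope <- unname(cf["x"]); intercept <- unname(cf["(Intercept)"])
  se_slope <- unname(se["x"]); se_intercept <- unname(se["(Intercept)"])
  r <- stats::cor(points$x, points$y)

  K_A <- NA_real_; n_a <- NA_real_; se_K_A <- NA_real_
  ci_K_A <- c(NA_real_, NA_real_)
  if (slope < 0 && intercept > 0) {
    pars <- derive_parameters(slope, intercept)
    K_A <- pars$K_A; n_a <- pars$n_a
    # first-order (delta-method) propagation: K_A = -1/slope
    se_K_A <- se_slope / slope^2
    tq <- stats::qt(0.975, df = nrow(points) - 2L)
    ci_K_A <- K_A + c(-1, 1) * tq * se_K_A
  } else {
    warning("no saturable binding detected (non-negative slope or non-positive intercept); K_A and n_a unset",
            call. = FALSE)
  }

  points$fitted <- intercept + slope * points$x
  points$residual <- points$y - points$fitted

  structure(list(analyte = analyte,
                 slope = slope, intercept = intercept,
                 r = r, r_squared = r^2,
                 se_slope = se_slope, se_intercept = se_intercept,
                 K_A = K_A, n_a = n_a, se_K_A = se_K_A, ci_K_A = ci_K_A,
                 n_points = nrow(points), points = points,
                 monotone_violation = NA),
            class = "binding_fit")
}

#' Binding parameters from the fitted line
#'
#' K_A = -1/slope (L/mol) and n_a = intercept (mol). The intercept of the
#' linearized binding plot has the dimension of moles; published reports
#' sometimes print the same number with an mol/L unit string.
#'
#' @param slope Slope of the linearized binding line, mol/L; must be < 0.
#' @param intercept Intercept, mol; must be > 0.
#' @return List with `K_A` (L/mol) and `n_a` (mol).
#' @examples
#' derive_parameters(-1.376e-6, 1.24e-8)
#' @export
derive_parameters <- function(slope, intercept) {
  stopifnot(is.numeric(slope), length(slope) == 1L,
            is.numeric(intercept), length(intercept) == 1L)
  if (!(slope < 0)) {
    stop("parameter extraction failed: slope must be negative (saturable binding)",
         call. = FALSE)
  }
  if (!(intercept > 0)) {
    stop("parameter extraction failed: intercept must be positive",
         call. = FALSE)
  }
  list(K_A = -1 / slope, n_a = intercept)
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit>%s n = %d\n",
              if (is.na(x$analyte)) "" else paste0(" ", x$analyte), x$n_points))
  cat(sprintf("  line: y = %.4g x + %.4g   (r = %.4f, r^2 = %.4f)\n",
              x$slope, x$intercept, x$r, x$r_squared))
  if (!is.na(x$K_A)) {
    cat(sprintf("  K_A = %.4g L/mol (95%% CI %.4g-%.4g), n_a = %.4g mol\n",
                x$K_A, x$ci_K_A[1], x$ci_K_A[2], x$n_a))
  } else {
    cat("  no saturable binding detected\n")
  }
  if (isTRUE(x$monotone_violation)) {
    cat("  warning: k' not non-increasing in injected amount\n")
  }
  invisible(x)
}

#' Assemble an injection series
#'
#' A series is one analyte injected at several concentrations on one
#' column, at a common injection volume and flow rate. Either retention
#' times or capacity factors may be supplied; the missing one is derived
#' from the column's void time.
#'
#' @param analyte Analyte label.
#' @param column A [column_system()].
#' @param concentration Concentrations in mol/L, pairwise distinct.
#' @param injection_volume Common injection volume in litres.
#' @param t_R Observed retention times in minutes (optional if `k_prime`
#'   given).
#' @param k_prime Capacity factors (optional if `t_R` given).
#' @return An object of class `injection_series`: list with `analyte`,
#'   `column` and a data frame `injections` (columns `concentration`,
#'   `volume`, `n_b`, `t_R`, `k_prime`).
#' @export
injection_series <- function(analyte, column, concentration, injection_volume,
                             t_R = NULL, k_prime = NULL) {
  stopifnot(inherits(column, "column_system"), is.numeric(concentration))
  if (anyDuplicated(concentration)) {
    stop("concentrations within a series must be pairwise distinct",
         call. = FALSE)
  }
  n_b <- injected_moles(concentration, injection_volume)
  if (is.null(k_prime)) {
    if (is.null(t_R)) stop("supply `t_R` or `k_prime`", call. = FALSE)
    stopifnot(length(t_R) == length(concentration))
    k_prime <- capacity_factor(t_R, column$t0)
  } else {
    stopifnot(length(k_prime) == length(concentration))
    if (is.null(t_R)) t_R <- column$t0 * (1 + k_prime)
  }
  inj <- data.frame(concentration = concentration,
                    volume = injection_volume,
                    n_b = n_b, t_R = t_R, k_prime = k_prime)
  structure(list(analyte = analyte, column = column, injections = inj),
            class = "injection_series")
}

#' @export
print.injection_series <- function(x, ...) {
  cat(sprintf("<injection_series> %s: %d injections, %.3g-%.3g mM\n",
              x$analyte, nrow(x$injections),
              1e3 * min(x$injections$concentration),
              1e3 * max(x$injections$concentration)))
  invisible(x)
}

#' Estimate binding parameters from an injection series
#'
#' The full injection-amount-dependent analysis: computes injected moles,
#' transforms each retained injection to the linearized coordinates, fits
#' the line by ordinary least squares and derives K_A and n_a. Per-point
#' residuals are attached, and the fit is flagged when k' is not
#' non-increasing in injected amount — the saturable-binding model
#' requires retention to fall as the load rises.
#'
#' @param series An [injection_series()] with at least 3 retained
#'   injections.
#' @return A [fit_binding_line()] result with `monotone_violation` set.
#' @export
analyze_series <- function(series) {
  stopifnot(inherits(series, "injection_series"))
  inj <- series$injections
  valid <- is.finite(inj$k_prime) & inj$k_prime > 0
  if (sum(valid) < 3L) {
    stop("insufficient data: at least 3 injections with valid k' are required",
         call. = FALSE)
  }
  inj <- inj[valid, , drop = FALSE]
  pts <- transform_point(inj$k_prime, inj$n_b, series$column$V_m)
  fit <- fit_binding_line(pts, analyte = series$analyte)
  ord <- order(inj$n_b)
  fit$monotone_violation <- any(diff(inj$k_prime[ord]) > 0)
  if (fit$monotone_violation) {
    warning("k' increases with injected amount for some injections; saturable-binding assumption questionable",
            call. = FALSE)
  }
  fit
}

#' Rank ligands by association constant
#'
#' Stable descending sort on K_A; ties broken alphabetically by analyte
#' label. Fits without a valid K_A are dropped.
#'
#' @param fits Either a named numeric vector of K_A values or a named list
#'   of `binding_fit` objects.
#' @return Data frame with columns `analyte` and `K_A`, strongest binder
#'   first.
#' @examples
#' rank_ligands(c(zafirlukast = 2.193e5, pranlukast = 4.789e5,
#'                `MK-571` = 4.272e5, `rosmarinic acid` = 7.268e5))
#' @export
rank_ligands <- function(fits) {
  if (is.list(fits)) {
    ka <- vapply(fits, function(f) {
      if (inherits(f, "binding_fit")) f$K_A else as.numeric(f)
    }, numeric(1))
  } else {
    ka <- fits
  }
  if (is.null(names(ka)) || any(!nzchar(names(ka)))) {
    stop("`fits` must be named by analyte", call. = FALSE)
  }
  ka <- ka[is.finite(ka)]
  if (length(ka) < 1L) stop("no fit with a valid K_A", call. = FALSE)
  ord <- order(-ka, names(ka))
  data.frame(analyte = names(ka)[ord], K_A = unname(ka[ord]))
}

#' Read a per-series injection metadata table
#'
#' The table has one row per injection with columns `file`, `analyte`,
#' `concentration_mM`, `injection_volume_uL`, `flow_rate_mL_min` and
#' `wavelength_nm`; chromatogram files are resolved relative to `dir`.
#'
#' @param path CSV file path.
#' @return Data frame with the columns above.
#' @seealso [analyze_injection_table()]
#' @export
read_injection_table <- function(path) {
  required <- c("file", "analyte", "concentration_mM", "injection_volume_uL",
                "flow_rate_mL_min", "wavelength_nm")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop(sprintf("injection table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tab
}

#' Run the full pipeline over a table of chromatogram files
#'
#' For each analyte in the injection table: read each chromatogram, locate
#' the apex, convert to capacity factors against the supplied void time,
#' and fit the binding line.
#'
#' @param table Injection metadata data frame (see
#'   [read_injection_table()]) or a path to one.
#' @param t0 Void time in minutes at the flow rate of these runs.
#' @param dir Directory the `file` column is relative to.
#' @param measure `"apex"` (default) or `"centroid"`: which retention
#'   measure of the detected peak to use as t_R.
#' @return Named list of `binding_fit` objects, one per analyte.
#' @export
analyze_injection_table <- function(table, t0, dir = ".", measure = c("apex", "centroid")) {
  measure <- match.arg(measure)
  if (is.character(table)) table <- read_injection_table(table)
  fits <- list()
  for (an in unique(table$analyte)) {
    rows <- table[table$analyte == an, , drop = FALSE]
    flow <- unique(rows$flow_rate_mL_min)
    vol <- unique(rows$injection_volume_uL)
    if (length(flow) != 1L || length(vol) != 1L) {
      stop(sprintf("series '%s': flow rate and injection volume must be constant within a series", an),
           call. = FALSE)
    }
    col <- column_system(t0, flow)
    t_R <- vapply(rows$file, function(f) {
      pk <- detect_apex(read_chromatogram(file.path(dir, f)))
      if (measure == "apex") pk$apex_time else pk$centroid_time
    }, numeric(1))
    ser <- injection_series(an, col,
                            concentration = rows$concentration_mM * 1e-3,
                            injection_volume = vol * 1e-6,
                            t_R = unname(t_R))
    fits[[an]] <- analyze_series(ser)
  }
  fits
}
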