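#' Ground truth for a simulated binding study
#'
#' Bundles the binding parameters, column frame of reference, peak-shape
#' parameters and noise levels that define a synthetic injection study.
#' Defaults render tailing peaks on a fine acquisition grid, resembling
#' typical isocratic affinity-column traces.
#'
#' @param K_A Association constant, L/mol (> 0).
#' @param n_a Total binding-site amount on the column, mol (> 0).
#' @param column A [column_system()].
#' @param sigma Gaussian width of the rendered peak, minutes (> 0;
#'   default 0.05).
#' @param tau Exponential tailing time constant, minutes (>= 0; default
#'   0.15 — tau > 0 gives asymmetry > 1).
#' @param baseline Additive baseline level, signal units (default 0).
#' @param height_scale Peak area per injected mole, signal·min/mol
#'   (default 1e10: a 1e-8 mol injection integrates to 100 signal·min).
#' @param rel_sd_tR Relative standard deviation of multiplicative Gaussian
#'   noise on retention times (default 0 = noiseless).
#' @param detector_sd Additive white Gaussian detector noise, signal units
#'   (default 0).
#' @param seed Integer RNG seed for reproducible series (optional).
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(K_A, n_a, column,
                             sigma = 0.05, tau = 0.15,
                             baseline = 0, height_scale = 1e10,
                             rel_sd_tR = 0, detector_sd = 0,
                             seed = NULL) {
  stopifnot(inherits(column, "column_system"))
  if (!(K_A > 0)) stop("`K_A` must be > 0", call. = FALSE)
  if (!(n_a > 0)) stop("`n_a` must be > 0", call. = FALSE)
  if (!(sigma > 0)) stop("`sigma` must be > 0", call. = FALSE)
  if (tau < 0) stop("`tau` must be >= 0", call. = FALSE)
  if (rel_sd_tR < 0 || detector_sd < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  structure(list(K_A = K_A, n_a = n_a, column = column,
                 peak_shape = list(sigma = sigma, tau = tau,
                                   baseline = baseline,
                                   height_scale = height_scale),
                 noise = list(rel_sd_tR = rel_sd_tR,
                              detector_sd = detector_sd),
                 seed = seed),
            class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("<simulation_truth> K_A = %.4g L/mol, n_a = %.4g mol, V_m = %.4g L\n",
              x$K_A, x$n_a, x$column$V_m))
  invisible(x)
}

#' Capacity factor implied by the saturable-binding model
#'
#' Inverts the linearized binding relation y = n_a - x/K_A (with
#' y = k'n_b/(1+k') and x = k'V_m) for k' at a given injected amount:
#' the unique positive root of
#'
#'   V_m k'^2 + (V_m + n_b K_A - n_a K_A) k' - n_a K_A = 0.
#'
#' k' is strictly decreasing in n_b — retention shortens as the load
#' approaches the binding capacity — and its n_b -> 0 limit is the
#' linear-regime value K_A n_a / V_m. Evaluated with the cancellation-free
#' quadratic form so transformed points sit on the model line to machine
#' precision.
#'
#' @param truth A [simulation_truth()].
#' @param n_b Injected amount(s) in moles (>= 0), vectorised.
#' @return Capacity factor(s), dimensionless.
#' @export
apparent_k <- function(truth, n_b) {
  stopifnot(inherits(truth, "simulation_truth"), is.numeric(n_b))
  if (any(n_b < 0)) stop("`n_b` must be >= 0", call. = FALSE)
  k_from_params(truth$K_A, truth$n_a, truth$column$V_m, n_b)
}

k_from_params <- function(K_A, n_a, V_m, n_b) {
  b <- V_m + K_A * n_b - K_A * n_a
  cc <- K_A * n_a
  disc <- sqrt(b^2 + 4 * V_m * cc)
  # pick the algebraically equivalent branch that avoids subtracting
  # nearly equal quantities
  ifelse(b <= 0, (disc - b) / (2 * V_m), 2 * cc / (b + disc))
}

# closed-form exponentially modified Gaussian density, evaluated on the
# log scale for numerical stability at large sigma/tau ratios
emg_density <- function(t, mu, sigma, tau) {
  if (tau <= 0) return(stats::dnorm(t, mean = mu, sd = sigma))
  z <- (sigma / tau - (t - mu) / sigma) / sqrt(2)
  log_erfc <- log(2) + stats::pnorm(z * sqrt(2), lower.tail = FALSE, log.p = TRUE)
  exp(-log(2 * tau) + sigma^2 / (2 * tau^2) - (t - mu) / tau + log_erfc)
}

# offset of the EMG mode above the Gaussian centre mu (0 for tau = 0)
emg_mode_offset <- function(sigma, tau) {
  if (tau <= 0) return(0)
  stats::optimize(function(d) -emg_density(d, 0, sigma, tau),
                  interval = c(-sigma, tau + 2 * sigma), tol = 1e-12)$minimum
}

#' Render a single chromatographic peak
#'
#' Draws an exponentially modified Gaussian (EMG) peak whose mode — the
#' apex — falls exactly at t_R = t0 (1 + k'), with area proportional to
#' the injected amount, an additive baseline, and optional white detector
#' noise. tau = 0 degenerates to a symmetric Gaussian; tau > 0 gives the
#' tailing shape characteristic of overloaded affinity columns.
#'
#' @param truth A [simulation_truth()].
#' @param k_prime Capacity factor locating the apex.
#' @param n_b Injected amount in moles (scales the peak area).
#' @param duration Trace length in minutes; must cover
#'   t0(1 + k') + 5(sigma + tau). Defaults to exactly that span.
#' @param dt Sampling interval in minutes (default 0.002).
#' @param noise If `TRUE`, add detector noise at `truth$noise$detector_sd`
#'   using the current RNG state.
#' @return A [chromatogram()].
#' @export
render_peak <- function(truth, k_prime, n_b, duration = NULL, dt = 0.002,
                        noise = FALSE) {
  stopifnot(inherits(truth, "simulation_truth"), dt > 0, k_prime >= 0, n_b > 0)
  ps <- truth$peak_shape
  t_R <- truth$column$t0 * (1 + k_prime)
  needed <- t_R + 5 * (ps$sigma + ps$tau)
  if (is.null(duration)) duration <- needed
  if (duration < needed) {
    stop(sprintf("duration %.3g min too short: trace must cover %.3g min",
                 duration, needed), call. = FALSE)
  }
  mu <- t_R - emg_mode_offset(ps$sigma, ps$tau)
  tt <- seq(0, duration, by = dt)
  ss <- n_b * ps$height_scale * emg_density(tt, mu, ps$sigma, ps$tau) +
    ps$baseline
  if (noise && truth$noise$detector_sd > 0) {
    ss <- ss + stats::rnorm(length(ss), 0, truth$noise$detector_sd)
  }
  chromatogram(tt, ss, meta = list(t_R = t_R, n_b = n_b))
}

#' Render a void-marker trace
#'
#' A narrow symmetric peak at the void time t0, emulating a non-retained
#' marker such as sodium nitrite; peak detection plus [capacity_factor()]
#' on it recovers k' = 0 within the grid resolution.
#'
#' @param truth A [simulation_truth()].
#' @param sigma Marker peak width in minutes (default 0.01).
#' @param dt Sampling interval in minutes (default 0.002).
#' @return A [chromatogram()].
#' @export
generate_void_marker <- function(truth, sigma = 0.01, dt = 0.002) {
  stopifnot(inherits(truth, "simulation_truth"))
  t0 <- truth$column$t0
  duration <- max(2 * t0, t0 + 10 * sigma, 60 * dt)
  tt <- seq(0, duration, by = dt)
  ss <- stats::dnorm(tt, mean = t0, sd = sigma) + truth$peak_shape$baseline
  chromatogram(tt, ss, meta = list(analyte = "void marker", t_R = t0))
}

#' Generate a synthetic injection series with known ground truth
#'
#' For each concentration: n_b = c V_inj; the model capacity factor from
#' [apparent_k()]; an observed retention time
#' t_R = t0 (1 + k') (1 + eps) with eps ~ Normal(0, rel_sd_tR), per
#' replicate; replicates are averaged at the k' level, matching the
#' one-point-per-concentration structure of a binding plot. Optionally
#' renders a tailing-peak trace per concentration. All randomness is
#' driven by `truth$seed`, so identical seeds give bit-identical output;
#' the caller's RNG state is left untouched.
#'
#' @param truth A [simulation_truth()].
#' @param concentrations Concentrations in mol/L, positive, distinct.
#' @param injection_volume Injection volume in litres.
#' @param replicates Injections per concentration (default 1; the
#'   laboratory convention is triplicates).
#' @param with_traces If `TRUE`, also render a chromatogram per
#'   concentration (at the replicate-averaged k', with detector noise if
#'   configured).
#' @param dt Sampling interval for rendered traces, minutes.
#' @return List with `series` (an [injection_series()]), `traces` (list of
#'   chromatograms or `NULL`) and `truth` (echo of the ground truth for
#'   recovery scoring).
#' @export
generate_series <- function(truth, concentrations, injection_volume,
                            replicates = 1L, with_traces = FALSE, dt = 0.002) {
  stopifnot(inherits(truth, "simulation_truth"),
            is.numeric(concentrations), length(concentrations) >= 1L,
            replicates >= 1L)
  if (any(concentrations <= 0)) {
    stop("`concentrations` must all be > 0", call. = FALSE)
  }
  if (anyDuplicated(concentrations)) {
    stop("`concentrations` must be pairwise distinct", call. = FALSE)
  }
  if (!is.null(truth$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(truth$seed)
  }
  t0 <- truth$column$t0
  n_b <- injected_moles(concentrations, injection_volume)
  k_true <- apparent_k(truth, n_b)

  k_obs <- vapply(seq_along(n_b), function(i) {
    eps <- if (truth$noise$rel_sd_tR > 0) {
      stats::rnorm(replicates, 0, truth$noise$rel_sd_tR)
    } else {
      rep(0, replicates)
    }
    t_R_rep <- t0 * (1 + k_true[i]) * (1 + eps)
    mean((t_R_rep - t0) / t0)
  }, numeric(1))

  series <- injection_series(analyte = "synthetic", column = truth$column,
                             concentration = concentrations,
                             injection_volume = injection_volume,
                             k_prime = k_obs)
  traces <- NULL
  if (with_traces) {
    duration <- t0 * (1 + max(k_obs)) +
      5 * (truth$peak_shape$sigma + truth$peak_shape$tau)
    traces <- lapply(seq_along(k_obs), function(i) {
      render_peak(truth, k_obs[i], n_b[i], duration = duration, dt = dt,
                  noise = truth$noise$detector_sd > 0)
    })
  }
  list(series = series, traces = traces, truth = truth)
}

#' Build an injection series from measured chromatograms
#'
#' Pipeline glue for the render -> detect -> analyze path: locates the
#' peak in each trace, converts the chosen retention measure to capacity
#' factors, and assembles an [injection_series()] ready for
#' [analyze_series()].
#'
#' @param traces List of [chromatogram()]s, one per concentration, in the
#'   same order as `concentrations`.
#' @param column A [column_system()].
#' @param concentrations Concentrations in mol/L.
#' @param injection_volume Injection volume in litres.
#' @param analyte Analyte label.
#' @param measure `"apex"` (default) or `"centroid"`.
#' @return An [injection_series()].
#' @export
measure_series <- function(traces, column, concentrations, injection_volume,
                           analyte = "measured", measure = c("apex", "centroid")) {
  measure <- match.arg(measure)
  stopifnot(length(traces) == length(concentrations))
  t_R <- vapply(traces, function(ch) {
    pk <- detect_apex(ch)
    if (measure == "apex") pk$apex_time else pk$centroid_time
  }, numeric(1))
  injection_series(analyte, column, concentrations, injection_volume, t_R = t_R)
}
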