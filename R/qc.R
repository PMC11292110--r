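#' Relative standard deviation of repeated retention times
#'
#' RSD (%) = 100 * sample standard deviation (n-1 denominator) / mean.
#' The usual repeatability statistic for column-stability checks over
#' repeated injections of a probe compound.
#'
#' @param values Numeric vector of at least 2 positive retention times
#'   (minutes).
#' @return RSD in percent; 0 iff all values are equal.
#' @examples
#' rsd(c(9, 11))  # 14.14%
#' @export
rsd <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L) stop("`values` needs at least 2 entries", call. = FALSE)
  if (any(values <= 0)) stop("`values` must all be > 0", call. = FALSE)
  100 * stats::sd(values) / mean(values)
}

#' Specificity report against a control column
#'
#' Compares per-analyte capacity factors on the receptor column with those
#' on a control column (bare stationary phase). Retention on the control
#' column reflects nonspecific interaction with the support; an analyte is
#' flagged when its control k' exceeds `threshold` times its test k'.
#'
#' @param test_k Named numeric vector of capacity factors on the receptor
#'   column.
#' @param control_k Named numeric vector of capacity factors on the
#'   control column; must cover every analyte in `test_k`.
#' @param threshold Nonspecific-retention ratio above which an analyte is
#'   flagged (default 0.1).
#' @return Data frame with columns `analyte`, `test_k`, `control_k`,
#'   `ratio` and `nonspecific`, ordered by increasing `test_k`.
#' @export
specificity_report <- function(test_k, control_k, threshold = 0.1) {
  stopifnot(is.numeric(test_k), is.numeric(control_k),
            is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  if (is.null(names(test_k)) || is.null(names(control_k))) {
    stop("`test_k` and `control_k` must be named by analyte", call. = FALSE)
  }
  missing <- setdiff(names(test_k), names(control_k))
  if (length(missing)) {
    stop(sprintf("analyte(s) missing from control column: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  an <- names(test_k)
  ctrl <- control_k[an]
  ratio <- ifelse(test_k > 0, ctrl / test_k, Inf)
  out <- data.frame(analyte = an,
                    test_k = unname(test_k),
                    control_k = unname(ctrl),
                    ratio = unname(ratio),
                    nonspecific = unname(ctrl > threshold * test_k))
  out[order(out$test_k), , drop = FALSE]
}
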