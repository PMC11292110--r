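test_that("injected_moles multiplies concentration by volume and rejects zeros", {
  expect_equal(injected_moles(1.0e-3, 1.0e-5), 1.0e-8)
  expect_equal(injected_moles(0.3e-3, 1.0e-5), 3.0e-9)
  expect_error(injected_moles(0, 1e-5), "concentration")
  expect_error(injected_moles(1e-3, 0), "injection_volume")
})

test_that("transform_point maps to the linearized coordinates", {
  pt <- transform_point(1, 2e-8, 1e-4)
  expect_equal(pt$x, 1e-4)
  expect_equal(pt$y, 1e-8)

  # asymptote: y -> n_b as k' -> Inf
  expect_equal(transform_point(1e9, 2e-8, 1e-4)$y, 2e-8, tolerance = 1e-8)

  # non-positive k' is excluded with a warning
  expect_warning(pts <- transform_point(c(-0.5, 0, 2), rep(1e-8, 3), 1e-4),
                 "excluded")
  expect_equal(nrow(pts), 1L)
})

test_that("model-generated points lie exactly on y = n_a - x/K_A", {
  tr <- ra_truth()
  set.seed(42)
  n_b <- runif(50, 5e-10, 3e-8)
  k <- apparent_k(tr, n_b)
  pts <- transform_point(k, n_b, tr$column$V_m)
  resid <- tr$n_a - pts$x / tr$K_A - pts$y
  expect_lt(max(abs(resid)), 1e-18)
})

test_that("fit_binding_line recovers an exact line and tolerates duplicated x", {
  x <- seq(1e-4, 9e-4, length.out = 5)
  exact <- data.frame(x = x, y = -2e-6 * x + 1e-8)
  fit <- fit_binding_line(exact)
  expect_equal(fit$slope, -2e-6)
  expect_equal(fit$intercept, 1e-8)
  expect_equal(abs(fit$r), 1)
  expect_equal(fit$K_A * fit$slope, -1)           # consistency invariant
  expect_equal(fit$n_a, fit$intercept)

  dup <- data.frame(x = c(1e-4, 1e-4, 2e-4, 3e-4),
                    y = c(9e-9, 8e-9, 6e-9, 4e-9))
  fit2 <- fit_binding_line(dup)
  expect_lt(abs(fit2$r), 1)
  expect_true(is.finite(fit2$K_A))

  expect_error(fit_binding_line(exact[1:2, ]), "insufficient data")
  expect_error(fit_binding_line(data.frame(x = rep(1e-4, 3), y = 1:3 * 1e-9)),
               "all equal")
  # positive slope: no saturable binding, parameters unset
  expect_warning(up <- fit_binding_line(data.frame(x = x, y = 2e-6 * x + 1e-9)),
                 "no saturable binding")
  expect_true(is.na(up$K_A) && is.na(up$n_a))
})

test_that("derive_parameters reproduces published fits from slope/intercept", {
  ra <- derive_parameters(-1.376e-6, 1.24e-8)
  expect_equal(ra$K_A, 7.268e5, tolerance = 5e-3)
  expect_equal(ra$n_a, 1.237e-8, tolerance = 5e-3)

  pran <- derive_parameters(-2.09e-6, 2.6e-8)
  expect_equal(pran$K_A, 4.789e5, tolerance = 5e-3)
  expect_equal(pran$n_a, 2.598e-8, tolerance = 5e-3)

  unit <- derive_parameters(-1, 1)
  expect_equal(unit$K_A, 1)
  expect_equal(unit$n_a, 1)

  expect_error(derive_parameters(2e-6, 1e-8), "slope")
  expect_error(derive_parameters(-2e-6, -1e-8), "intercept")
})

test_that("analyze_series recovers noiseless truth and flags violations", {
  tr <- ra_truth()
  g <- generate_series(tr, ra_conc(), 1e-5)
  fit <- analyze_series(g$series)
  expect_equal(fit$K_A, tr$K_A, tolerance = 1e-6)
  expect_equal(fit$n_a, tr$n_a, tolerance = 1e-6)
  expect_false(fit$monotone_violation)

  # constructed violation: k' increasing with load
  bad <- injection_series("bad", ra_column(),
                          concentration = c(3e-4, 5e-4, 7e-4),
                          injection_volume = 1e-5,
                          k_prime = c(10, 12, 14))
  w <- capture_warnings(fb <- analyze_series(bad))
  expect_match(w, "increases", all = FALSE)
  expect_match(w, "no saturable binding", all = FALSE)  # rising k' flips the slope
  expect_true(fb$monotone_violation)

  two <- injection_series("short", ra_column(),
                          concentration = c(3e-4, 5e-4),
                          injection_volume = 1e-5, k_prime = c(12, 10))
  expect_error(analyze_series(two), "insufficient data")
})

test_that("K_A confidence interval tracks the slope uncertainty", {
  tr <- ra_truth(rel_sd_tR = 0.01, seed = 7)
  fit <- analyze_series(generate_series(tr, ra_conc(), 1e-5)$series)
  expect_gt(fit$se_K_A, 0)
  expect_lt(fit$ci_K_A[1], fit$K_A)
  expect_gt(fit$ci_K_A[2], fit$K_A)
  expect_equal(fit$se_K_A, fit$se_slope / fit$slope^2)
})

test_that("rank_ligands orders by K_A descending with alphabetical ties", {
  published <- c(zafirlukast = 2.193e5, pranlukast = 4.789e5,
                 `MK-571` = 4.272e5, `rosmarinic acid` = 7.268e5)
  rk <- rank_ligands(published)
  expect_equal(rk$analyte,
               c("rosmarinic acid", "pranlukast", "MK-571", "zafirlukast"))

  expect_equal(rank_ligands(c(solo = 1e5))$analyte, "solo")
  expect_equal(rank_ligands(c(b = 2, a = 2))$analyte, c("a", "b"))
})

test_that("injection_series enforces distinct concentrations and derives k'", {
  expect_error(injection_series("x", ra_column(), c(3e-4, 3e-4, 5e-4), 1e-5,
                                k_prime = c(3, 2, 1)),
               "distinct")
  ser <- injection_series("x", ra_column(), c(3e-4, 5e-4, 7e-4), 1e-5,
                          t_R = c(12, 10, 8))
  expect_equal(ser$injections$n_b, c(3e-9, 5e-9, 7e-9))
  expect_equal(ser$injections$k_prime, (c(12, 10, 8) - 0.298) / 0.298)
})

test_that("analyze_injection_table runs the file-based pipeline end to end", {
  dir <- withr::local_tempdir()
  tr <- ra_truth()
  conc <- ra_conc()
  g <- generate_series(tr, conc, 1e-5, with_traces = TRUE)
  files <- sprintf("ra_%02d.csv", seq_along(conc))
  for (i in seq_along(conc)) {
    write_chromatogram(g$traces[[i]], file.path(dir, files[i]))
  }
  meta <- data.frame(file = files, analyte = "rosmarinic acid",
                     concentration_mM = conc * 1e3,
                     injection_volume_uL = 10, flow_rate_mL_min = 0.6,
                     wavelength_nm = 330)
  meta_path <- file.path(dir, "series.csv")
  write.csv(meta, meta_path, row.names = FALSE)

  fits <- analyze_injection_table(read_injection_table(meta_path),
                                  t0 = 0.298, dir = dir)
  expect_named(fits, "rosmarinic acid")
  expect_equal(fits[[1]]$K_A, tr$K_A, tolerance = 0.01)
  expect_equal(fits[[1]]$n_a, tr$n_a, tolerance = 0.01)

  expect_error(read_injection_table(
    { p <- file.path(dir, "bad.csv"); write.csv(meta[, -1], p, row.names = FALSE); p }
  ), "missing column")
})
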