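# Grid co-refinement: parameter recovery on generated data, profile
# confidence ranges against a brute-force chi2 scan, and the model
# selection rule.

test_that("a noise-free X-ray curve is recovered exactly at the true grid point", {
  mix <- pg_mix()
  truep <- monolayer_params(mix, 668, 16.2, 8.0, sigma = 4.2,
                            solvent_fraction = 0.053)
  xr <- contrast_spec("xray")
  g <- gen_reflectivity(truep, list(xr), noise_rel = 0, seed = 1)
  res <- cofit_grid(g$datasets, list(xr), mix, sigma_grid = 4.2,
                    vtail_grid = 668, dq_over_q = 0.01, n_starts = 2)
  fit <- res[[1]]
  expect_true(fit$converged)
  expect_lt(abs(fit$theta[["d_tail"]] - 16.2) / 16.2, 0.005)
  expect_lt(abs(fit$theta[["d_hg"]] - 8.0) / 8.0, 0.005)
  expect_lt(abs(fit$theta[["solvent_fraction"]] - 0.053), 0.005)
})

test_that("a D2O + ACMW co-fit recovers the waters per lipid within 0.3", {
  mix <- pg_mix()
  A_M <- 668 / 16.2
  phi <- 1.0 * 30 / (A_M * 8.0)          # one water per lipid
  truep <- monolayer_params(mix, 668, 16.2, 8.0, sigma = 3.6,
                            solvent_fraction = phi)
  cd <- contrast_spec("neutron", "D2O", exchange = c(DMPG = 2))
  ca <- contrast_spec("neutron", "ACMW", exchange = c(DMPG = 2))
  g <- gen_reflectivity(truep, list(cd, ca), noise_rel = 0.01, seed = 7)
  res <- cofit_grid(g$datasets, list(cd, ca), mix, sigma_grid = 3.6,
                    vtail_grid = 668, dq_over_q = 0.07, n_starts = 3)
  expect_lt(abs(res[[1]]$derived$n_w - 1.0), 0.3)
  expect_lt(abs(res[[1]]$theta[["d_tail"]] - 16.2) / 16.2, 0.02)
})

test_that("co-fitting two contrasts is no worse than the worse single-contrast fit", {
  mix <- pg_mix()
  truep <- monolayer_params(mix, 668, 16.2, 8.0, sigma = 3.6,
                            solvent_fraction = 0.12)
  cd <- contrast_spec("neutron", "D2O", exchange = c(DMPG = 2))
  ca <- contrast_spec("neutron", "ACMW", exchange = c(DMPG = 2))
  g <- gen_reflectivity(truep, list(cd, ca), noise_rel = 0.03, seed = 21)
  err <- function(datasets, contrasts) {
    r <- cofit_grid(datasets, contrasts, mix, sigma_grid = 3.6,
                    vtail_grid = 668, dq_over_q = 0.07, n_starts = 2)[[1]]
    abs(r$theta[["d_tail"]] - 16.2)
  }
  e_both <- err(g$datasets, list(cd, ca))
  e_single <- max(err(g$datasets[1], list(cd)), err(g$datasets[2], list(ca)))
  expect_lte(e_both, e_single + 1e-6)
})

test_that("profile confidence ranges match a brute-force chi2 scan", {
  mix <- pg_mix()
  truep <- monolayer_params(mix, 668, 16.2, 8.0, sigma = 4.2,
                            solvent_fraction = 0.05)
  xr <- contrast_spec("xray")
  g <- gen_reflectivity(truep, list(xr), noise_rel = 0.02, seed = 9)
  fit <- cofit_grid(g$datasets, list(xr), mix, sigma_grid = 4.2,
                    vtail_grid = 668, dq_over_q = 0.01, n_starts = 2)[[1]]
  cr <- confidence_ranges(fit, parameters = "d_tail")
  expect_true(cr$low <= cr$best && cr$best <= cr$high)
  expect_false(cr$open_low || cr$open_high)
  # independent scan of the same profile
  target <- fit$chi2 + stats::qchisq(0.95, 1)
  best <- fit$theta[["d_tail"]]
  xs <- seq(cr$low - 0.02, cr$high + 0.02, length.out = 21)
  prof <- vapply(xs, function(v) monofilm:::profile_chi2(fit, "d_tail", v),
                 numeric(1))
  lo_bf <- stats::approx(prof[xs < best], xs[xs < best], xout = target)$y
  hi_bf <- stats::approx(prof[xs > best], xs[xs > best], xout = target)$y
  expect_equal(cr$low, lo_bf, tolerance = 2e-3)
  expect_equal(cr$high, hi_bf, tolerance = 2e-3)
})

test_that("confidence range width shrinks with the noise amplitude", {
  mix <- pg_mix()
  truep <- monolayer_params(mix, 668, 16.2, 8.0, sigma = 4.2,
                            solvent_fraction = 0.05)
  xr <- contrast_spec("xray")
  width <- function(noise) {
    g <- gen_reflectivity(truep, list(xr), noise_rel = noise, seed = 13)
    fit <- cofit_grid(g$datasets, list(xr), mix, sigma_grid = 4.2,
                      vtail_grid = 668, dq_over_q = 0.01, n_starts = 1)[[1]]
    cr <- confidence_ranges(fit, parameters = "d_tail")
    cr$high - cr$low
  }
  expect_lt(width(0.005), width(0.04))
})

test_that("model selection balances chi2 band and reference area", {
  mk <- function(chi2, A) structure(list(chi2 = chi2,
                                         derived = list(A_M = A),
                                         converged = TRUE),
                                    class = "cofit_fit")
  one <- select_best_model(list(mk(5, 42)), 41.2)
  expect_equal(one$derived$A_M, 42)
  tie <- select_best_model(list(mk(10, 41.0), mk(10, 43.0)), 41.2)
  expect_equal(tie$derived$A_M, 41.0)
  # 5 percent worse chi2 but closer area is outside a 2 percent band
  out <- select_best_model(list(mk(10, 43.0), mk(10.5, 41.2)), 41.2,
                           rel_tol = 0.02)
  expect_equal(out$derived$A_M, 43.0)
  # inside a wider band the area tie-break wins
  inn <- select_best_model(list(mk(10, 43.0), mk(10.5, 41.2)), 41.2,
                           rel_tol = 0.10)
  expect_equal(inn$derived$A_M, 41.2)
  expect_error(select_best_model(list(), 41), "no usable fits")
})
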