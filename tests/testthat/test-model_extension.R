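test_that("screening recovers perfect and inverse correlations", {
  set.seed(2)
  resid <- rnorm(35)
  rep <- screen_residual_correlations(resid,
                                      data.frame(same = resid, neg = -resid))
  expect_equal(rep$r[rep$variable == "same"], 1, tolerance = 1e-12)
  expect_equal(rep$r[rep$variable == "neg"], -1, tolerance = 1e-12)
  expect_true(all(rep$relevant))
})

test_that("zero-variance candidates are skipped with a log entry", {
  set.seed(4)
  resid <- rnorm(10)
  expect_message(
    rep <- screen_residual_correlations(resid,
                                        data.frame(flat = rep(1, 10),
                                                   ok = rnorm(10))),
    "zero-variance")
  expect_equal(rep$variable, "ok")
})

test_that("independent noise is flagged relevant in about the null rate", {
  # |r| >= 0.3 at n = 35 has null probability ~0.08
  set.seed(101)
  hits <- replicate(500, {
    r <- screen_residual_correlations(rnorm(35), data.frame(x = rnorm(35)))
    r$relevant
  })
  expect_lt(mean(hits), 0.12)
  expect_gt(mean(hits), 0.04)
})

test_that("noiseless affine residuals recover their coefficients exactly", {
  rmot <- seq(2, 20, length.out = 35)
  resid <- -0.024 * rmot + 0.264
  ext <- suppressWarnings(fit_rmot_extension(resid, rmot))  # exact fit
  expect_equal(ext$beta_rmot, -0.024, tolerance = 1e-10)
  expect_equal(ext$intercept_rmot, 0.264, tolerance = 1e-10)

  zero <- suppressWarnings(fit_rmot_extension(rep(0, 35), rmot))
  expect_equal(zero$beta_rmot, 0, tolerance = 1e-12)
  expect_equal(zero$intercept_rmot, 0, tolerance = 1e-12)
  expect_error(fit_rmot_extension(resid, rep(10, 35)), "constant")
})

test_that("PMV* application is affine with the fitted coefficients", {
  rmot <- seq(2, 20, length.out = 10)
  ext <- suppressWarnings(fit_rmot_extension(-0.024 * rmot + 0.264, rmot))
  expect_equal(predict_pmv_star(0, 11, ext), 0.264 - 0.264, tolerance = 1e-10)
  expect_equal(predict_pmv_star(1.3, 0, ext), 1.3 + 0.264, tolerance = 1e-10)
  ident <- ext; ident$beta_rmot <- 0; ident$intercept_rmot <- 0
  expect_equal(predict_pmv_star(c(-1, 0, 2), c(5, 10, 15), ident), c(-1, 0, 2))
})

test_that("day-level CI covers an injected RMOT effect at the nominal rate", {
  set.seed(88)
  cover <- replicate(400, {
    rmot <- runif(35, 2, 20)
    resid <- -0.024 * rmot + 0.264 + rnorm(35, 0, 0.06)
    ext <- fit_rmot_extension(resid, rmot)
    ext$beta_rmot_ci95[1] <= -0.024 && -0.024 <= ext$beta_rmot_ci95[2]
  })
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("preference extension recovers coefficients and needs variance", {
  pref <- seq(-1.5, 1.5, length.out = 35)
  rmot <- seq(2, 20, length.out = 35)
  base <- fit_rmot_extension(rnorm(35, 0, 0.01), rmot)
  ext <- suppressWarnings(fit_preference_extension(base, -0.742 * pref + 0.035, pref))
  expect_equal(ext$beta_pref, -0.742, tolerance = 1e-10)
  expect_equal(ext$intercept_pref, 0.035, tolerance = 1e-10)
  expect_equal(predict_pmv_star_star(0.5, 0, ext), 0.5 + 0.035,
               tolerance = 1e-10)

  z <- suppressWarnings(fit_preference_extension(base, rep(0, 35), pref))
  expect_equal(z$beta_pref, 0, tolerance = 1e-12)
  expect_error(fit_preference_extension(base, pref, rep(0, 35)), "constant")
  expect_error(predict_pmv_star_star(0.5, 0, base), "preference stage")
})

test_that("post-extension residuals are orthogonal to RMOT and refits vanish", {
  set.seed(6)
  rmot <- runif(35, 2, 20)
  resid <- -0.024 * rmot + 0.264 + rnorm(35, 0, 0.05)
  ext <- fit_rmot_extension(resid, rmot)
  resid_star <- resid - (ext$beta_rmot * rmot + ext$intercept_rmot)
  # OLS normal equations: exact orthogonality on the training days
  expect_lt(abs(sum(resid_star * (rmot - mean(rmot)))), 1e-10)
  refit <- fit_rmot_extension(resid_star, rmot)
  expect_equal(refit$beta_rmot, 0, tolerance = 1e-12)
  expect_equal(refit$intercept_rmot, 0, tolerance = 1e-12)
})

test_that("a candidate collinear with RMOT de-correlates after extension", {
  set.seed(7)
  rmot <- runif(35, 2, 20)
  clo <- 1.25 - 0.025 * rmot + rnorm(35, 0, 0.03)  # clothing tracks RMOT
  resid <- -0.024 * rmot + 0.264 + rnorm(35, 0, 0.04)
  pre <- screen_residual_correlations(resid, data.frame(rmot = rmot, clo = clo))
  expect_true(all(pre$relevant))
  expect_lt(pre$r[pre$variable == "rmot"], 0)
  expect_gt(pre$r[pre$variable == "clo"], 0)
  ext <- fit_rmot_extension(resid, rmot)
  resid_star <- resid - (ext$beta_rmot * rmot + ext$intercept_rmot)
  post <- post_extension_screen(resid_star, data.frame(rmot = rmot, clo = clo))
  expect_false(any(post$relevant))
})

test_that("extension models serialize to text and back", {
  rmot <- seq(2, 20, length.out = 35)
  ext <- fit_rmot_extension(-0.024 * rmot + 0.264 + rnorm(35, 0, 0.01), rmot)
  ext <- fit_preference_extension(ext, rnorm(35, 0, 0.01),
                                  seq(-1, 1, length.out = 35))
  path <- withr::local_tempfile(fileext = ".json")
  write_extension(ext, path)
  back <- read_extension(path)
  expect_equal(back$beta_rmot, ext$beta_rmot)
  expect_equal(back$beta_pref, ext$beta_pref)
  expect_equal(predict_pmv_star(0.2, 10, back), predict_pmv_star(0.2, 10, ext))
})
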