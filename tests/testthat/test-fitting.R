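test_that("preprocessing detrends, z-scores and averages runs", {
  n <- 180
  # an exact line is removed entirely
  line <- 3 + 0.05 * seq_len(n)
  expect_warning(out <- preprocess_runs(line), "zero-variance")
  expect_equal(as.vector(out), rep(0, n))
  expect_false(attr(out, "ok"))
  # z-score contract on a single noisy run
  set.seed(5)
  run <- rnorm(n) + 0.2 * seq_len(n)
  out <- preprocess_runs(run)
  expect_equal(mean(out), 0, tolerance = 1e-12)
  expect_equal(stats::sd(out), 1, tolerance = 1e-12)
  # two identical runs average to either one
  two <- rbind(run, run)
  expect_equal(as.vector(preprocess_runs(two)), as.vector(out))
})

test_that("coarse stage finds exact bank predictions and respects sign", {
  scaf <- default_scaffold()
  bank <- default_bank()
  idx <- 2500L
  p <- bank$params[idx, ]
  y <- prfmap:::.predict_unit(scaf, p$x0, p$y0, p$sigma)
  cf <- coarse_fit(prfmap:::.detrend(scaf, y), bank)
  expect_equal(cf$index, idx)
  expect_equal(cf$r, 1, tolerance = 1e-10)
  # a negated prediction anticorrelates there, so the argmax moves away
  cf_neg <- coarse_fit(-prfmap:::.detrend(scaf, y), bank)
  expect_true(cf_neg$index != idx)
  expect_lt(stats::cor(bank$preds[, idx], -prfmap:::.detrend(scaf, y)), -0.99)
  expect_error(coarse_fit(rep(0, scaf$n), bank), "zero variance")
})

test_that("noiseless off-grid vertex snaps to the nearest coarse candidate", {
  scaf <- default_scaffold()
  bank <- default_bank()
  truth <- c(x0 = 1.62, y0 = -2.13, sigma = 0.8)
  y <- prfmap:::.predict_unit(scaf, truth[1], truth[2], truth[3])
  cf <- coarse_fit(prfmap:::.detrend(scaf, y), bank)
  # brute-force oracle over the full bank
  v <- prfmap:::.detrend(scaf, y); v <- v - mean(v)
  r_all <- as.vector(crossprod(bank$preds, v / sqrt(sum(v^2))))
  expect_equal(cf$index, which.max(r_all))
  expect_lte(abs(cf$x0 - truth[["x0"]]), 0.25)
  expect_lte(abs(cf$y0 - truth[["y0"]]), 0.25)
})

test_that("fine stage recovers noiseless parameters and improves on coarse", {
  scaf <- default_scaffold()
  bank <- default_bank()
  cases <- list(c(1.5, -2.0, 0.8), c(-2.3, 1.1, 0.5), c(0.9, 2.6, 1.4))
  for (tr in cases) {
    y <- predict_timeseries(prf_params(tr[1], tr[2], tr[3], beta = 2.5,
                                       baseline = 1), scaf)
    fit <- prf_fit(y, scaf, bank = bank)
    expect_lt(abs(coef(fit)[["x0"]] - tr[1]), 0.05)
    expect_lt(abs(coef(fit)[["y0"]] - tr[2]), 0.05)
    expect_lt(abs(coef(fit)[["sigma"]] - tr[3]) / tr[3], 0.05)
    expect_gt(fit$r_squared, 0.99)
    expect_true(fit$converged)
    expect_gte(fit$r_squared, fit$coarse$r^2)  # fine never loses to coarse
    expect_gt(coef(fit)[["beta"]], 0)
  }
})

test_that("fitted R-squared stays near the null level on structureless noise", {
  scaf <- default_scaffold()
  bank <- default_bank()
  set.seed(42)
  r2 <- replicate(200, prf_fit(rnorm(scaf$n), scaf, bank = bank)$r_squared)
  expect_lt(stats::median(r2), 0.05)
  expect_lt(stats::quantile(r2, 0.95), 0.08)
})

test_that("degenerate series are flagged instead of fitted", {
  scaf <- default_scaffold()
  bank <- default_bank()
  expect_warning(fit <- prf_fit(rep(2, scaf$n), scaf, bank = bank),
                 "zero-variance")
  expect_false(fit$converged)
  expect_true(fit$flat)
  expect_equal(fit$r_squared, 0)
})

test_that("polar angle and eccentricity derive from the centre", {
  expect_equal(derive_polar_ecc(1, 0), cbind(polar_rad = 0, ecc_deg = 1))
  expect_equal(derive_polar_ecc(0, 2), cbind(polar_rad = pi / 2, ecc_deg = 2))
  expect_equal(derive_polar_ecc(-3, -4),
               cbind(polar_rad = atan2(-4, -3), ecc_deg = 5))
  expect_equal(derive_polar_ecc(0, 0), cbind(polar_rad = 0, ecc_deg = 0))
})

test_that("dataset fitting is deterministic and respects vertex identity", {
  scaf <- default_scaffold()
  bank <- default_bank()
  truth <- sample_ground_truth(n_per_area = 4, seed = 3, band_fraction = 1)
  ds <- simulate_runs(truth, scaf, noise = noise_model(white_sd = 2),
                      condition_gains = c(mapping = 1), seed = 3)
  f1 <- fit_prf_dataset(ds, scaf, bank = bank)
  f2 <- fit_prf_dataset(ds, scaf, bank = bank)
  expect_identical(f1, f2)
  expect_identical(nrow(f1), nrow(truth))
  expect_identical(f1$vertex_id, truth$vertex_id)
  # vertex relabelling equivariance: permuting vertices permutes rows
  perm <- c(7, 1, 4, 12, 2, 9, 3, 11, 5, 10, 8, 6)
  ds_perm <- ds
  ds_perm$ground_truth <- ds$ground_truth[perm, ]
  ds_perm$series$mapping <- lapply(ds$series$mapping,
                                   function(m) m[perm, , drop = FALSE])
  f3 <- fit_prf_dataset(ds_perm, scaf, bank = bank)
  expect_equal(f3$x0, f1$x0[perm])
  expect_equal(f3$r_squared, f1$r_squared[perm])
  # empty vertex set
  ds0 <- ds
  ds0$ground_truth <- ds$ground_truth[0, ]
  ds0$series$mapping <- lapply(ds$series$mapping,
                               function(m) m[0, , drop = FALSE])
  expect_identical(nrow(fit_prf_dataset(ds0, scaf, bank = bank)), 0L)
  # design mismatch is caught
  ds_bad <- ds
  ds_bad$series$mapping[[1]] <- ds$series$mapping[[1]][, 1:100]
  expect_error(fit_prf_dataset(ds_bad, scaf, bank = bank), "match")
})

test_that("high-SNR mapping runs recover nearly all centres within a quarter degree", {
  scaf <- default_scaffold()
  bank <- default_bank()
  truth <- sample_ground_truth(n_per_area = 10, seed = 11, band_fraction = 1)
  ds <- simulate_runs(truth, scaf, noise = noise_model(white_sd = 1),
                      condition_gains = c(mapping = 1), seed = 11)
  fits <- fit_prf_dataset(ds, scaf, bank = bank)
  err <- sqrt((fits$x0 - truth$x0)^2 + (fits$y0 - truth$y0)^2)
  expect_gte(mean(err < 0.25), 0.95)
})
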