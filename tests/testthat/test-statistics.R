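test_that("quadrant band filter keeps the carpet interior only", {
  fits <- data.frame(x0 = c(1.0, 0.5, 3.2, -2.0, 0.75, -3.0),
                     y0 = c(1.0, 2.0, 1.0, -1.5, 3.0, -0.75))
  expect_identical(roi_filter(fits),
                   c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE))  # bounds inclusive
  expect_error(roi_filter(data.frame(a = 1)), "x0")
  expect_error(roi_band(inner_deg = 3, outer_deg = 1), "inner")
})

test_that("responsive fraction applies a strict threshold", {
  fits <- data.frame(r_squared = c(0.2, 0.2, 0.2))
  expect_equal(responsive_fraction(fits), 1)
  fits2 <- data.frame(r_squared = c(0.05, 0.051, 0.2, 0.01))
  expect_equal(responsive_fraction(fits2), 0.5)  # 0.05 itself excluded
  expect_error(responsive_fraction(fits2, mask = rep(FALSE, 4)), "undefined")
})

test_that("prediction correlation is exact on matched data and null on noise", {
  scaf <- default_scaffold()
  truth <- sample_ground_truth(n_per_area = 5, seed = 21, band_fraction = 1)
  preds <- t(sapply(seq_len(nrow(truth)), function(v)
    predict_timeseries(prf_params(truth$x0[v], truth$y0[v], truth$sigma[v]),
                       scaf)))
  # observed series enter after preprocessing, like real data
  obs <- t(apply(preds, 1, function(y) as.vector(preprocess_runs(y))))
  pc <- prediction_correlation(obs, truth, scaf)
  expect_equal(unname(pc$r), rep(1, nrow(truth)), tolerance = 1e-9)
  expect_equal(pc$summary, 1, tolerance = 1e-6)
  # independent noise: Fisher-z mean ~ 0 at 500 vertices
  truth_big <- sample_ground_truth(n_per_area = 167, seed = 22)
  set.seed(23)
  noise <- matrix(rnorm(nrow(truth_big) * scaf$n), nrow(truth_big))
  pc0 <- prediction_correlation(noise, truth_big, scaf)
  expect_lt(abs(pc0$summary), 0.02)
  # antisymmetry of the Fisher-z average
  expect_equal(fisher_z_mean(c(0.5, -0.5)), 0)
  expect_equal(tanh(mean(atanh(c(0.5, -0.5)))), 0)
})

test_that("permutation test attains its floor on matched data and enumerates tiny cases", {
  scaf <- default_scaffold()
  truth <- sample_ground_truth(n_per_area = 8, seed = 31, band_fraction = 1)
  ds <- simulate_runs(truth, scaf, noise = noise_model(white_sd = 1),
                      condition_gains = c(mapping = 1), seed = 31)
  obs <- t(sapply(seq_len(nrow(truth)), function(v)
    preprocess_runs(do.call(rbind,
                            lapply(ds$series$mapping, function(m) m[v, ])))))
  res <- permutation_test(obs, truth, scaf, n_perm = 1000, seed = 1)
  expect_equal(res$p_value, 1 / 1001)
  expect_equal(res$p_value, (sum(res$null_zbars >= res$observed_zbar) + 1) /
                 (res$n_perm + 1))
  # reproducible given seed
  res2 <- permutation_test(obs, truth, scaf, n_perm = 1000, seed = 1)
  expect_identical(res$null_zbars, res2$null_zbars)
  # 2 vertices, 1 permutation: p is 1/2 or 1
  two <- truth[1:2, ]
  res3 <- permutation_test(obs[1:2, ], two, scaf, n_perm = 1, seed = 5)
  expect_true(res3$p_value %in% c(0.5, 1))
  expect_error(permutation_test(obs, truth, scaf, n_perm = 0), "n_perm")
  expect_error(permutation_test(obs[1, , drop = FALSE], truth[1, ], scaf),
               "2 vertices")
})

test_that("circular correlation is rotation invariant and null for independent angles", {
  set.seed(41)
  a <- runif(50, -pi, pi)
  noise <- rnorm(50, sd = 0.3)
  expect_equal(circular_correlation(a, a), 1)
  expect_equal(circular_correlation(a, a + 1.3), 1, tolerance = 1e-12)
  # invariant to adding constants to either vector and to joint negation
  b <- a + noise
  r0 <- circular_correlation(a, b)
  expect_equal(circular_correlation(a + 0.7, b - 2.1), r0, tolerance = 1e-12)
  expect_equal(circular_correlation(-a, -b), r0, tolerance = 1e-12)
  # independent uniform angles decorrelate
  set.seed(42)
  u1 <- runif(1000, -pi, pi); u2 <- runif(1000, -pi, pi)
  expect_lt(abs(circular_correlation(u1, u2)), 0.08)
  expect_warning(r <- circular_correlation(rep(1, 5), u1[1:5]), "variance")
  expect_true(is.na(r))
  expect_error(circular_correlation(1:2, 1:3), "equal-length")
})

test_that("parameter consistency matrices separate copied from scrambled maps", {
  set.seed(51)
  n <- 60
  base <- data.frame(
    vertex_id = sprintf("v%02d", 1:n), area = "V1", condition = "mapping",
    sigma = runif(n, 0.3, 1.5), beta = runif(n, 0.5, 2),
    r_squared = runif(n, 0, 1), polar_rad = runif(n, -pi, pi),
    ecc_deg = runif(n, 0.5, 3))
  copy <- base; copy$condition <- "kanizsa"
  scram <- base; scram$condition <- "occlusion"
  scram$sigma <- runif(n, 0.3, 1.5)  # sigma replaced by independent noise
  fits <- rbind(base, copy, scram)
  cm <- parameter_correlations(fits)
  pick <- function(p, a, b) cm$r[cm$parameter == p &
                                 ((cm$cond_a == a & cm$cond_b == b) |
                                  (cm$cond_a == b & cm$cond_b == a))]
  for (p in c("polar", "ecc", "sigma", "beta", "r_squared"))
    expect_equal(pick(p, "mapping", "kanizsa"), 1, tolerance = 1e-9)
  expect_lt(abs(pick("sigma", "mapping", "occlusion")), 0.3)
  expect_equal(pick("ecc", "mapping", "occlusion"), 1, tolerance = 1e-9)
  expect_identical(cm$method[cm$parameter == "polar"][1], "circular")
  # masking drops vertices
  cm2 <- parameter_correlations(fits, mask = seq_len(n) <= 2)
  expect_true(all(is.na(cm2$r)))
})

test_that("gaze MAD matches hand-computable traces", {
  tr <- data.frame(x_deg = c(0.3, -0.3, 0.3, -0.3), y_deg = rep(0, 4))
  m <- gaze_mad(tr)
  expect_equal(unname(m), c(0.3, 0))
  expect_error(gaze_mad(data.frame()), "x_deg")
})
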