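test_that("parameter sampling stays in bounds and is uniform per column", {
  space <- parameter_space()
  expect_equal(nrow(space), 14)
  X <- sample_parameter_sets(space, 1e4, seed = 5)
  expect_identical(X, sample_parameter_sets(space, 1e4, seed = 5))
  for (j in seq_len(ncol(X))) {
    expect_true(all(X[, j] >= space$low[j] & X[, j] <= space$high[j]))
    p <- suppressWarnings(stats::ks.test(
      X[, j], "punif", space$low[j], space$high[j]))$p.value
    expect_gt(p, 1e-3)
  }
})

test_that("physiological filter enforces pathway ordering and the RR range", {
  base <- function(r_min_sp, r_min_fp)
    model_params(pathway_params(r_min_sp, 0, 100, 25, 10, 150),
                 pathway_params(r_min_fp, 0, 100, 5, 5, 150))
  expect_true(physiological_filter(base(250, 600))$accept)
  rej <- physiological_filter(base(400, 300))
  expect_false(rej$accept)
  expect_equal(rej$reason, "refractory_ordering")
  # curves that cross between the endpoints must be caught by the dense grid
  cross <- model_params(pathway_params(300, 300, 50, 25, 10, 150),
                        pathway_params(420, 100, 300, 5, 5, 150))
  # SP: 300 -> 600 fast; FP: 420 -> 520 slow; SP overtakes FP mid-range
  expect_false(physiological_filter(cross)$accept)
  ok <- base(250, 600)
  expect_false(physiological_filter(ok, rr_mean = 1200)$accept)
  expect_false(physiological_filter(ok, rr_mean = 250)$accept)
  expect_true(physiological_filter(ok, rr_mean = 656)$accept)
  # delay ordering: SP must be slower at every gap
  slowfp <- model_params(pathway_params(250, 0, 100, 5, 5, 150),
                         pathway_params(600, 0, 100, 25, 10, 150))
  expect_equal(physiological_filter(slowfp)$reason, "delay_ordering")
})

test_that("KS distance matches the pooled brute force and its properties", {
  expect_equal(ks_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_distance(c(0, 0, 0), c(1, 1, 1)), 1)
  expect_equal(ks_distance(c(1, 2), c(1, 3)), 0.5)
  expect_error(ks_distance(numeric(0), 1), "non-empty")
  set.seed(12)
  for (k in 1:200) {
    a <- runif(sample(3:60, 1))
    b <- c(a[seq_len(sample(0:2, 1))], rnorm(sample(3:60, 1))) # some ties
    d <- ks_distance(a, b)
    expect_equal(d, oracle_ks(a, b), tolerance = 1e-12)
    expect_true(d >= 0 && d <= 1)
    expect_equal(ks_distance(b, a), d)
    cc <- runif(20)
    expect_lte(d, ks_distance(a, cc) + ks_distance(cc, b) + 1e-12)
  }
})

test_that("sensitivity coefficient degenerate and calibration cases", {
  set.seed(13)
  x <- runif(3000)
  expect_equal(sensitivity_coefficient(x, rep(1, 3000), seed = 1)$s, 0)
  expect_equal(dummy_threshold(rep(2, 3000), seed = 1), 0)
  # D = 2: a single KS value, median of one
  d2 <- dummy_threshold(rnorm(3000), C = 15, D = 2, seed = 2)
  expect_length(d2, 1)
  expect_true(d2 >= 0 && d2 <= 1)
  # an independent column concentrates near the dummy threshold
  ratio <- replicate(5, {
    y <- rnorm(3000)
    sensitivity_coefficient(runif(3000), y, seed = NULL)$s /
      dummy_threshold(y, seed = NULL)
  })
  expect_true(all(ratio > 0.5 & ratio < 2))
  # empty conditioning intervals are skipped with a warning
  xg <- c(runif(500), runif(500) + 10)
  expect_warning(sensitivity_coefficient(xg, rnorm(1000), seed = 3), "empty")
})

test_that("dummy threshold shrinks with sample size", {
  set.seed(14)
  d <- vapply(c(1e3, 1e4, 1e5), function(n)
    median(replicate(3, dummy_threshold(rnorm(n)))), numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("a degenerate space isolates the atrial mean as the top input", {
  # collapse everything except mu to near-points around fitted means
  space <- parameter_space()
  pt <- c(339, 232, 160, 20, 39, 171, 493, 369, 162, 7, 23, 163, NA, 20)
  for (j in seq_len(14)) {
    if (space$parameter[j] == "mu") next
    space$low[j] <- pt[j] - 1e-3
    space$high[j] <- pt[j] + 1e-3
  }
  res <- run_sensitivity_study(space, K = 1500, n_aa = 6000, n_rr = 800,
                               D = 200, seed = 2, min_accepted = 800)
  co <- res$coefficients
  s_mu <- co$s_mean[co$parameter == "mu"]
  expect_true(co$influential_mean[co$parameter == "mu"])
  expect_gt(s_mu, 2 * max(co$s_mean[co$parameter != "mu"]))
  expect_true(all(is.finite(as.matrix(co[, c("s_mean", "s_rmssd", "s_sampen")]))))
  expect_true(all(res$dataset$Y[, "rr_mean"] >= 300 &
                    res$dataset$Y[, "rr_mean"] <= 1000))
})

test_that("the study aborts cleanly when too few sets survive", {
  space <- parameter_space()
  expect_error(run_sensitivity_study(space, K = 20, n_aa = 500, n_rr = 100,
                                     seed = 3, min_accepted = 19),
               "accepted")
})
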