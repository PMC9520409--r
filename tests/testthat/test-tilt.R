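test_that("protocol validation pins the supine reference", {
  p <- tilt_protocol()
  expect_equal(p$labels, c("supine", "hdt", "hut"))
  expect_error(tilt_protocol(a_r = c(0.9, 1, 1)), "supine")
  expect_error(tilt_protocol(durations_s = c(0, 300, 300)))
})

test_that("synthetic AFR trend hits anchors and handles the noiseless case", {
  afr <- synth_afr_trend(seed = 17)
  expect_equal(nrow(afr), 900 / 0.02)
  expect_equal(diff(afr$time_s)[1], 0.02, tolerance = 1e-9)
  segs <- list(c(0, 300), c(300, 600), c(600, 900))
  anchors <- c(6.78, 6.62, 6.84)
  for (k in 1:3) {
    i <- afr$time_s >= segs[[k]][1] & afr$time_s < segs[[k]][2]
    expect_equal(mean(afr$afr_hz[i]), anchors[k], tolerance = 0.01 * anchors[k])
  }
  flat <- synth_afr_trend(anchors = c(7, 7, 7), noise_sd = 0, drift_amp = 0,
                          seed = 1)
  expect_true(all(flat$afr_hz == 7))
})

test_that("AA parameter estimation is a windowed mean/sd of 1000/AFR", {
  # constant AFR: mu = 1000/6.78, sigma = 0 -> generator error path
  const <- synth_afr_trend(anchors = c(6.78, 6.78, 6.78), noise_sd = 0,
                           drift_amp = 0, seed = 1)
  expect_error(estimate_aa_params_from_afr(const), "sigma")
  # sinusoidal AFR tracks a direct recomputation
  t <- seq(0, 120 - 0.02, by = 0.02)
  afr <- structure(data.frame(time_s = t,
                              afr_hz = 6.7 + 0.5 * sin(2 * pi * t / 17)),
                   class = c("afr_trend", "data.frame"))
  est <- estimate_aa_params_from_afr(afr, window_s = 60)
  w <- as.integer(60 / 0.02)
  expect_equal(nrow(est), length(t) - w + 1)
  x <- 1000 / afr$afr_hz
  for (i in sample(nrow(est), 4)) {
    idx <- i:(i + w - 1)
    expect_equal(est$mu_ms[i], mean(x[idx]), tolerance = 1e-9)
    expect_equal(est$sigma_ms[i], sd(x[idx]), tolerance = 1e-9)
  }
  short <- structure(data.frame(time_s = t[1:100], afr_hz = rep(6.7, 100)),
                     class = c("afr_trend", "data.frame"))
  expect_error(estimate_aa_params_from_afr(short, window_s = 60), "longer")
})

test_that("population trend is smooth and anchored at the segment level", {
  trend <- population_aa_trend(n_patients = 8, seed = 18)
  expect_s3_class(trend, "aa_param_trend")
  seg <- function(col, w) mean(trend[[col]][trend$time_s >= w[1] &
                                              trend$time_s < w[2]])
  mu_sup <- seg("mu_ms", c(60, 300))
  mu_hdt <- seg("mu_ms", c(360, 600))
  mu_hut <- seg("mu_ms", c(660, 900))
  expect_equal(mu_sup, 150, tolerance = 7) # approx 1000/6.78 plus convexity
  expect_gt(mu_hdt, mu_sup) # AFR falls in HDT, AA mean rises
  expect_lt(mu_hut, mu_hdt) # AFR rises in HUT
  expect_true(all(trend$sigma_ms > 5 & trend$sigma_ms < 40))
})

test_that("stand-in ensembles respect the physiological ordering", {
  ens <- generate_tilt_ensemble(6, seed = 19)
  expect_length(ens, 6)
  for (mp in ens) expect_true(physiological_filter(mp)$accept)
})

test_that("original model equals extended with unit scales; averaging is sane", {
  ens <- generate_tilt_ensemble(2, seed = 20)
  trend <- aa_param_trend(c(0, 900), c(150, 150), c(20, 20))
  unit <- tilt_protocol(a_r = c(1, 1, 1), a_d = c(1, 1, 1))
  a <- run_tilt_experiment(ens, trend, unit, realizations = 1, seed = 21,
                           extended = TRUE)
  b <- run_tilt_experiment(ens, trend, unit, realizations = 1, seed = 21,
                           extended = FALSE)
  expect_identical(a$averaged, b$averaged)
  # population average of a single run equals that run
  one <- run_tilt_experiment(ens[1], trend, unit, realizations = 1, seed = 22,
                             keep_runs = TRUE)
  tr <- one$runs[[1]]$mean
  grid_val <- approx(tr$time_s, tr$value, xout = one$averaged$time_s,
                     rule = 1)$y
  expect_equal(one$averaged$rr_mean_ms, grid_val)
  expect_error(run_tilt_experiment(list(), trend, unit, seed = 1), "ensemble")
})

test_that("position comparison reduces trends to a 3 x 3 table", {
  av <- data.frame(time_s = 0:899, rr_mean_ms = 600, rr_v_ms = 150,
                   rr_i = 1.4)
  tab <- compare_positions(av)
  expect_equal(dim(tab), c(3L, 4L))
  expect_true(all(tab$rr_mean_ms == 600))
  expect_true(all(tab$rr_i == 1.4))
  av2 <- av
  av2$rr_mean_ms <- ifelse(av$time_s < 300, 500, 700)
  tab2 <- compare_positions(av2)
  expect_equal(tab2$rr_mean_ms, c(500, 700, 700))
})

test_that("selection ranks a self-target first and beats the population mean", {
  ens <- generate_tilt_ensemble(8, seed = 23)
  ch <- matrix(c(runif(8, 500, 900), runif(8, 80, 220), runif(8, 0.8, 1.8)),
               ncol = 3)
  sel <- select_parameter_sets(ens, targets = ch[5, ], n_select = 1,
                               characteristics = ch)
  expect_identical(sel[[1]], ens[[5]])
  expect_error(select_parameter_sets(ens, ch[1, ], n_select = 9,
                                     characteristics = ch), "exceeds")
  sel3 <- select_parameter_sets(ens, targets = ch[5, ], n_select = 3,
                                characteristics = ch)
  picked <- attr(sel3, "order")[1:3]
  sds <- apply(ch, 2, sd)
  d <- sqrt(colSums((t(ch) / sds - ch[5, ] / sds)^2))
  expect_true(mean(d[picked]) <= mean(d))
})
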