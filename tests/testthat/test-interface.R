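test_that("series CSVs round-trip byte-stably", {
  td <- withr::local_tempdir()
  aa <- cumsum(sample_intervals(aa_params(150, 20), 1e5, seed = 31))
  f1 <- file.path(td, "aa.csv")
  f2 <- file.path(td, "aa2.csv")
  write_aa_csv(aa, f1)
  x <- read_aa_csv(f1)
  expect_equal(x, as.numeric(aa), tolerance = 1e-12)
  write_aa_csv(x, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  rr <- rr_series(runif(30, 500, 900), valid = runif(30) > 0.1)
  fr <- file.path(td, "rr.csv")
  write_rr_csv(rr, fr)
  rr2 <- read_rr_csv(fr)
  expect_equal(rr2$intervals, rr$intervals, tolerance = 1e-12)
  expect_identical(rr2$valid, rr$valid)
  tr <- aa_param_trend(c(0, 60, 120), c(150, 155, 149), c(20, 21, 19))
  ft <- file.path(td, "trend.csv")
  write_trend_csv(tr, ft)
  expect_equal(read_trend_csv(ft)$mu_ms, tr$mu_ms)
  afr <- synth_afr_trend(durations_s = c(2, 2, 2), seed = 1)
  fa <- file.path(td, "afr.csv")
  write_afr_csv(afr, fa)
  expect_equal(read_afr_csv(fa)$afr_hz, afr$afr_hz, tolerance = 1e-12)
})

test_that("parameter JSON and protocol YAML round-trip", {
  td <- withr::local_tempdir()
  mp <- fx_model(a_r = 0.95, a_d = 1.1)
  fp <- file.path(td, "params.json")
  write_params_json(mp, fp)
  mp2 <- read_params_json(fp)
  expect_equal(unclass(mp2$sp), unclass(mp$sp))
  expect_equal(mp2$a_r, 0.95)
  ens <- generate_tilt_ensemble(3, seed = 33)
  fe <- file.path(td, "ens.json")
  write_ensemble_json(ens, fe)
  ens2 <- read_ensemble_json(fe)
  expect_equal(unclass(ens2[[2]]$fp), unclass(ens[[2]]$fp))
  pr <- tilt_protocol(a_r = c(1, 1, 0.95), a_d = c(1, 0.9, 0.9))
  fy <- file.path(td, "protocol.yaml")
  write_protocol(pr, fy)
  pr2 <- read_protocol(fy)
  expect_equal(pr2$a_d, pr$a_d)
  expect_equal(pr2$durations_s, pr$durations_s)
})

test_that("malformed files give parse errors naming column and row", {
  td <- withr::local_tempdir()
  f <- file.path(td, "bad.csv")
  writeLines(c("wrong_name", "1", "2"), f)
  expect_error(read_aa_csv(f), "missing column 'time_ms'")
  writeLines(c("time_ms", "1", "oops", "3"), f)
  expect_error(read_aa_csv(f), "column 'time_ms' at data row 2")
  writeLines(c("time_ms", "5", "4"), f)
  expect_error(read_aa_csv(f), "strictly increasing")
  writeLines(c("rr_ms,valid", "500,1"), f)
  expect_silent(read_rr_csv(f))
  writeLines(c("rr_ms", "500"), f)
  expect_error(read_rr_csv(f), "missing column 'valid'")
})

test_that("manifests require a seed and reproduce summaries", {
  td <- withr::local_tempdir()
  f <- file.path(td, "manifest.json")
  expect_error(run_manifest(list(K = 10), list(x = 1), f), "seed")
  m <- run_manifest(list(seed = 7, K = 10), list(accept = 0.5), f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$package, "avnodenet")
  expect_equal(j$seeds$master, 7)
  expect_equal(j$summary$accept, 0.5)
  expect_true(nzchar(j$version))
})

test_that("the CLI runs simulate, generate-aa and metrics end to end", {
  td <- withr::local_tempdir()
  pfile <- file.path(td, "params.json")
  write_params_json(fx_model(), pfile)
  aafile <- file.path(td, "aa.csv")
  out1 <- file.path(td, "aa_gen.csv")
  suppressMessages(avnode_main(c("generate-aa", "--mu", "150", "--sigma", "20",
                                 "--n", "500", "--seed", "5",
                                 "--out", out1)))
  aa <- read_aa_csv(out1)
  expect_length(aa, 500)
  expect_true(file.exists(paste0(out1, ".manifest.json")))
  # reproducibility of the full command
  out1b <- file.path(td, "aa_gen_b.csv")
  suppressMessages(avnode_main(c("generate-aa", "--mu", "150", "--sigma", "20",
                                 "--n", "500", "--seed", "5",
                                 "--out", out1b)))
  expect_identical(readBin(out1, "raw", file.size(out1)),
                   readBin(out1b, "raw", file.size(out1b)))
  write_aa_csv(aa, aafile)
  vfile <- file.path(td, "v.csv")
  suppressMessages(avnode_main(c("simulate", "--params", pfile,
                                 "--aa", aafile, "--out", vfile)))
  v <- read_aa_csv(vfile)
  expect_true(length(v) > 50 && all(diff(v) > 0))
  rrfile <- file.path(td, "rr.csv")
  write_rr_csv(rr_series(diff(v)), rrfile)
  mfile <- file.path(td, "metrics.csv")
  suppressMessages(avnode_main(c("metrics", "--rr", rrfile, "--out", mfile)))
  met <- data.table::fread(mfile)
  expect_equal(met$metric, c("rr_mean_ms", "rr_rmssd_ms", "rr_sampen"))
  expect_equal(met$value[1], rr_mean(diff(v)), tolerance = 1e-9)
  expect_error(avnode_main(c("unknown-cmd")), "unknown subcommand")
  expect_error(suppressMessages(avnode_main(
    c("generate-aa", "--mu", "150", "--sigma", "20", "--n", "10",
      "--out", out1))), "--seed")
})
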