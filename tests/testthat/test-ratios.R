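test_that("ion_count evaluates the signal-to-noise conversion", {
  # at the reference resolution with one microscan, count = (S/N) * 3
  expect_equal(ion_count(S = 100, N = 1, r = 240000, mu = 1), 300)
  # square-root scaling of the resolution ratio and microscans
  expect_equal(ion_count(S = 100, N = 1, r = 60000, mu = 2),
               100 * 3 * sqrt(4) * sqrt(2), tolerance = 1e-12)
  expect_equal(ion_count(S = 0, N = 5, r = 60000, mu = 2), 0)
  # linear reading reachable by config
  cfg_lin <- ion_count_config(res_exp = 1, micro_exp = 1)
  expect_equal(ion_count(100, 1, 60000, 2, cfg_lin), 100 * 3 * 4 * 2)
  expect_error(ion_count(1, 0, 60000, 2), "noise")
  expect_error(ion_count(1, 1, -1, 2), "resolution")
})

test_that("ion_count is linear in S and invariant under (S,N) scaling", {
  s <- c(10, 100, 1000); n <- c(2, 3, 4)
  base <- ion_count(s, n, 60000, 2)
  expect_equal(ion_count(5 * s, n, 60000, 2), 5 * base)
  expect_equal(ion_count(7.3 * s, 7.3 * n, 60000, 2), base)
})

test_that("scan ratios reduce to the signal-to-noise quotient", {
  run <- run_table(
    tibble::tibble(
      scan = 1:2, time_min = c(0, 1) / 60, tic = 1,
      S_M0 = c(100, 50), N_M0 = c(1, 1),
      S_13C1 = c(5, 5), N_13C1 = c(1, 2)
    ),
    resolution = 60000, microscans = 2L
  )
  s <- scan_ratios(run)
  expect_equal(s$ratio, c(5 / 100, 2.5 / 50))
  # constants cancel: ratio equals ion_count(num)/ion_count(den) for any cfg
  for (cfg in list(ion_count_config(),
                   ion_count_config(res_exp = 1, micro_exp = 0.25),
                   ion_count_config(noise_charges = 7))) {
    cn <- ion_count(run$S_13C1, run$N_13C1, 60000, 2, cfg)
    cd <- ion_count(run$S_M0, run$N_M0, 60000, 2, cfg)
    expect_equal(s$ratio, cn / cd, tolerance = 1e-12)
  }
  # identical S and N across species gives ratio 1
  runi <- run_table(
    tibble::tibble(scan = 1:2, time_min = c(0, 1) / 60, tic = 1,
                   S_M0 = 40, N_M0 = 2, S_13C1 = 40, N_13C1 = 2))
  expect_equal(scan_ratios(runi)$ratio, c(1, 1))
})

test_that("zero denominator scans are masked, not dropped", {
  run <- run_table(
    tibble::tibble(scan = 1:5, time_min = (0:4) / 60, tic = 1,
                   S_M0 = c(10, 0, 10, 10, 10), N_M0 = 1,
                   S_13C1 = 1, N_13C1 = 1))
  s <- scan_ratios(run)
  expect_equal(nrow(s), 5)
  expect_false(s$retained[2])
  expect_equal(s$reason[2], "zero_base_peak")
})

test_that("scan ratios are invariant under common per-scan rescaling", {
  run <- simulate_session(sim_config(seed = 31, flux = 2e4))
  fac <- withr::with_seed(32, runif(nrow(run), 0.5, 2))
  scaled <- tibble::as_tibble(run)
  scaled$S_M0 <- scaled$S_M0 * fac
  scaled$S_13C1 <- scaled$S_13C1 * fac
  run2 <- run_table(scaled, resolution = 60000, microscans = 2L)
  expect_equal(scan_ratios(run2)$ratio, scan_ratios(run)$ratio,
               tolerance = 1e-12)
})

test_that("outlier filtering removes constructed spikes and nothing else", {
  # constant series: nothing excluded
  runc <- run_table(
    tibble::tibble(scan = 1:20, time_min = (0:19) / 60, tic = 100,
                   S_M0 = 100, N_M0 = 1, S_13C1 = 5, N_13C1 = 1))
  sc <- filter_outlier_scans(scan_ratios(runc))
  expect_true(all(sc$retained))
  expect_equal(nrow(attr(sc, "outlier_report")), 0)

  # one 10x ratio spike in a 100-scan Poisson series
  withr::with_seed(43, {
    n <- 100
    c12 <- rpois(n, 2e4); c13 <- rpois(n, 4e3)
  })
  c13[57] <- c12[57] * 10 * median(c13 / c12)
  runp <- run_table(
    tibble::tibble(scan = 1:n, time_min = (0:(n - 1)) / 60,
                   tic = c12 + c13, S_M0 = c12, N_M0 = 1,
                   S_13C1 = c13, N_13C1 = 1))
  sp <- filter_outlier_scans(scan_ratios(runp), k_tic = Inf, k_ratio = 3)
  expect_false(sp$retained[57])
  expect_equal(sum(!sp$retained), 1)

  # k = Inf disables the filter entirely
  sinf <- filter_outlier_scans(scan_ratios(runp), k_tic = Inf, k_ratio = Inf)
  expect_true(all(sinf$retained))

  expect_error(filter_outlier_scans(scan_ratios(runc)[1:4, ]), "5 scans")
})

test_that("a six-sigma screen almost never rejects Gaussian scans", {
  hits <- vapply(1:50, function(i) {
    withr::with_seed(100 + i, {
      n <- 300
      r <- 0.2 * (1 + 0.01 * rnorm(n))
      tic <- 1000 * (1 + 0.01 * rnorm(n))
    })
    run <- run_table(
      tibble::tibble(scan = 1:n, time_min = (0:(n - 1)) / 60, tic = tic,
                     S_M0 = 100, N_M0 = 1, S_13C1 = 100 * r, N_13C1 = 1))
    s <- filter_outlier_scans(scan_ratios(run), k_tic = 6, k_ratio = 6)
    sum(!s$retained)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.99)
})

test_that("aggregation methods behave and coincide on proportional scans", {
  runc <- run_table(
    tibble::tibble(scan = 1:10, time_min = (0:9) / 60, tic = 1,
                   S_M0 = 100, N_M0 = 1, S_13C1 = 20, N_13C1 = 1))
  s <- scan_ratios(runc)
  a1 <- aggregate_ratio(s, "mean_of_ratios")
  a2 <- aggregate_ratio(s, "ratio_of_sums")
  expect_equal(a1$ratio, 0.2); expect_equal(a2$ratio, 0.2)
  expect_equal(a1$sd, 0)

  # proportional per-scan counts: the two estimators agree exactly
  runp <- run_table(
    tibble::tibble(scan = 1:2, time_min = c(0, 1) / 60, tic = 1,
                   S_M0 = c(100, 300), N_M0 = 1,
                   S_13C1 = c(10, 30), N_13C1 = 1))
  sp <- scan_ratios(runp)
  expect_equal(aggregate_ratio(sp, "mean_of_ratios")$ratio,
               aggregate_ratio(sp, "ratio_of_sums")$ratio)

  # non-proportional counts: mean of {0.1, 0.3} vs 40/400
  runn <- run_table(
    tibble::tibble(scan = 1:2, time_min = c(0, 1) / 60, tic = 1,
                   S_M0 = c(100, 100), N_M0 = 1,
                   S_13C1 = c(10, 30), N_13C1 = 1))
  sn <- scan_ratios(runn)
  expect_equal(aggregate_ratio(sn, "mean_of_ratios")$ratio, 0.2)
  expect_equal(aggregate_ratio(sn, "ratio_of_sums")$ratio, 0.2)
})

test_that("Poisson blocks recover the true ratio within shot-noise error", {
  true_r <- 0.2089
  withr::with_seed(77, {
    n <- 300
    c12 <- rpois(n, 2e4)
    c13 <- rpois(n, 2e4 * true_r)
  })
  # S/N chosen so the Eq-1 conversion returns the drawn counts exactly
  run <- run_table(
    tibble::tibble(scan = 1:n, time_min = (0:(n - 1)) / 60,
                   tic = c12 + c13, S_M0 = c12 / 3, N_M0 = 1,
                   S_13C1 = c13 / 3, N_13C1 = 1),
    resolution = 240000, microscans = 1L)
  s <- scan_ratios(run, cfg = ion_count_config())
  expect_equal(sum(s$count_den), sum(c12))
  for (m in c("mean_of_ratios", "ratio_of_sums")) {
    a <- aggregate_ratio(s, m)
    expect_lt(abs(a$ratio - true_r), 3 * true_r * a$shot_noise_rel)
  }
})

test_that("per-scan ratio scatter matches the shot-noise prediction", {
  withr::with_seed(88, {
    n <- 400
    lam12 <- 5e4; lam13 <- 5e3
    c12 <- rpois(n, lam12); c13 <- rpois(n, lam13)
  })
  r <- c13 / c12
  predicted_rel <- sqrt(1 / lam13 + 1 / lam12)
  expect_equal(sd(r) / mean(r), predicted_rel, tolerance = 0.2)
})
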