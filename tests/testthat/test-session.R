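test_that("the default dual-inlet layout alternates seven blocks", {
  lay <- session_layout()
  expect_equal(nrow(lay$blocks), 7)
  expect_equal(lay$blocks$role,
               rep(c("reference", "sample"), length.out = 7))
  expect_equal(lay$total_min, 35)
  expect_error(session_layout(n_blocks = 6))  # must end on a reference
})

test_that("scans are assigned to blocks with half-open intervals and trim", {
  run <- simulate_session(sim_config(seed = 51, flux = 2e4, poisson = FALSE))
  s <- segment_blocks(scan_ratios(run), session_layout(), trim_s = 30)
  tab <- dplyr::count(dplyr::filter(s, !is.na(block)), block, role)
  expect_equal(tab$block, 1:7)
  expect_equal(tab$role, rep(c("reference", "sample"), length.out = 7))
  # 5-min blocks at 1 scan/s with 30 s trimmed each side
  expect_true(all(tab$n == 240))

  # boundary scan joins the later block when trim is zero
  lay2 <- session_layout(n_blocks = 3, block_min = 1)
  scans <- tibble::tibble(scan = 1:13, time_min = seq(0, 3, 0.25),
                          tic = 1, S_M0 = 10, N_M0 = 1, S_13C1 = 1,
                          N_13C1 = 1)
  s2 <- segment_blocks(scan_ratios(run_table(scans)), lay2, trim_s = 0,
                       min_scans = 2)
  expect_equal(s2$block[s2$time_min == 1], 2L)
  expect_equal(s2$block[s2$time_min == 2], 3L)
  expect_true(is.na(s2$block[s2$time_min == 3]))  # past the layout end

  # a run shorter than the layout fails
  short <- run_table(dplyr::filter(tibble::as_tibble(run), time_min < 20),
                     resolution = 60000, microscans = 2L)
  expect_error(segment_blocks(scan_ratios(short), session_layout()),
               "shorter")
  expect_error(segment_blocks(scan_ratios(run), session_layout(),
                              trim_s = 200), "trim")
})

test_that("plateau detection finds the flat top of a trapezoid", {
  # 1-min ramps around a 10-min flat top, 15-min trace
  t <- seq(0, 15, 1 / 60)
  env <- pmin(1, pmin(t, 12 - t)); env[t > 12] <- 0; env[env < 0] <- 0
  x <- tibble::tibble(time_min = t, tic = 1000 * env)
  keep <- detect_plateau(x, threshold = 0.5, trim_s = 30)
  kept_t <- t[keep]
  expect_gte(min(kept_t), 1)      # inside the flat top
  expect_lte(max(kept_t), 11)
  expect_gte(max(kept_t) - min(kept_t), 9)

  # constant TIC: everything except the edge trims
  xc <- tibble::tibble(time_min = t, tic = 1000)
  keepc <- detect_plateau(xc, trim_s = 30)
  expect_equal(range(t[keepc]), c(0.5, 14.5))

  expect_error(detect_plateau(tibble::tibble(time_min = t, tic = 0)),
               "all-zero")
  expect_error(detect_plateau(x, threshold = 0.5, min_duration_min = 12),
               "shorter")
})

test_that("bracketing gives zero for identical blocks and exact per mil", {
  blocks <- tibble::tibble(
    block = 1:7, role = rep(c("reference", "sample"), length.out = 7),
    t_mid = seq(2.5, 32.5, 5), ratio = 0.21
  )
  d <- bracket_delta(blocks)
  expect_equal(d$delta_permil, rep(0, 3))
  expect_equal(sd(d$delta_permil), 0)

  b2 <- blocks
  b2$ratio[b2$role == "sample"] <- 0.21 * 1.001
  expect_equal(bracket_delta(b2)$delta_permil, rep(1, 3),
               tolerance = 1e-12)
  expect_equal(bracket_delta(b2, "interpolate")$delta_permil, rep(1, 3),
               tolerance = 1e-12)

  expect_error(bracket_delta(blocks[blocks$role == "sample", ]),
               "not bracketed")
})

test_that("source drift common to both species cancels in bracketing", {
  for (scheme in c("adjacent_mean", "interpolate")) {
    cfg <- sim_config(seed = 61, flux = 1e5, poisson = FALSE,
                      drift = "linear", drift_rate = 0.01,
                      delta_sample_vpdb = to_vpdb(-1.5, -27.8))
    res <- process_session(simulate_session(cfg), scheme = scheme)
    expect_lt(abs(res$delta_vs_std - (-1.5)), 0.05)
  }
})

test_that("bracketed delta is invariant under per-scan common rescaling", {
  cfg <- sim_config(seed = 62, flux = 5e4)
  run <- simulate_session(cfg)
  fac <- withr::with_seed(63, runif(nrow(run), 0.2, 5))
  scaled <- tibble::as_tibble(run)
  for (lab in run_species(run)) {
    scaled[[paste0("S_", lab)]] <- scaled[[paste0("S_", lab)]] * fac
  }
  run2 <- run_table(scaled, resolution = 60000, microscans = 2L,
                    mode = "dual_inlet")
  # mean_of_ratios weights every scan equally, so common per-scan intensity
  # factors drop out exactly; ratio_of_sums deliberately weights scans by
  # their ion counts and is only invariant under uniform rescaling
  r1 <- process_session(run, method = "mean_of_ratios")
  r2 <- process_session(run2, method = "mean_of_ratios")
  expect_equal(r2$delta_vs_std, r1$delta_vs_std, tolerance = 1e-9)
  u <- tibble::as_tibble(run)
  for (lab in run_species(run)) u[[paste0("S_", lab)]] <-
    u[[paste0("S_", lab)]] * 3.7
  r3 <- process_session(run_table(u, resolution = 60000, microscans = 2L))
  expect_equal(r3$delta_vs_std, process_session(run)$delta_vs_std,
               tolerance = 1e-9)
})

test_that("VPDB conversion matches its definition and inverts exactly", {
  expect_equal(to_vpdb(0, calibration(-27.8)), -27.8)
  expect_equal(to_vpdb(-1.0, -27.8), -28.7722, tolerance = 1e-12)
  # round trip
  d <- seq(-5, 5, 0.5)
  expect_equal(from_vpdb(to_vpdb(d, -27.8), -27.8), d, tolerance = 1e-9)
  # chain composition: A -> B -> C equals A -> C
  d_b_c <- -12.3        # delta of standard B on scale C
  d_a_b <- 4.56         # delta of A against B
  via_b <- to_vpdb(d_a_b, d_b_c)
  r_scale <- function(dd, ds) (1 + dd / 1000) * (1 + ds / 1000)
  direct <- (r_scale(d_a_b, d_b_c) - 1) * 1000
  expect_equal(via_b, direct, tolerance = 1e-9)
})

test_that("MAE reproduces the published dual-inlet sodiated value", {
  di_na <- dplyr::filter(orbitrap_standard_results(),
                         mode == "dual_inlet", adduct == "Na")
  rep_printed <- mae(di_na$residue_reported, rep(0, 9), labels = di_na$name)
  expect_equal(round(rep_printed$mae, 2), 0.72)
  expect_equal(mae(c(1, 1), c(1, 1))$mae, 0)
  expect_equal(mae(c(1, -1), c(0, 0))$mae, 1)
  expect_error(mae(1:3, 1:2), "equal length")
})

test_that("recomputed residues match reported ones except Standard 9", {
  di_na <- dplyr::filter(orbitrap_standard_results(),
                         mode == "dual_inlet", adduct == "Na")
  ev <- evaluate_standards(di_na)
  recomputed <- round(ev$table$residue, 1)
  expect_equal(recomputed[1:8], di_na$residue_reported[1:8],
               tolerance = 1e-9)
  # Standard 9 is internally inconsistent in the published table
  expect_gt(abs(recomputed[9] - di_na$residue_reported[9]), 0.4)
  expect_equal(round(ev$mae_reported, 2), 0.72)
})

test_that("replicate combination uses the Student-t interval", {
  nine <- rep(-30.9, 9)
  expect_equal(combine_replicates(nine)$ci_halfwidth, 0)
  cr <- combine_replicates(c(-1, 1))
  expect_equal(cr$mean, 0)
  # t(0.975, 1) * sd/sqrt(2) with sample sd sqrt(2)
  expect_equal(cr$ci_halfwidth, qt(0.975, 1) * sqrt(2) / sqrt(2),
               tolerance = 1e-6)
  expect_equal(round(cr$ci_halfwidth, 4), 12.7062)
  expect_error(combine_replicates(1), "two replicates")
})

test_that("t intervals cover the truth at the nominal rate", {
  hits <- withr::with_seed(91, {
    vapply(1:2000, function(i) {
      x <- rnorm(9, mean = -30, sd = 0.5)
      cr <- combine_replicates(x)
      abs(cr$mean - (-30)) <= cr$ci_halfwidth
    }, logical(1))
  })
  expect_equal(mean(hits), 0.95, tolerance = 0.02)
})

test_that("group comparison is a Welch test with degenerate convention", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  ident <- compare_groups(c(2, 2), c(2, 2))
  expect_equal(ident$p_value, 1)

  far <- compare_groups(c(0, 0, 0.001), c(10, 10, 10.001))
  expect_lt(far$p_value, 1e-6)

  # closed-form Welch computation as the independent check
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2)
  w <- compare_groups(a, b)
  se <- sqrt(var(a) / 10 + var(b) / 10)
  tstat <- (mean(a) - mean(b)) / se
  df <- se^4 / ((var(a) / 10)^2 / 9 + (var(b) / 10)^2 / 9)
  expect_equal(w$statistic, tstat, tolerance = 1e-10)
  expect_equal(w$df, df, tolerance = 1e-10)
  expect_equal(round(w$p_value, 4),
               round(2 * pt(-abs(tstat), df), 4))
})
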