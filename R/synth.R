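#' Configure a synthetic measurement session
#'
#' Full parameterisation of a simulated bracketing session with known
#' ground truth: the target ion, the true carbon isotope composition of
#' sample and reference (as delta-13C versus VPDB), the mean ion flux
#' reaching the detector per scan, acquisition settings, session layout,
#' source drift, co-isolated contamination and the noise model. All
#' randomness flows from `seed`.
#'
#' The defaults mirror the acquisition this workflow targets: resolution
#' 60,000, two microscans, 1-second scans, a seven-block dual-inlet
#' schedule, and a working standard at -27.8 per mil versus VPDB.
#'
#' @param formula,adduct,charge,species Target ion declaration (see
#'   [target_ion()]).
#' @param delta_sample_vpdb True sample delta-13C versus VPDB (per mil).
#' @param delta_reference_vpdb Working-standard delta-13C versus VPDB
#'   (default -27.8).
#' @param flux Mean total ion flux per scan for the target ion (ions;
#'   default 5e5, an AGC-target-scale population).
#' @param resolution,microscans,scan_period_s Acquisition settings.
#' @param layout A [session_layout()] (default seven 5-min dual-inlet
#'   blocks).
#' @param drift `"none"`, `"linear"` or `"exponential"` multiplicative
#'   source drift; `drift_rate` is the fractional change per hour.
#' @param contamination Expected contaminant fraction of the window
#'   intensity (default 0; realised only in simulated spectra).
#' @param adduct_split Intensity ratio of the sodiated to the protonated
#'   ion (default 10); used when simulating full spectra.
#' @param snr_base Nominal base-peak signal-to-noise used to set the
#'   noise scale (default 500), with log-normal jitter `snr_sigma`
#'   (default 0.1).
#' @param ramp_min Flow-injection ramp time in minutes (default 1).
#' @param poisson Draw Poisson ion counts (`TRUE`) or use exact expected
#'   counts (`FALSE`, for forward-inverse consistency checks).
#' @param seed Integer random seed; recorded in the output metadata.
#' @param isotopes Base isotope table to delta-shift.
#' @return A `sim_config` list.
#' @export
sim_config <- function(formula = "C19H38O2", adduct = "H", charge = 1L,
                       species = c("M0", "13C1", "13C2", "18O1"),
                       delta_sample_vpdb = -29.0,
                       delta_reference_vpdb = -27.8,
                       flux = 5e5, resolution = 60000, microscans = 2L,
                       scan_period_s = 1.0, layout = session_layout(),
                       drift = c("none", "linear", "exponential"),
                       drift_rate = 0, contamination = 0, adduct_split = 10,
                       snr_base = 500, snr_sigma = 0.1, ramp_min = 1,
                       poisson = TRUE, seed = 1L,
                       isotopes = iupac_isotopes()) {
  drift <- match.arg(drift)
  stopifnot(flux > 0, contamination >= 0, contamination < 1,
            adduct_split > 0, snr_base > 0, snr_sigma >= 0,
            scan_period_s > 0)
  structure(
    list(formula = formula, adduct = adduct, charge = as.integer(charge),
         species = species, delta_sample_vpdb = delta_sample_vpdb,
         delta_reference_vpdb = delta_reference_vpdb, flux = flux,
         resolution = resolution, microscans = as.integer(microscans),
         scan_period_s = scan_period_s, layout = layout, drift = drift,
         drift_rate = drift_rate, contamination = contamination,
         adduct_split = adduct_split, snr_base = snr_base,
         snr_sigma = snr_sigma, ramp_min = ramp_min, poisson = poisson,
         seed = as.integer(seed), isotopes = isotopes),
    class = "sim_config"
  )
}

# species abundance vectors for the two roles, delta-shifted in carbon only
sim_abundances <- function(cfg) {
  ab_for <- function(delta) {
    fs <- fine_structure(cfg$formula, cfg$adduct, cfg$charge, prune = 0,
                         isotopes = shift_carbon_delta(delta, cfg$isotopes))
    fs$abundance[match(cfg$species, fs$label)]
  }
  list(reference = ab_for(cfg$delta_reference_vpdb),
       sample = ab_for(cfg$delta_sample_vpdb))
}

sim_drift_factor <- function(cfg, t_min) {
  switch(cfg$drift,
    none = rep(1, length(t_min)),
    linear = 1 + cfg$drift_rate * t_min / 60,
    exponential = exp(cfg$drift_rate * t_min / 60)
  )
}

# trapezoidal flow-injection envelope inside each injection slot
sim_shape_factor <- function(cfg, t_min, role_block) {
  if (cfg$layout$mode != "hplc") return(rep(1, length(t_min)))
  slot <- cfg$layout$injection_min
  tt <- t_min %% slot
  ramp <- cfg$ramp_min
  flat_end <- ramp + cfg$layout$plateau_min
  env <- numeric(length(tt))
  env[tt < ramp] <- tt[tt < ramp] / ramp
  env[tt >= ramp & tt < flat_end] <- 1
  down <- tt >= flat_end & tt < flat_end + ramp
  env[down] <- 1 - (tt[down] - flat_end) / ramp
  env
}

#' Simulate a bracketing session
#'
#' Forward model of the measurement: per scan, the expected ion count of
#' each monitored species is `flux * abundance * drift(t) * envelope(t)`,
#' where the abundances come from the exact fine structure of the target
#' ion under the role's (sample or reference) carbon composition. Realised
#' counts are Poisson draws (or the exact expectations when
#' `poisson = FALSE`); counts are then converted to intensity/noise pairs
#' through the same signal-to-noise relation the analysis inverts, with a
#' per-scan log-normal noise level. Deterministic given `seed`.
#'
#' @param cfg A [sim_config()].
#' @return A `run_table` whose metadata records the configuration's truth
#'   (`delta_sample_vpdb`, `delta_reference_vpdb`, `seed`).
#' @examples
#' run <- simulate_session(sim_config(seed = 7, flux = 1e5))
#' @export
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ab <- sim_abundances(cfg)
  if (cfg$flux * min(ab$reference) < 1) {
    stop("flux too low: expected count below one ion per scan",
         call. = FALSE)
  }
  lay <- cfg$layout
  period_min <- cfg$scan_period_s / 60
  t <- seq(0, lay$total_min - period_min, by = period_min)
  block <- findInterval(t, lay$blocks$t_start)
  role <- lay$blocks$role[block]
  drift <- sim_drift_factor(cfg, t)
  envelope <- sim_shape_factor(cfg, t, block)
  nsp <- length(cfg$species)
  withr::with_seed(cfg$seed, {
    noise_scale <- cfg$flux * max(ab$reference) /
      ion_count_scale(cfg$resolution, cfg$microscans) / cfg$snr_base
    N <- noise_scale *
      exp(stats::rnorm(length(t), -cfg$snr_sigma^2 / 2, cfg$snr_sigma))
    out <- tibble::tibble(scan = seq_along(t), time_min = t)
    k <- ion_count_scale(cfg$resolution, cfg$microscans)
    S_all <- matrix(0, length(t), nsp)
    for (j in seq_len(nsp)) {
      a <- ifelse(role == "sample", ab$sample[j], ab$reference[j])
      lambda <- cfg$flux * a * drift * envelope
      counts <- if (cfg$poisson) stats::rpois(length(t), lambda) else lambda
      S_all[, j] <- counts / k * N
    }
    out$tic <- rowSums(S_all)
    for (j in seq_len(nsp)) {
      out[[paste0("S_", cfg$species[j])]] <- S_all[, j]
      out[[paste0("N_", cfg$species[j])]] <- N
    }
  })
  run_table(out, formula = cfg$formula, adduct = cfg$adduct,
            charge = cfg$charge, resolution = cfg$resolution,
            microscans = cfg$microscans, mode = lay$mode,
            extra = list(seed = cfg$seed,
                         delta_sample_vpdb = cfg$delta_sample_vpdb,
                         delta_reference_vpdb = cfg$delta_reference_vpdb))
}

#' Simulate centroid spectra for a session
#'
#' Generates the tidy centroid-peak stream corresponding to
#' [simulate_session()]: one peak per monitored species per scan at its
#' exact m/z, plus, when `cfg$contamination > 0`, one co-isolated
#' contaminant peak inside the monitored window (offset from every
#' monitored species by much more than the matching tolerance) carrying on
#' average the configured fraction of the window intensity.
#'
#' @param cfg A [sim_config()].
#' @return Tibble: `scan`, `time_min`, `mz`, `intensity`, `noise`.
#' @export
simulate_spectra <- function(cfg) {
  run <- simulate_session(cfg)
  tgt <- target_ion(cfg$formula, cfg$adduct, cfg$charge, cfg$species,
                    isotopes = cfg$isotopes)
  sp <- tgt$species
  long <- purrr::map_dfr(seq_len(nrow(sp)), function(j) {
    tibble::tibble(
      scan = run$scan, time_min = run$time_min, mz = sp$mz[j],
      intensity = run[[paste0("S_", sp$label[j])]],
      noise = run[[paste0("N_", sp$label[j])]]
    )
  })
  if (cfg$contamination > 0) {
    f <- cfg$contamination
    tot <- run$tic
    contam_mz <- min(sp$mz) + 0.5  # inside the window, off every species
    withr::with_seed(cfg$seed + 1L, {
      lam <- f / (1 - f) * tot
      inten <- if (cfg$poisson) {
        # contaminant intensity jitter at the same relative scale
        lam * exp(stats::rnorm(length(lam), 0, 0.02))
      } else lam
    })
    long <- dplyr::bind_rows(long, tibble::tibble(
      scan = run$scan, time_min = run$time_min, mz = contam_mz,
      intensity = inten,
      noise = run[[paste0("N_", sp$label[1])]]
    ))
  }
  dplyr::arrange(long, .data$scan, .data$mz)
}

#' Predicted shot-noise precision of a session
#'
#' Counting-statistics prediction of the standard error of the bracketed
#' delta estimate:
#' `SE = 1000 * sqrt(2) * sqrt(1/C_minor + 1/C_major) / sqrt(n_sample)`
#' where `C` are the total retained ions per block for the minor and major
#' isotopologue and the `sqrt(2)` accounts for reference-and-sample noise.
#'
#' @param cfg A [sim_config()].
#' @param numerator,denominator The ratio species (defaults `"13C1"`,
#'   `"M0"`).
#' @param trim_s Edge trim assumed per block side (default 30 s).
#' @return Predicted delta standard error in per mil.
#' @export
predict_precision <- function(cfg, numerator = "13C1", denominator = "M0",
                              trim_s = 30) {
  ab <- sim_abundances(cfg)$reference
  names(ab) <- cfg$species
  lay <- cfg$layout
  slot_min <- if (lay$mode == "dual_inlet") lay$block_min else
    lay$plateau_min
  scans_per_block <- max((slot_min * 60 - 2 * trim_s) / cfg$scan_period_s, 1)
  c_minor <- cfg$flux * ab[[numerator]] * scans_per_block
  c_major <- cfg$flux * ab[[denominator]] * scans_per_block
  n_sample <- sum(lay$blocks$role == "sample")
  1000 * sqrt(2) * sqrt(1 / c_minor + 1 / c_major) / sqrt(n_sample)
}

#' Process a run into a calibrated delta result
#'
#' End-to-end analysis of one session: per-scan ratios, block segmentation
#' (dual-inlet) or plateau detection within injection slots (flow
#' injection), robust outlier rejection, per-block aggregation,
#' sample-standard bracketing and VPDB anchoring.
#'
#' @param run A `run_table`.
#' @param layout A [session_layout()]; defaults to the standard layout for
#'   the run's mode.
#' @param cal A [calibration()] for the working standard.
#' @param numerator,denominator Ratio species (defaults `"13C1"`, `"M0"`).
#' @param method Block aggregation method (see [aggregate_ratio()]).
#' @param scheme Bracketing scheme (see [bracket_delta()]).
#' @param trim_s Block edge trim in seconds (default 30).
#' @param k_tic,k_ratio Outlier thresholds (see [filter_outlier_scans()]).
#' @param min_scans Minimum retained scans per block.
#' @return A `delta_result` object; see [tidy.delta_result()] and
#'   [glance.delta_result()].
#' @export
process_session <- function(run, layout = NULL, cal = calibration(),
                            numerator = "13C1", denominator = "M0",
                            method = "ratio_of_sums",
                            scheme = "adjacent_mean", trim_s = 30,
                            k_tic = 5, k_ratio = 3, min_scans = 10) {
  m <- run_meta(run)
  if (is.null(layout)) layout <- session_layout(mode = m$mode)
  series <- scan_ratios(run, numerator, denominator)
  if (layout$mode == "hplc") {
    # plateau detection per injection slot
    slot <- floor(series$time_min / layout$injection_min)
    plateau <- logical(nrow(series))
    for (s in unique(slot)) {
      idx <- which(slot == s)
      plateau[idx] <- detect_plateau(series[idx, ], trim_s = trim_s)
    }
    cut <- !plateau & series$retained
    series$retained[cut] <- FALSE
    series$reason[cut] <- "off_plateau"
  }
  series <- segment_blocks(series, layout, trim_s = trim_s,
                           min_scans = min_scans)
  series <- filter_outlier_scans(series, k_tic = k_tic, k_ratio = k_ratio)
  blocks <- block_summaries(series, method = method)
  per_sample <- bracket_delta(blocks, scheme = scheme)
  d_std <- mean(per_sample$delta_permil)
  sd_blocks <- if (nrow(per_sample) > 1) stats::sd(per_sample$delta_permil)
    else 0
  n <- nrow(per_sample)
  structure(
    list(
      delta_vs_std = d_std,
      delta_vpdb = to_vpdb(d_std, cal),
      sd = sd_blocks, se = sd_blocks / sqrt(n), n = n,
      per_block = per_sample, blocks = blocks, series = series,
      calibration = cal, method = method, scheme = scheme,
      flags = list(
        outliers = attr(series, "outlier_report"),
        low_scan_blocks = blocks$block[blocks$n < min_scans]
      )
    ),
    class = "delta_result"
  )
}

#' @export
print.delta_result <- function(x, ...) {
  cat("<delta_result>\n",
      sprintf("  delta-13C vs working standard: %8.4f permil (SD %.4f, n = %d)\n",
              x$delta_vs_std, x$sd, x$n),
      sprintf("  delta-13C vs VPDB:             %8.4f permil\n", x$delta_vpdb),
      sep = "")
  invisible(x)
}
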