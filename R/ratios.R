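#' Ion-count estimation settings
#'
#' Parameters of the signal-to-noise ion-count conversion: the
#' noise-equivalent charge constant (3 charges, experimentally determined
#' at the reference resolution), the reference resolution at which that
#' constant was determined (240,000), and the exponents applied to the
#' resolution ratio and the microscan count. The default 0.5 exponents
#' follow the square-root scaling of the protocol this conversion comes
#' from; setting both to 1 gives the linear reading.
#'
#' @param noise_charges Charges equivalent to the noise band (default 3).
#' @param ref_resolution Reference resolution Rn (default 240000).
#' @param res_exp,micro_exp Exponents for `(Rn/r)` and microscans
#'   (defaults 0.5, in `[0, 1]`).
#' @return An `ion_count_config` list.
#' @export
ion_count_config <- function(noise_charges = 3, ref_resolution = 240000,
                             res_exp = 0.5, micro_exp = 0.5) {
  stopifnot(noise_charges > 0, ref_resolution > 0,
            res_exp >= 0, res_exp <= 1, micro_exp >= 0, micro_exp <= 1)
  structure(list(noise_charges = noise_charges,
                 ref_resolution = ref_resolution,
                 res_exp = res_exp, micro_exp = micro_exp),
            class = "ion_count_config")
}

#' Estimate ion counts from signal-to-noise
#'
#' Converts an Orbitrap peak's intensity/noise reading into an estimated
#' number of detected ions:
#' `count = (S/N) * c * (Rn/r)^a * mu^b`
#' with noise-equivalent charge constant `c`, reference resolution `Rn`,
#' resolution exponent `a` and microscan exponent `b` taken from `cfg`.
#' Vectorised over all arguments.
#'
#' @param S Peak intensity (arbitrary units, >= 0).
#' @param N Peak noise (same units, > 0).
#' @param r Mass resolution setting (> 0).
#' @param mu Microscans per scan (>= 1).
#' @param cfg An [ion_count_config()].
#' @return Estimated ion count (dimensionless).
#' @examples
#' ion_count(S = 300, N = 3, r = 240000, mu = 1)  # 300 ions
#' @export
ion_count <- function(S, N, r, mu, cfg = ion_count_config()) {
  if (any(N <= 0)) stop("noise must be positive", call. = FALSE)
  if (any(r <= 0)) stop("resolution must be positive", call. = FALSE)
  if (any(mu < 1)) stop("microscans must be >= 1", call. = FALSE)
  (S / N) * cfg$noise_charges * (cfg$ref_resolution / r)^cfg$res_exp *
    mu^cfg$micro_exp
}

# scale factor count/(S/N) for a run's settings
ion_count_scale <- function(r, mu, cfg = ion_count_config()) {
  cfg$noise_charges * (cfg$ref_resolution / r)^cfg$res_exp *
    mu^cfg$micro_exp
}

#' Per-scan isotopologue ratios
#'
#' Forms the per-scan ratio of ion counts between two monitored species.
#' Because the count conversion applies the same constants to both species
#' of a scan, the ratio reduces exactly to `(S_num/N_num) / (S_den/N_den)`.
#' Scans with zero denominator signal are retained in the table but masked
#' with reason `"zero_base_peak"`.
#'
#' @param run A `run_table`.
#' @param numerator,denominator Monitored species labels (defaults `"13C1"`
#'   over `"M0"`).
#' @param cfg An [ion_count_config()] (used for the reported counts).
#' @return A `ratio_series` tibble: `scan`, `time_min`, `tic`, `count_num`,
#'   `count_den`, `ratio`, `retained` (logical), `reason` (character, `NA`
#'   when retained), with the run metadata and species pair in attributes.
#' @export
scan_ratios <- function(run, numerator = "13C1", denominator = "M0",
                        cfg = ion_count_config()) {
  labs <- run_species(run)
  if (!all(c(numerator, denominator) %in% labs)) {
    stop("species not present in run: ",
         paste(setdiff(c(numerator, denominator), labs), collapse = ", "),
         call. = FALSE)
  }
  m <- run_meta(run)
  k <- ion_count_scale(m$resolution, m$microscans, cfg)
  sn_num <- run[[paste0("S_", numerator)]] / run[[paste0("N_", numerator)]]
  sn_den <- run[[paste0("S_", denominator)]] / run[[paste0("N_", denominator)]]
  out <- tibble::tibble(
    scan = run$scan, time_min = run$time_min, tic = run$tic,
    count_num = sn_num * k, count_den = sn_den * k,
    ratio = ifelse(sn_den > 0, sn_num / sn_den, NA_real_),
    retained = sn_den > 0,
    reason = ifelse(sn_den > 0, NA_character_, "zero_base_peak")
  )
  structure(out, meta = m, numerator = numerator, denominator = denominator,
            class = c("ratio_series", class(out)))
}

#' Robust outlier-scan rejection
#'
#' Masks scans whose total ion current or per-scan ratio deviates from the
#' (block) median by more than `k` robust standard deviations, where the
#' robust SD is the median absolute deviation scaled to the Gaussian
#' (`mad()`). A single pass is applied; scans already masked (for example
#' zero denominator) stay masked. Use `k = Inf` to disable either screen.
#'
#' When the series carries a `block` column (see [segment_blocks()]) the
#' medians are computed per block, so a composition step between blocks is
#' not mistaken for an outlier.
#'
#' @param series A `ratio_series` from [scan_ratios()].
#' @param k_tic,k_ratio Rejection thresholds in robust SDs
#'   (defaults 5 and 3).
#' @return The series with `retained`/`reason` updated; the exclusion
#'   report (tibble: scan, reason) is in attribute `outlier_report`.
#' @export
filter_outlier_scans <- function(series, k_tic = 5, k_ratio = 3) {
  if (nrow(series) < 5) stop("need at least 5 scans", call. = FALSE)
  grp <- if ("block" %in% names(series)) series$block else rep(1L, nrow(series))
  newly <- character(nrow(series))
  for (g in unique(grp[!is.na(grp)])) {
    idx <- which(grp == g & series$retained)
    if (length(idx) < 3) next
    flag_dev <- function(x, k) {
      med <- stats::median(x)
      s <- stats::mad(x)
      if (!is.finite(k) || s == 0) return(rep(FALSE, length(x)))
      abs(x - med) > k * s
    }
    bad_tic <- flag_dev(series$tic[idx], k_tic)
    bad_ratio <- flag_dev(series$ratio[idx], k_ratio)
    newly[idx[bad_tic]] <- "tic_outlier"
    newly[idx[bad_ratio & !bad_tic]] <- "ratio_outlier"
  }
  hit <- newly != ""
  series$retained[hit] <- FALSE
  series$reason[hit] <- newly[hit]
  if (!any(series$retained)) stop("all scans excluded", call. = FALSE)
  attr(series, "outlier_report") <-
    tibble::tibble(scan = series$scan[hit], reason = newly[hit])
  series
}

#' Aggregate a ratio series into a block estimate
#'
#' Two estimators are provided. `"ratio_of_sums"` (default) divides the
#' summed numerator ion counts by the summed denominator counts over
#' retained scans, which has lower small-count bias; `"mean_of_ratios"`
#' averages the per-scan ratios. SD and SE are computed from the retained
#' per-scan ratios in both cases, and the counting-statistics (shot-noise)
#' relative error `sqrt(1/sum_num + 1/sum_den)` is reported alongside.
#'
#' @param series A `ratio_series`, optionally filtered.
#' @param method `"ratio_of_sums"` or `"mean_of_ratios"`.
#' @return One-row tibble: `ratio`, `sd`, `se`, `n`, `n_outliers`,
#'   `shot_noise_rel`, `method`.
#' @export
aggregate_ratio <- function(series,
                            method = c("ratio_of_sums", "mean_of_ratios")) {
  method <- match.arg(method)
  keep <- series$retained
  if (!any(keep)) stop("no retained scans", call. = FALSE)
  r <- series$ratio[keep]
  cn <- sum(series$count_num[keep])
  cd <- sum(series$count_den[keep])
  est <- switch(method,
    ratio_of_sums = cn / cd,
    mean_of_ratios = mean(r)
  )
  n <- sum(keep)
  sdv <- if (n > 1) stats::sd(r) else 0
  tibble::tibble(
    ratio = est, sd = sdv, se = sdv / sqrt(n), n = n,
    n_outliers = sum(!keep),
    shot_noise_rel = if (cn > 0 && cd > 0) sqrt(1 / cn + 1 / cd) else NA_real_,
    method = method
  )
}
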