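#' Describe a measurement session layout
#'
#' A session alternates reference and sample introductions. In dual-inlet
#' mode a valve switches between two syringes on a fixed period (default
#' seven 5-minute blocks, roles R,S,R,S,R,S,R over 35 min). In flow-injection
#' (`"hplc"`) mode each role occupies one injection slot (default 15 min)
#' whose usable signal is a broad plateau (nominally 10 min) found by
#' [detect_plateau()].
#'
#' @param mode `"dual_inlet"` or `"hplc"`.
#' @param n_blocks Number of alternating role blocks (odd; default 7).
#' @param block_min Dual-inlet block duration in minutes (default 5).
#' @param injection_min Injection slot length in minutes (default 15).
#' @param plateau_min Nominal plateau duration in minutes (default 10).
#' @return A `session_layout` list with a `blocks` tibble (block, role,
#'   t_start, t_end in minutes).
#' @export
session_layout <- function(mode = c("dual_inlet", "hplc"), n_blocks = 7,
                           block_min = 5, injection_min = 15,
                           plateau_min = 10) {
  mode <- match.arg(mode)
  stopifnot(n_blocks >= 3, n_blocks %% 2 == 1, block_min > 0)
  slot <- if (mode == "dual_inlet") block_min else injection_min
  roles <- rep(c("reference", "sample"), length.out = n_blocks)
  blocks <- tibble::tibble(
    block = seq_len(n_blocks), role = roles,
    t_start = (seq_len(n_blocks) - 1) * slot,
    t_end = seq_len(n_blocks) * slot
  )
  structure(list(mode = mode, n_blocks = n_blocks, block_min = block_min,
                 injection_min = injection_min, plateau_min = plateau_min,
                 blocks = blocks, total_min = n_blocks * slot),
            class = "session_layout")
}

#' Assign scans to session blocks
#'
#' Labels each scan of a ratio series (or any tibble with a `time_min`
#' column) with its block number and role. Time intervals are half-open
#' `[start, end)`: a scan exactly on a boundary belongs to the later block.
#' The first and last `trim_s` seconds of every block are dropped
#' (valve-switch / injection transients): trimmed scans get `block = NA`
#' and, for ratio series, are masked with reason `"edge_trim"`.
#'
#' @param series A `ratio_series` or tibble with `time_min`.
#' @param layout A [session_layout()].
#' @param trim_s Edge trim in seconds per block side (default 30; must be
#'   less than half the block duration).
#' @param min_scans Minimum retained scans per block (default 10).
#' @return `series` with `block` and `role` columns added.
#' @export
segment_blocks <- function(series, layout, trim_s = 30, min_scans = 10) {
  stopifnot(inherits(layout, "session_layout"))
  slot <- if (layout$mode == "dual_inlet") layout$block_min else
    layout$injection_min
  if (trim_s >= slot * 60 / 2) {
    stop("trim must be below half the block duration", call. = FALSE)
  }
  t <- series$time_min
  if (max(t) < layout$blocks$t_end[nrow(layout$blocks)] - slot) {
    stop("run shorter than the session layout", call. = FALSE)
  }
  b <- findInterval(t, layout$blocks$t_start)  # half-open [start, end)
  b[t >= layout$total_min] <- NA_integer_
  b[b < 1] <- NA_integer_
  trim_min <- trim_s / 60
  inside <- !is.na(b) &
    t >= layout$blocks$t_start[pmax(b, 1)] + trim_min &
    t < layout$blocks$t_end[pmax(b, 1)] - trim_min
  b[!inside] <- NA_integer_
  series$block <- b
  series$role <- layout$blocks$role[b]
  if ("retained" %in% names(series)) {
    cut <- is.na(b) & series$retained
    series$retained[cut] <- FALSE
    series$reason[cut] <- "edge_trim"
  }
  counts <- table(b[if ("retained" %in% names(series))
    series$retained else !is.na(b)])
  have <- as.integer(names(counts))
  short <- layout$blocks$block[!(layout$blocks$block %in% have) |
    layout$blocks$block %in% have[counts < min_scans]]
  if (length(short) > 0) {
    stop("block(s) with fewer than ", min_scans, " retained scans: ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  series
}

#' Locate the flow-injection plateau
#'
#' Finds the usable plateau of a flow-injection profile: the longest
#' contiguous scan window whose TIC is at least `threshold` times the
#' median TIC of the top-half scans, rejected if shorter than
#' `min_duration_min`, then edge-trimmed by `trim_s` per side.
#'
#' @param x Tibble with `time_min` and `tic` columns (a `run_table` or
#'   `ratio_series`).
#' @param threshold Fraction of the plateau-level TIC (default 0.5).
#' @param min_duration_min Minimum acceptable plateau length (default 2).
#' @param trim_s Edge trim in seconds per side (default 30).
#' @return Logical vector marking scans inside the retained window.
#' @export
detect_plateau <- function(x, threshold = 0.5, min_duration_min = 2,
                           trim_s = 30) {
  stopifnot(threshold > 0, threshold < 1)
  tic <- x$tic
  if (all(tic <= 0)) stop("no signal: all-zero TIC", call. = FALSE)
  top <- tic[tic >= stats::median(tic)]
  level <- stats::median(top)
  above <- tic >= threshold * level
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values)
  if (length(cand) == 0) stop("no plateau found", call. = FALSE)
  span <- x$time_min[ends[cand]] - x$time_min[starts[cand]]
  bi <- which.max(span)
  best <- cand[bi]
  if (span[bi] < min_duration_min) {
    stop("plateau shorter than ", min_duration_min, " min", call. = FALSE)
  }
  t0 <- x$time_min[starts[best]] + trim_s / 60
  t1 <- x$time_min[ends[best]] - trim_s / 60
  x$time_min >= t0 & x$time_min <= t1
}

#' Per-block ratio summaries
#'
#' Aggregates a segmented ratio series block by block (see
#' [aggregate_ratio()]).
#'
#' @param series A segmented `ratio_series` (with `block`/`role`).
#' @param method Aggregation method, passed to [aggregate_ratio()].
#' @return Tibble: one row per block with role, time span and the
#'   aggregate columns.
#' @export
block_summaries <- function(series, method = "ratio_of_sums") {
  stopifnot(all(c("block", "role") %in% names(series)))
  series |>
    dplyr::filter(!is.na(.data$block)) |>
    dplyr::group_by(.data$block, .data$role) |>
    dplyr::group_modify(function(d, key) {
      cbind(
        tibble::tibble(t_start = min(d$time_min), t_end = max(d$time_min),
                       t_mid = (min(d$time_min) + max(d$time_min)) / 2),
        aggregate_ratio(d, method = method)
      )
    }) |>
    dplyr::ungroup()
}

#' Sample-standard bracketing
#'
#' Computes each sample block's delta versus the working standard by
#' comparing its isotopologue ratio with the two neighbouring reference
#' blocks: `delta_i = (R_sample_i / R_ref_i - 1) * 1000` (per mil), where
#' `R_ref_i` is either the plain mean of the flanking reference ratios
#' (`"adjacent_mean"`) or their linear interpolation in time at the sample
#' block's midpoint (`"interpolate"`, for monotone drift). Because both
#' schemes reference each sample block to its immediate neighbours, source
#' drift common to both isotopologues cancels.
#'
#' @param blocks A block summary tibble from [block_summaries()]. Every
#'   sample block must have a reference block before and after it.
#' @param scheme `"adjacent_mean"` or `"interpolate"`.
#' @return Tibble: one row per sample block with `block`, `ratio`,
#'   `ratio_ref`, `delta_permil`.
#' @export
bracket_delta <- function(blocks, scheme = c("adjacent_mean", "interpolate")) {
  scheme <- match.arg(scheme)
  refs <- blocks[blocks$role == "reference", ]
  samples <- blocks[blocks$role == "sample", ]
  if (nrow(samples) == 0) stop("no sample blocks", call. = FALSE)
  out <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    b <- samples$block[i]
    before <- refs[refs$block < b, ]
    after <- refs[refs$block > b, ]
    if (nrow(before) == 0 || nrow(after) == 0) {
      stop("sample block ", b, " is not bracketed by reference blocks",
           call. = FALSE)
    }
    rb <- before[which.max(before$block), ]
    ra <- after[which.min(after$block), ]
    r_ref <- switch(scheme,
      adjacent_mean = (rb$ratio + ra$ratio) / 2,
      interpolate = stats::approx(
        x = c(rb$t_mid, ra$t_mid), y = c(rb$ratio, ra$ratio),
        xout = samples$t_mid[i])$y
    )
    tibble::tibble(block = b, ratio = samples$ratio[i], ratio_ref = r_ref,
                   delta_permil = (samples$ratio[i] / r_ref - 1) * 1000)
  })
  out
}

#' Working-standard calibration
#'
#' The delta-13C of the working standard on the VPDB scale, with its
#' stated uncertainty, used to anchor bracketed results.
#'
#' @param delta_vpdb Working-standard delta-13C versus VPDB (per mil).
#' @param sd Its standard deviation (per mil, >= 0).
#' @return A `calibration` list.
#' @export
calibration <- function(delta_vpdb = -27.8, sd = 0.4) {
  stopifnot(is.finite(delta_vpdb), is.finite(sd), sd >= 0)
  structure(list(delta_vpdb = delta_vpdb, sd = sd), class = "calibration")
}

#' Convert a delta value between reference scales
#'
#' `to_vpdb()` re-expresses a delta measured against the working standard
#' on the VPDB scale via the exact multiplicative composition
#' `delta_vpdb = d + s + d*s/1000`, where `s` is the standard's delta
#' versus VPDB. `from_vpdb()` is its algebraic inverse. Vectorised.
#'
#' @param delta_vs_std Delta versus the working standard (per mil).
#' @param cal A [calibration()] or a numeric delta of the standard vs VPDB.
#' @return Delta on the VPDB scale (per mil).
#' @examples
#' to_vpdb(0, calibration(-27.8))   # -27.8
#' @export
to_vpdb <- function(delta_vs_std, cal = calibration()) {
  s <- if (inherits(cal, "calibration")) cal$delta_vpdb else cal
  stopifnot(all(is.finite(delta_vs_std)), is.finite(s))
  delta_vs_std + s + delta_vs_std * s / 1000
}

#' @rdname to_vpdb
#' @param delta_vpdb Delta on the VPDB scale (per mil).
#' @export
from_vpdb <- function(delta_vpdb, cal = calibration()) {
  s <- if (inherits(cal, "calibration")) cal$delta_vpdb else cal
  stopifnot(all(is.finite(delta_vpdb)), is.finite(s))
  (delta_vpdb - s) / (1 + s / 1000)
}

#' Mean absolute error against expected delta values
#'
#' Evaluates a set of measured delta values against their expected
#' (reference-method) values: per-standard residues `measured - expected`
#' and their mean absolute value.
#'
#' @param measured,expected Equal-length numeric vectors (per mil).
#' @param labels Optional standard names.
#' @return An `evaluation_report`: list with `per_standard` tibble
#'   (label, measured, expected, residue) and `mae`.
#' @examples
#' mae(c(-29.6, -29.8), c(-29.5, -29.8))
#' @export
mae <- function(measured, expected, labels = NULL) {
  if (length(measured) != length(expected)) {
    stop("measured and expected must have equal length", call. = FALSE)
  }
  if (length(measured) < 1) stop("need at least one value", call. = FALSE)
  if (is.null(labels)) labels <- as.character(seq_along(measured))
  per <- tibble::tibble(label = labels, measured = measured,
                        expected = expected,
                        residue = measured - expected)
  structure(list(per_standard = per, mae = mean(abs(per$residue)),
                 n = nrow(per)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> n =", x$n,
      " MAE =", sprintf("%.4f", x$mae), "permil\n")
  print(x$per_standard)
  invisible(x)
}

#' Combine replicate delta values
#'
#' Mean, SD and a Student-t confidence half-width
#' `t(1 - alpha/2, n - 1) * SD / sqrt(n)` over replicate delta values
#' (for example nine values from three bracketed runs of three sample
#' blocks each).
#'
#' @param deltas Numeric vector of replicate deltas (per mil), `n >= 2`.
#' @param conf Confidence level (default 0.95).
#' @return One-row tibble: `mean`, `sd`, `n`, `ci_halfwidth`, `conf`.
#' @export
combine_replicates <- function(deltas, conf = 0.95) {
  n <- length(deltas)
  if (n < 2) stop("need at least two replicates", call. = FALSE)
  s <- stats::sd(deltas)
  tibble::tibble(
    mean = mean(deltas), sd = s, n = n,
    ci_halfwidth = stats::qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n),
    conf = conf
  )
}

#' Compare two groups of replicate deltas
#'
#' Two-sided unequal-variance (Welch) two-sample comparison of replicate
#' delta values, e.g. between two sample sources. Degenerate zero-variance
#' groups with equal means return p = 1 by convention.
#'
#' @param a,b Numeric vectors (per mil), each of length >= 2.
#' @return One-row tibble: `statistic`, `df`, `p_value`, group means.
#' @export
compare_groups <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble::tibble(statistic = 0, df = length(a) + length(b) - 2,
                            p_value = 1, mean_a = mean(a), mean_b = mean(b)))
    }
    stop("both groups have zero variance with different means",
         call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}
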