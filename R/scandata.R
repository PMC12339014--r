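#' Construct a per-scan signal table
#'
#' A `run_table` is a tibble with one row per Orbitrap scan and paired
#' `S_<label>` / `N_<label>` columns holding each monitored species'
#' intensity and noise reading, plus `scan`, `time_min` and `tic`. Run-level
#' acquisition metadata (formula, adduct, charge, resolution, microscans,
#' mode) is carried in the `meta` attribute, mirroring the header block of
#' the on-disk format.
#'
#' @param scans Tibble (or data frame) with columns `scan`, `time_min`,
#'   `tic` and `S_*`/`N_*` pairs.
#' @param formula,adduct,charge,resolution,microscans,mode Run metadata.
#'   `resolution` and `microscans` are shared by all scans of a run.
#' @param extra Optional named list of further metadata (source description,
#'   seed, flags).
#' @return A `run_table` object.
#' @export
run_table <- function(scans, formula = NA_character_, adduct = "H",
                      charge = 1L, resolution = 60000, microscans = 2L,
                      mode = c("dual_inlet", "hplc"), extra = list()) {
  mode <- match.arg(mode)
  x <- tibble::as_tibble(scans)
  meta <- c(list(formula = formula, adduct = adduct,
                 charge = as.integer(charge), resolution = resolution,
                 microscans = as.integer(microscans), mode = mode), extra)
  new_run_table(x, meta)
}

new_run_table <- function(x, meta) {
  x <- validate_run_scans(x, meta)
  structure(x, meta = meta,
            class = c("run_table", class(tibble::tibble())))
}

#' @export
print.run_table <- function(x, ...) {
  m <- attr(x, "meta")
  cat("<run_table> ", nrow(x), " scans | ", m$formula, " +", m$adduct,
      " | r = ", format(m$resolution, big.mark = ","),
      ", microscans = ", m$microscans, " | mode = ", m$mode, "\n", sep = "")
  NextMethod()
}

run_meta <- function(run) attr(run, "meta")

#' Monitored species labels of a run table
#' @param run A `run_table`.
#' @return Character vector of labels, in column order.
#' @export
run_species <- function(run) {
  sub("^S_", "", grep("^S_", names(run), value = TRUE))
}

validate_run_scans <- function(x, meta) {
  need <- c("scan", "time_min", "tic")
  if (!all(need %in% names(x))) {
    stop("scan table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  s_cols <- grep("^S_", names(x), value = TRUE)
  n_cols <- grep("^N_", names(x), value = TRUE)
  labels <- sub("^S_", "", s_cols)
  if (length(labels) == 0 ||
      !setequal(sub("^N_", "", n_cols), labels)) {
    stop("each species needs paired S_<label>/N_<label> columns",
         call. = FALSE)
  }
  for (lab in labels) {
    s <- x[[paste0("S_", lab)]]
    n <- x[[paste0("N_", lab)]]
    if (any(s < 0, na.rm = TRUE)) {
      stop("negative intensity for species ", lab, " at scan ",
           x$scan[which(s < 0)[1]], call. = FALSE)
    }
    if (any(n <= 0, na.rm = TRUE)) {
      stop("non-positive noise for species ", lab, " at scan ",
           x$scan[which(n <= 0)[1]], call. = FALSE)
    }
  }
  if (!is.null(meta$resolution) && meta$resolution <= 0) {
    stop("resolution must be positive", call. = FALSE)
  }
  if (!is.null(meta$microscans) && meta$microscans < 1) {
    stop("microscans must be >= 1", call. = FALSE)
  }
  if (is.unsorted(x$scan)) x <- dplyr::arrange(x, .data$scan)
  if (is.unsorted(x$time_min)) {
    warning("scan times not monotone in scan index; kept sorted by scan",
            call. = FALSE)
  }
  x
}

# header keys written/read as "# key: value" lines
.meta_keys <- c("formula", "adduct", "charge", "resolution", "microscans",
                "mode")

#' Write a scan table to disk
#'
#' Tab-delimited UTF-8: `#`-prefixed metadata lines, then a header row
#' `scan  time_min  tic  S_<label>  N_<label> ...` and one row per scan.
#' Round-trips losslessly through [read_scan_table()].
#'
#' @param run A `run_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(run, path) {
  m <- run_meta(run)
  hdr <- purrr::imap_chr(m[.meta_keys],
                         function(v, k) sprintf("# %s: %s", k, v))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  tab <- tibble::as_tibble(run)
  writeLines(paste(names(tab), collapse = "\t"), con)
  # %.17g keeps doubles bit-exact across the round trip
  cols <- lapply(tab, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  })
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Read a scan table
#'
#' Parses the delimited scan-table format written by [write_scan_table()]:
#' `#` metadata lines, a header naming `S_`/`N_` species columns, one row
#' per scan. Enforces run invariants: non-negative S, strictly positive N
#' (reported with the offending scan index), monotone time (warning + sort
#' by scan index otherwise).
#'
#' @param path Input path.
#' @return A `run_table`.
#' @export
read_scan_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta_lines,
                   regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", meta_lines))
  meta <- stats::setNames(
    lapply(kv, function(x) x[3]),
    vapply(kv, function(x) x[2], character(1))
  )
  for (k in c("charge", "microscans")) {
    if (!is.null(meta[[k]])) meta[[k]] <- as.integer(meta[[k]])
  }
  if (!is.null(meta$resolution)) meta$resolution <- as.numeric(meta$resolution)
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2) stop("malformed scan table: no data rows",
                             call. = FALSE)
  # base parser: strtod is correctly rounded, keeping the round trip exact
  tab <- utils::read.delim(text = body, check.names = FALSE)
  tab$scan <- as.integer(tab$scan)
  new_run_table(tibble::as_tibble(tab), meta)
}

#' Extract per-species signals from centroid spectra
#'
#' Assigns centroided peaks to the monitored species of a target ion by m/z
#' window matching. For each scan and species the most intense peak within
#' `ppm` of the species m/z provides (S, N); a missing peak yields S = 0
#' with N set to the median noise of the scan's window and a flag; multiple
#' candidate peaks set a multiplicity flag. Species windows must be
#' disjoint at the configured tolerance.
#'
#' @param peaks Tidy centroid-peak tibble with columns `scan`, `time_min`,
#'   `mz`, `intensity`, `noise` (one row per peak). This is the column
#'   layout an mzML centroid read yields.
#' @param target A [target_ion()].
#' @param ppm Matching tolerance; defaults to the target's.
#' @param resolution,microscans,mode Run metadata for the result.
#' @return A `run_table`; per-scan flags are recorded in the `flags`
#'   element of its metadata (tibble: scan, species, flag).
#' @export
extract_signals <- function(peaks, target, ppm = target$ppm,
                            resolution = 60000, microscans = 2L,
                            mode = "dual_inlet") {
  stopifnot(inherits(target, "target_ion"))
  sp <- target$species
  lo <- sp$mz * (1 - ppm * 1e-6)
  hi <- sp$mz * (1 + ppm * 1e-6)
  ord <- order(sp$mz)
  if (any(hi[ord][-length(ord)] >= lo[ord][-1])) {
    stop("species match windows overlap at ", ppm, " ppm", call. = FALSE)
  }
  peaks <- dplyr::arrange(tibble::as_tibble(peaks), .data$scan, .data$mz)
  scans <- dplyr::distinct(peaks, .data$scan, .data$time_min)
  # window covering all species, for the missing-peak noise fallback
  win <- range(c(lo, hi))
  flags <- list()
  out <- scans
  out$tic <- vapply(scans$scan, function(s) {
    p <- peaks[peaks$scan == s, ]
    sum(p$intensity[p$mz >= win[1] & p$mz <= win[2]])
  }, numeric(1))
  for (i in seq_len(nrow(sp))) {
    lab <- sp$label[i]
    S <- N <- numeric(nrow(scans))
    for (j in seq_len(nrow(scans))) {
      p <- peaks[peaks$scan == scans$scan[j], ]
      inwin <- p$mz >= lo[i] & p$mz <= hi[i]
      if (!any(inwin)) {
        S[j] <- 0
        nz <- p$noise[p$mz >= win[1] & p$mz <= win[2]]
        N[j] <- if (length(nz) > 0) stats::median(nz) else 1
        flags[[length(flags) + 1]] <- tibble::tibble(
          scan = scans$scan[j], species = lab, flag = "missing_peak")
      } else {
        hit <- which(inwin)[which.max(p$intensity[inwin])]
        S[j] <- p$intensity[hit]
        N[j] <- p$noise[hit]
        if (sum(inwin) > 1) {
          flags[[length(flags) + 1]] <- tibble::tibble(
            scan = scans$scan[j], species = lab, flag = "multiple_peaks")
        }
      }
    }
    out[[paste0("S_", lab)]] <- S
    out[[paste0("N_", lab)]] <- N
  }
  f <- paste0(names(target$formula),
              ifelse(target$formula > 1, target$formula, ""), collapse = "")
  run_table(out, formula = f, adduct = target$adduct, charge = target$charge,
            resolution = resolution, microscans = microscans, mode = mode,
            extra = list(flags = dplyr::bind_rows(flags)))
}

#' Contaminant signal fraction in the monitored window
#'
#' Fraction of summed centroid intensity inside an m/z window that is not
#' assigned to any monitored species, per scan, with a run-level summary
#' (median and max). Runs whose median exceeds `threshold` are flagged, not
#' rejected: coisolated species can perturb apparent isotope ratios even
#' when mass-resolved.
#'
#' @param peaks Tidy centroid-peak tibble (see [extract_signals()]).
#' @param target A [target_ion()].
#' @param window Length-2 numeric m/z interval; defaults to the span of the
#'   monitored species padded by 0.5 Da. Must cover all monitored species.
#' @param ppm Species assignment tolerance; defaults to the target's.
#' @param threshold Flagging threshold on the run median (default 0.10).
#' @return List with `per_scan` (tibble: scan, fraction), `median`, `max`
#'   and `flagged`.
#' @export
contamination_fraction <- function(peaks, target, window = NULL,
                                   ppm = target$ppm, threshold = 0.10) {
  stopifnot(inherits(target, "target_ion"))
  sp <- target$species
  if (is.null(window)) window <- range(sp$mz) + c(-0.5, 0.5)
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("window must be an increasing length-2 m/z interval", call. = FALSE)
  }
  if (any(sp$mz < window[1] | sp$mz > window[2])) {
    stop("window must cover all monitored species", call. = FALSE)
  }
  lo <- sp$mz * (1 - ppm * 1e-6)
  hi <- sp$mz * (1 + ppm * 1e-6)
  peaks <- tibble::as_tibble(peaks)
  per_scan <- peaks |>
    dplyr::filter(.data$mz >= window[1], .data$mz <= window[2]) |>
    dplyr::mutate(
      assigned = purrr::map_lgl(.data$mz,
                                function(m) any(m >= lo & m <= hi))
    ) |>
    dplyr::summarise(
      fraction = {
        tot <- sum(.data$intensity)
        if (tot == 0) 0 else sum(.data$intensity[!.data$assigned]) / tot
      },
      .by = "scan"
    )
  med <- stats::median(per_scan$fraction)
  list(per_scan = per_scan, median = med, max = max(per_scan$fraction),
       flagged = med >= threshold)
}
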