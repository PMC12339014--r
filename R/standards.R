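#' Reference delta-13C values of the methyl stearate standard set
#'
#' The working reference and nine gravimetrically prepared 13C-enriched
#' stearic acid methyl ester standards, with their delta-13C versus VPDB as
#' assigned by GC-C-IRMS (the calibration benchmark for this workflow).
#'
#' @return Tibble: `name`, `delta_vpdb` (per mil), `sd` (per mil).
#' @export
fame_standards <- function() {
  tibble::tribble(
    ~name,       ~delta_vpdb, ~sd,
    "Reference", -27.8,       0.4,
    "Std 1",     -29.5,       0.5,
    "Std 2",     -29.8,       0.2,
    "Std 3",     -29.2,       0.2,
    "Std 4",     -29.0,       0.2,
    "Std 5",     -27.4,       0.1,
    "Std 6",     -29.6,       0.5,
    "Std 7",     -29.6,       0.2,
    "Std 8",     -28.9,       0.2,
    "Std 9",     -28.5,       0.2
  )
}

#' Orbitrap delta-13C measurements of the standard set
#'
#' The Orbitrap-measured delta-13C (versus VPDB) of Standards 1-9 for both
#' introduction modes and both adduct ions, together with the residues
#' against the GC-C-IRMS values as originally reported. Note that the
#' reported Std 9 residues are not consistent with the delta columns and
#' [fame_standards()] (recomputation gives different values); use
#' [evaluate_standards()] to compare as-reported and recomputed residues.
#'
#' @return Tibble: `name`, `mode` (`"dual_inlet"`/`"hplc"`), `adduct`
#'   (`"H"`/`"Na"`), `delta_vpdb`, `sd`, `residue_reported` (all per mil).
#' @export
orbitrap_standard_results <- function() {
  di_h  <- c(-30.6, -30.5, -30.1, -29.8, -27.9, -30.2, -30.2, -29.9, -29.7)
  di_h_sd  <- c(0.1, 0.3, 0.3, 0.5, 0.3, 0.3, 0.2, 0.4, 0.3)
  di_h_res  <- c(-1.1, -0.7, -0.9, -0.8, -0.5, -0.6, -0.6, -1.0, -1.7)
  di_na <- c(-29.6, -29.8, -29.3, -28.3, -26.5, -28.7, -28.4, -27.0, -27.3)
  di_na_sd <- c(0.1, 0.2, 0.5, 0.3, 0.6, 0.2, 0.1, 0.3, 0.6)
  di_na_res <- c(-0.1, 0.0, -0.1, 0.7, 0.9, 0.9, 1.2, 1.9, 0.7)
  hp_h  <- c(-28.8, -29.8, -28.1, -28.4, -27.2, -29.2, -28.6, -28.9, -27.5)
  hp_h_sd  <- c(0.4, 1.0, 0.4, 0.4, 0.9, 0.2, 0.5, 1.0, 0.5)
  hp_h_res  <- c(0.7, 0.0, 1.1, 0.6, 0.2, 0.4, 1.0, 0.0, 0.5)
  hp_na <- c(-29.1, -29.7, -28.9, -27.4, -26.7, -28.7, -28.5, -28.4, -27.1)
  hp_na_sd <- c(0.2, 0.4, 0.9, 0.8, 0.7, 0.2, 0.6, 0.4, 0.3)
  hp_na_res <- c(0.4, 0.1, 0.3, 1.6, 0.7, 0.9, 1.1, 0.5, 0.9)
  nm <- paste("Std", 1:9)
  dplyr::bind_rows(
    tibble::tibble(name = nm, mode = "dual_inlet", adduct = "H",
                   delta_vpdb = di_h, sd = di_h_sd,
                   residue_reported = di_h_res),
    tibble::tibble(name = nm, mode = "dual_inlet", adduct = "Na",
                   delta_vpdb = di_na, sd = di_na_sd,
                   residue_reported = di_na_res),
    tibble::tibble(name = nm, mode = "hplc", adduct = "H",
                   delta_vpdb = hp_h, sd = hp_h_sd,
                   residue_reported = hp_h_res),
    tibble::tibble(name = nm, mode = "hplc", adduct = "Na",
                   delta_vpdb = hp_na, sd = hp_na_sd,
                   residue_reported = hp_na_res)
  )
}

#' Evaluate measured standards against their reference values
#'
#' Joins a table of measured delta values with the reference values and
#' reports both the recomputed residues (measured - expected) with their
#' MAE and, when a `residue_reported` column is present, the MAE of the
#' residues as originally reported. The two can differ when a published
#' table is internally inconsistent.
#'
#' @param measured Tibble with `name` and `delta_vpdb` (and optionally
#'   `residue_reported`), e.g. a filtered [orbitrap_standard_results()].
#' @param expected Tibble with `name` and `delta_vpdb`; defaults to
#'   [fame_standards()].
#' @return List: `report` (an `evaluation_report` on recomputed residues),
#'   `mae_recomputed`, `mae_reported` (`NA` when unavailable), and the
#'   joined `table`.
#' @export
evaluate_standards <- function(measured, expected = fame_standards()) {
  joined <- dplyr::inner_join(
    measured,
    dplyr::select(expected, "name", expected = "delta_vpdb"),
    by = "name"
  )
  if (nrow(joined) == 0) stop("no standards in common", call. = FALSE)
  rep <- mae(joined$delta_vpdb, joined$expected, labels = joined$name)
  list(
    report = rep,
    mae_recomputed = rep$mae,
    mae_reported = if ("residue_reported" %in% names(joined)) {
      mean(abs(joined$residue_reported))
    } else NA_real_,
    table = dplyr::mutate(joined, residue = .data$delta_vpdb - .data$expected)
  )
}
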