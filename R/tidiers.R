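#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a delta result
#'
#' One row per bracketed sample block, with the block's isotopologue
#' ratio, its bracketing reference ratio and its delta versus the working
#' standard and versus VPDB.
#'
#' @param x A `delta_result` from [process_session()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy delta_result
#' @export
tidy.delta_result <- function(x, ...) {
  dplyr::mutate(
    x$per_block,
    delta_vpdb = to_vpdb(.data$delta_permil, x$calibration)
  )
}

#' Summarise a delta result in one row
#'
#' @param x A `delta_result` from [process_session()].
#' @param ... Unused.
#' @return One-row tibble: `delta_vs_std`, `delta_vpdb`, `sd`, `se`, `n`,
#'   `n_outliers`, `method`, `scheme`.
#' @method glance delta_result
#' @export
glance.delta_result <- function(x, ...) {
  tibble::tibble(
    delta_vs_std = x$delta_vs_std, delta_vpdb = x$delta_vpdb,
    sd = x$sd, se = x$se, n = x$n,
    n_outliers = sum(!x$series$retained, na.rm = TRUE),
    method = x$method, scheme = x$scheme
  )
}

#' Tidy an evaluation report
#'
#' @param x An `evaluation_report` from [mae()].
#' @param ... Unused.
#' @return The per-standard tibble (label, measured, expected, residue).
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) x$per_standard

#' Summarise an evaluation report in one row
#'
#' @param x An `evaluation_report` from [mae()].
#' @param ... Unused.
#' @return One-row tibble: `mae`, `n`.
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(mae = x$mae, n = x$n)
}
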