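#' Standard isotope masses and abundances
#'
#' Returns the isotope table used throughout the package: for each element,
#' the nuclide mass numbers, exact atomic masses (Da) and natural abundance
#' fractions, following current IUPAC representative values. Every function
#' that consumes an isotope table accepts a replacement built to the same
#' schema, so non-natural compositions (isotopically labelled material,
#' delta-shifted carbon) are expressed by editing this tibble rather than by
#' hidden switches.
#'
#' @return A tibble with columns `element` (symbol), `isotope` (mass number),
#'   `mass` (Da) and `abundance` (fraction; sums to 1 per element).
#' @examples
#' iupac_isotopes()
#' @export
iupac_isotopes <- function() {
  tibble::tribble(
    ~element, ~isotope, ~mass,          ~abundance,
    "H",       1L,      1.00782503207,  0.999885,
    "H",       2L,      2.01410177785,  0.000115,
    "C",      12L,     12.0,            0.9893,
    "C",      13L,     13.00335483507,  0.0107,
    "N",      14L,     14.0030740048,   0.99636,
    "N",      15L,     15.0001088989,   0.00364,
    "O",      16L,     15.99491461956,  0.99757,
    "O",      17L,     16.99913170,     0.00038,
    "O",      18L,     17.99916160,     0.00205,
    "Na",     23L,     22.9897692809,   1.0,
    "S",      32L,     31.97207100,     0.9499,
    "S",      33L,     32.97145876,     0.0075,
    "S",      34L,     33.96786690,     0.0425,
    "S",      36L,     35.96708076,     0.0001
  )
}

# Electron rest mass in Da; subtracted once per positive charge.
.electron_mass <- 0.000548579909

# 13C/12C ratio of the VPDB scale zero point.
.r13_vpdb <- 0.011180

#' Read an isotope table override file
#'
#' Parses a plain-text isotope table with one nuclide per line:
#' `element<TAB>isotope<TAB>mass<TAB>abundance`, `#` comments allowed.
#' Validates the per-element abundance sum and mass ordering.
#'
#' @param path Path to the override file.
#' @return A validated isotope tibble (see [iupac_isotopes()]).
#' @export
read_isotope_table <- function(path) {
  tab <- readr::read_tsv(
    path, comment = "#",
    col_names = c("element", "isotope", "mass", "abundance"),
    col_types = readr::cols(
      element = readr::col_character(), isotope = readr::col_integer(),
      mass = readr::col_double(), abundance = readr::col_double()
    )
  )
  validate_isotope_table(tab)
}

validate_isotope_table <- function(tab) {
  stopifnot(all(c("element", "isotope", "mass", "abundance") %in% names(tab)))
  bad_sum <- tab |>
    dplyr::summarise(s = sum(.data$abundance), .by = "element") |>
    dplyr::filter(abs(.data$s - 1) > 1e-9)
  if (nrow(bad_sum) > 0) {
    stop("isotope abundances do not sum to 1 for: ",
         paste(bad_sum$element, collapse = ", "), call. = FALSE)
  }
  ordered_ok <- tab |>
    dplyr::arrange(.data$element, .data$isotope) |>
    dplyr::summarise(ok = all(diff(.data$mass) > 0) || dplyr::n() == 1,
                     .by = "element")
  if (!all(ordered_ok$ok)) {
    stop("isotope masses must increase with mass number", call. = FALSE)
  }
  tibble::as_tibble(tab)
}

#' Shift the carbon isotope composition to a target delta-13C
#'
#' Rebuilds the 13C/12C abundance pair so that the table's carbon ratio
#' equals the VPDB ratio scaled by `(1 + delta/1000)`. All other elements
#' are left untouched. This is how the session simulator realises a known
#' ground-truth composition.
#'
#' @param delta_vpdb Target delta-13C versus VPDB, in per mil.
#' @param isotopes Isotope table to modify.
#' @return The modified isotope table.
#' @examples
#' shift_carbon_delta(-27.8)
#' @export
shift_carbon_delta <- function(delta_vpdb, isotopes = iupac_isotopes()) {
  stopifnot(is.finite(delta_vpdb))
  r <- .r13_vpdb * (1 + delta_vpdb / 1000)
  x13 <- r / (1 + r)
  dplyr::mutate(
    isotopes,
    abundance = dplyr::case_when(
      .data$element == "C" & .data$isotope == 13L ~ x13,
      .data$element == "C" & .data$isotope == 12L ~ 1 - x13,
      TRUE ~ .data$abundance
    )
  )
}

# Adduct registry: atoms added to the neutral formula and charges carried.
# Positive-mode cations only; extensible by name.
.adducts <- list(
  H  = list(atoms = c(H = 1L),  label = "[M+H]+"),
  Na = list(atoms = c(Na = 1L), label = "[M+Na]+")
)

adduct_atoms <- function(adduct) {
  if (!adduct %in% names(.adducts)) {
    stop("unknown adduct '", adduct, "'; available: ",
         paste(names(.adducts), collapse = ", "), call. = FALSE)
  }
  .adducts[[adduct]]$atoms
}
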