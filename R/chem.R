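#' Parse a molecular formula
#'
#' Parses a Hill-style element-count string such as `"C19H38O2"` into a
#' named integer vector of atom counts. Counts default to 1 when omitted
#' (`"CH4"`); zero or negative counts are rejected, as are element symbols
#' absent from the active isotope table.
#'
#' @param text Formula string.
#' @param isotopes Isotope table defining the allowed elements.
#' @return Named integer vector of atom counts.
#' @examples
#' parse_formula("C19H38O2")
#' @export
parse_formula <- function(text, isotopes = iupac_isotopes()) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(text)) stop("empty formula", call. = FALSE)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("cannot parse formula '", text, "'", call. = FALSE)
  }
  elements <- sub("[0-9]*$", "", toks)
  counts <- sub("^[A-Za-z]+", "", toks)
  counts <- ifelse(nzchar(counts), as.integer(counts), 1L)
  known <- unique(isotopes$element)
  if (any(!elements %in% known)) {
    stop("unknown element(s): ",
         paste(setdiff(elements, known), collapse = ", "), call. = FALSE)
  }
  if (any(counts <= 0)) stop("element counts must be positive", call. = FALSE)
  out <- vapply(split(counts, elements), sum, integer(1))
  out[order(names(out))]
}

# Per-element multinomial expansion: all ways of distributing `n` atoms over
# the element's isotopes, with exact multinomial probability and mass.
element_expansion <- function(element, n, isotopes) {
  iso <- dplyr::filter(isotopes, .data$element == !!element) |>
    dplyr::arrange(.data$isotope)
  k <- nrow(iso)
  if (k == 0) stop("no isotopes for element ", element, call. = FALSE)
  if (k == 1) {
    return(tibble::tibble(
      prob = 1, mass = n * iso$mass, label = list(character(0))
    ))
  }
  # counts of the k-1 heavier isotopes; remainder goes to the lightest
  grids <- lapply(seq_len(k - 1), function(i) 0:n)
  combos <- expand.grid(grids)
  combos <- combos[rowSums(combos) <= n, , drop = FALSE]
  heavy <- as.matrix(combos)
  light <- n - rowSums(heavy)
  counts <- cbind(light, heavy)
  lp <- lgamma(n + 1) - rowSums(lgamma(counts + 1)) +
    counts %*% log(pmax(iso$abundance, .Machine$double.xmin))
  prob <- as.numeric(exp(lp))
  mass <- as.numeric(counts %*% iso$mass)
  labels <- lapply(seq_len(nrow(counts)), function(i) {
    h <- heavy[i, ]
    idx <- which(h > 0)
    if (length(idx) == 0) return(character(0))
    paste0(iso$isotope[idx + 1], element, h[idx])
  })
  tibble::tibble(prob = prob, mass = mass, label = labels)
}

#' Isotopologue fine structure of an ionised formula
#'
#' Expands the full isotopologue distribution of `formula` plus adduct atoms
#' by exact per-element multinomial expansion, returning one row per
#' substitution pattern with its relative abundance (normalised over the
#' complete, unpruned expansion) and exact m/z for the declared adduct and
#' charge. Pruning removes low-abundance rows from the output only; it never
#' renormalises the remaining abundances.
#'
#' Species whose m/z falls within one resolution element (FWHM = m/z / r) of
#' another retained species are flagged `resolved = FALSE` rather than
#' merged; at the resolutions this workflow targets the monitored species
#' are cleanly separated.
#'
#' @param formula Formula string or named count vector (see
#'   [parse_formula()]).
#' @param adduct `"H"` (protonation) or `"Na"` (sodiation). Adduct atoms
#'   take part in the isotopic expansion: a proton adds one H site.
#' @param charge Positive integer charge.
#' @param prune Abundance fraction below which species are dropped from the
#'   output (default `1e-6`).
#' @param isotopes Isotope table.
#' @param resolution Optional mass resolution used only to set the
#'   `resolved` flag.
#' @return Tibble with columns `label` (`"M0"`, `"13C1"`, `"18O1"`,
#'   `"13C1.2H1"`, ...), `abundance`, `mz` and `resolved`, sorted by
#'   descending abundance.
#' @examples
#' fine_structure("C19H38O2", adduct = "H")
#' @export
fine_structure <- function(formula, adduct = "H", charge = 1L, prune = 1e-6,
                           isotopes = iupac_isotopes(), resolution = NULL) {
  if (is.character(formula)) formula <- parse_formula(formula, isotopes)
  if (length(formula) == 0) stop("empty formula", call. = FALSE)
  stopifnot(prune >= 0, prune < 1, charge >= 1)
  add <- adduct_atoms(adduct)
  atoms <- formula
  for (el in names(add)) {
    atoms[el] <- (if (el %in% names(atoms)) atoms[[el]] else 0L) + add[[el]]
  }
  parts <- purrr::imap(
    atoms, function(n, el) element_expansion(el, n, isotopes)
  )
  # cross the per-element expansions, pruning on the running product
  acc <- tibble::tibble(prob = 1, mass = 0, label = list(character(0)))
  for (p in parts) {
    acc <- tidyr::crossing(
      acc |> dplyr::rename(p0 = "prob", m0 = "mass", l0 = "label"),
      p |> dplyr::select(p1 = "prob", m1 = "mass", l1 = "label")
    ) |>
      dplyr::transmute(
        prob = .data$p0 * .data$p1,
        mass = .data$m0 + .data$m1,
        label = purrr::map2(.data$l0, .data$l1, c)
      ) |>
      dplyr::filter(.data$prob >= prune)
  }
  out <- acc |>
    dplyr::mutate(
      label = purrr::map_chr(
        .data$label,
        function(l) if (length(l) == 0) "M0" else paste(sort(l), collapse = ".")
      ),
      mz = (.data$mass - charge * .electron_mass) / charge
    ) |>
    dplyr::summarise(
      abundance = sum(.data$prob), mz = .data$mz[1],
      .by = "label"
    ) |>
    dplyr::arrange(dplyr::desc(.data$abundance))
  if (!is.null(resolution)) {
    fwhm <- out$mz / resolution
    out$resolved <- purrr::map_lgl(seq_len(nrow(out)), function(i) {
      all(abs(out$mz[-i] - out$mz[i]) > fwhm[i])
    })
  } else {
    out$resolved <- NA
  }
  out
}

#' Exact m/z of a species
#'
#' Computes `(sum of atomic masses with substitutions + adduct mass -
#' charge * electron mass) / charge` for a labelled substitution pattern of
#' a formula.
#'
#' @param formula Formula string or named count vector (neutral molecule).
#' @param label Substitution label as produced by [fine_structure()]
#'   (`"M0"`, `"13C1"`, `"18O1.13C1"`, ...).
#' @param adduct,charge Ion declaration (see [fine_structure()]).
#' @param isotopes Isotope table.
#' @return m/z in Da.
#' @examples
#' species_mz("C19H38O2", "M0", adduct = "H")
#' @export
species_mz <- function(formula, label = "M0", adduct = "H", charge = 1L,
                       isotopes = iupac_isotopes()) {
  fs <- fine_structure(formula, adduct, charge, prune = 0,
                       isotopes = isotopes)
  hit <- fs$mz[fs$label == label]
  if (length(hit) != 1) {
    stop("species '", label, "' not found in the expansion", call. = FALSE)
  }
  hit
}

#' Declare a target ion and its monitored species
#'
#' Bundles a formula, adduct, charge, the monitored isotopologue labels and
#' an m/z matching tolerance into the object consumed by signal extraction
#' and the simulator.
#'
#' @param formula Formula string or named count vector.
#' @param adduct,charge Ion declaration.
#' @param species Character vector of monitored labels; all must exist in
#'   the fine-structure expansion.
#' @param ppm Matching tolerance in parts per million (default 5).
#' @param isotopes Isotope table.
#' @return A `target_ion` object: list with the declaration and a `species`
#'   tibble (label, abundance, mz).
#' @examples
#' target_ion("C19H38O2", species = c("M0", "13C1"))
#' @export
target_ion <- function(formula, adduct = "H", charge = 1L,
                       species = c("M0", "13C1", "13C2", "18O1"),
                       ppm = 5, isotopes = iupac_isotopes()) {
  if (is.character(formula)) formula <- parse_formula(formula, isotopes)
  stopifnot(length(species) >= 1, !anyDuplicated(species), ppm > 0)
  fs <- fine_structure(formula, adduct, charge, prune = 0,
                       isotopes = isotopes)
  missing <- setdiff(species, fs$label)
  if (length(missing) > 0) {
    stop("monitored species not in expansion: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sp <- fs[match(species, fs$label), c("label", "abundance", "mz")]
  structure(
    list(formula = formula, adduct = adduct, charge = as.integer(charge),
         ppm = ppm, species = sp),
    class = "target_ion"
  )
}

#' @export
print.target_ion <- function(x, ...) {
  f <- paste0(names(x$formula), ifelse(x$formula > 1, x$formula, ""),
              collapse = "")
  cat("<target_ion> ", f, " ", .adducts[[x$adduct]]$label,
      "  (tolerance ", x$ppm, " ppm)\n", sep = "")
  print(x$species)
  invisible(x)
}
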