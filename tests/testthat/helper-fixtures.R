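# Shared fixtures built in code.

# Brute-force isotopologue enumeration: assigns an isotope to every atom
# site individually and aggregates by substitution pattern. Exponential in
# atom count; the independent oracle for small formulas.
brute_force_fine_structure <- function(atoms, isotopes,
                                       electron_mass = 0.000548579909,
                                       charge = 1L) {
  sites <- rep(names(atoms), atoms)
  per_site <- lapply(sites, function(el) {
    iso <- isotopes[isotopes$element == el, ]
    iso <- iso[order(iso$isotope), ]
    split(iso, seq_len(nrow(iso)))
  })
  grid <- expand.grid(lapply(per_site, seq_along))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    picks <- lapply(seq_along(per_site), function(j) {
      per_site[[j]][[grid[i, j]]]
    })
    prob <- prod(vapply(picks, function(p) p$abundance, numeric(1)))
    mass <- sum(vapply(picks, function(p) p$mass, numeric(1)))
    # substitution label: heavier-than-lightest isotopes per element
    subs <- character(0)
    for (el in unique(sites)) {
      iso <- isotopes[isotopes$element == el, ]
      lightest <- min(iso$isotope)
      chosen <- vapply(picks[sites == el], function(p) p$isotope, integer(1))
      for (h in sort(unique(chosen[chosen != lightest]))) {
        subs <- c(subs, paste0(h, el, sum(chosen == h)))
      }
    }
    lab <- if (length(subs) == 0) "M0" else paste(sort(subs), collapse = ".")
    data.frame(label = lab, prob = prob, mass = mass)
  })
  agg <- do.call(rbind, rows)
  out <- aggregate(prob ~ label, agg, sum)
  out$mz <- (agg$mass[match(out$label, agg$label)] -
               charge * electron_mass) / charge
  out[order(-out$prob), ]
}

# A minimal 3-scan run table with two species.
tiny_run <- function() {
  run_table(
    tibble::tibble(
      scan = 1:3, time_min = c(0, 1, 2) / 60, tic = c(100, 110, 105),
      S_M0 = c(90, 99, 94.5), N_M0 = c(1, 1.1, 1),
      S_13C1 = c(9, 9.9, 9.45), N_13C1 = c(1, 1.1, 1)
    ),
    formula = "C19H38O2", adduct = "H", resolution = 60000, microscans = 2L
  )
}

# Constructed centroid peaks: every scan carries the monitored species at
# exact m/z with given intensities; extra peaks appended as given.
make_peaks <- function(target, n_scans = 3, intensities = NULL,
                       noise = 2, extra = NULL) {
  sp <- target$species
  if (is.null(intensities)) {
    intensities <- stats::setNames(1000 * sp$abundance / max(sp$abundance),
                                   sp$label)
  }
  base <- do.call(rbind, lapply(seq_len(n_scans), function(s) {
    data.frame(scan = s, time_min = (s - 1) / 60, mz = sp$mz,
               intensity = unname(intensities[sp$label]), noise = noise)
  }))
  out <- rbind(base, extra)
  tibble::as_tibble(out[order(out$scan, out$mz), ])
}
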