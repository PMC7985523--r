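#' Load a bundled chromophore absorption table
#'
#' Reads one of the wavelength-resolved absorption tables shipped with the
#' package. The default table covers 650--1000 nm in 5 nm steps and holds
#' whole-blood absorption of fully oxygenated (`mu_a_hbo2`) and fully
#' deoxygenated (`mu_a_hb`) blood at the reference hemoglobin concentration
#' of 150 g/L, together with pure-water and melanosome absorption, all in
#' cm^-1. Values between grid nodes are obtained by linear interpolation;
#' querying outside the covered range is an error.
#'
#' The bundled table is a synthetic compilation: smooth spectra anchored at
#' landmark values of the standard tissue-optics literature (Hb peak near
#' 760 nm, Hb/HbO2 isosbestic point at 800 nm, water rise towards 970 nm),
#' documented in the file header.
#'
#' @param source identifier of the bundled table (currently
#'   `"nir_synthetic"`), or the path to a TSV file with columns
#'   `wavelength_nm`, `mu_a_hbo2`, `mu_a_hb`, `mu_a_water`, `mu_a_melanin`.
#' @return An object of class `chromophore_table`.
#' @examples
#' tab <- load_chromophore_table()
#' chromophore_absorption(tab, "hb", 760)
#' @export
load_chromophore_table <- function(source = "nir_synthetic") {
  path <- if (file.exists(source)) source else
    system.file("extdata", paste0("chromophores_", source, ".tsv"),
                package = "lsdox")
  if (!nzchar(path) || !file.exists(path))
    stopf("bundled chromophore table '%s' not found", source)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  needed <- c("wavelength_nm", "mu_a_hbo2", "mu_a_hb", "mu_a_water",
              "mu_a_melanin")
  if (!all(needed %in% names(tab)))
    stopf("chromophore table '%s' is corrupt: missing columns %s", source,
          paste(setdiff(needed, names(tab)), collapse = ", "))
  if (any(!is.finite(as.matrix(tab[needed]))) || any(tab[needed] < 0))
    stopf("chromophore table '%s' is corrupt: non-finite or negative values",
          source)
  wl <- tab$wavelength_nm
  if (is.unsorted(wl, strictly = TRUE))
    stopf("chromophore table wavelength grid must be strictly increasing")
  if (wl[1] > 660 || wl[length(wl)] < 960)
    stopf("chromophore table must cover at least 660-960 nm")
  structure(tab, class = c("chromophore_table", "data.frame"))
}

#' Query a chromophore table
#'
#' Linear interpolation of a stored spectrum at arbitrary wavelengths within
#' the covered range; exact at grid nodes.
#'
#' @param table a [load_chromophore_table()] object.
#' @param chromophore one of `"hbo2"`, `"hb"`, `"water"`, `"melanin"`.
#' @param wavelength numeric vector of wavelengths in nm.
#' @return absorption coefficient(s) in cm^-1.
#' @export
chromophore_absorption <- function(table, chromophore, wavelength) {
  stopifnot(inherits(table, "chromophore_table"))
  col <- paste0("mu_a_", match.arg(chromophore,
                                   c("hbo2", "hb", "water", "melanin")))
  wl <- table$wavelength_nm
  if (any(wavelength < wl[1] | wavelength > wl[length(wl)]))
    stopf("wavelength outside table range [%g, %g] nm", wl[1], wl[length(wl)])
  stats::approx(wl, table[[col]], xout = wavelength, rule = 1)$y
}

#' Whole-blood absorption coefficient
#'
#' Mixes the oxy- and deoxyhemoglobin endmembers according to the oxygen
#' saturation and rescales linearly with the hemoglobin concentration:
#' `(chb/150) * (so2 * mu_a_hbo2 + (1 - so2) * mu_a_hb)`.
#'
#' @param so2 oxygen saturation, fraction in \[0, 1\].
#' @param chb hemoglobin concentration in g/L (reference 150).
#' @param wavelength wavelength(s) in nm.
#' @param table chromophore table.
#' @return absorption in cm^-1.
#' @export
blood_absorption <- function(so2, chb = 150, wavelength,
                             table = load_chromophore_table()) {
  check_fraction(so2, "so2")
  if (!is.numeric(chb) || chb <= 0) stopf("`chb` must be positive (g/L)")
  (chb / 150) * (so2 * chromophore_absorption(table, "hbo2", wavelength) +
                   (1 - so2) * chromophore_absorption(table, "hb", wavelength))
}

#' Tissue composition
#'
#' Describes a tissue type by its chromophore volume fractions and scattering
#' parameters. Blood enters through `blood_volume_fraction` and `oxygenation`
#' at hemoglobin concentration `hemoglobin_concentration`; melanin and water
#' scale the pure-constituent reference spectra linearly. Reduced scattering
#' follows the power law `mus_prime_ref * (lambda/800)^(-scatter_power)`;
#' `scatter_power = 0` gives wavelength-constant scattering.
#'
#' @param blood_volume_fraction,oxygenation,melanin_fraction,water_fraction
#'   fractions in \[0, 1\].
#' @param hemoglobin_concentration whole-blood hemoglobin, g/L.
#' @param mus_prime_ref reduced scattering coefficient at 800 nm, cm^-1.
#' @param scatter_power exponent of the scattering power law.
#' @param anisotropy scattering anisotropy g in (-1, 1).
#' @return object of class `tissue_composition`.
#' @export
tissue_composition <- function(blood_volume_fraction = 0, oxygenation = 0,
                               melanin_fraction = 0, water_fraction = 0,
                               hemoglobin_concentration = 150,
                               mus_prime_ref = 0, scatter_power = 0,
                               anisotropy = 0.9) {
  check_fraction(blood_volume_fraction, "blood_volume_fraction")
  check_fraction(oxygenation, "oxygenation")
  check_fraction(melanin_fraction, "melanin_fraction")
  check_fraction(water_fraction, "water_fraction")
  if (hemoglobin_concentration <= 0) stopf("hemoglobin_concentration must be > 0")
  if (mus_prime_ref < 0) stopf("mus_prime_ref must be >= 0")
  if (abs(anisotropy) >= 1) stopf("anisotropy must lie in (-1, 1)")
  structure(list(blood_volume_fraction = blood_volume_fraction,
                 oxygenation = oxygenation,
                 melanin_fraction = melanin_fraction,
                 water_fraction = water_fraction,
                 hemoglobin_concentration = hemoglobin_concentration,
                 mus_prime_ref = mus_prime_ref,
                 scatter_power = scatter_power,
                 anisotropy = anisotropy),
            class = "tissue_composition")
}

#' Tissue absorption coefficient
#'
#' Superposition of the constituent spectra:
#' `mu_a = bvf * blood + melanin_fraction * melanin + water_fraction * water`.
#'
#' @param comp a [tissue_composition()].
#' @param wavelength wavelength(s) in nm.
#' @param table chromophore table.
#' @return absorption in cm^-1 (non-negative).
#' @export
tissue_absorption <- function(comp, wavelength,
                              table = load_chromophore_table()) {
  stopifnot(inherits(comp, "tissue_composition"))
  mu <- comp$melanin_fraction *
    chromophore_absorption(table, "melanin", wavelength) +
    comp$water_fraction * chromophore_absorption(table, "water", wavelength)
  if (comp$blood_volume_fraction > 0)
    mu <- mu + comp$blood_volume_fraction *
      blood_absorption(comp$oxygenation, comp$hemoglobin_concentration,
                       wavelength, table)
  mu
}

#' Tissue scattering coefficient
#'
#' Reduced scattering from the power law
#' `mus_prime(lambda) = mus_prime_ref * (lambda/800)^(-scatter_power)`, and
#' the full scattering coefficient `mus = mus_prime / (1 - g)`.
#'
#' @inheritParams tissue_absorption
#' @return list with elements `mu_s` (cm^-1), `mu_s_prime` (cm^-1) and `g`.
#' @export
tissue_scattering <- function(comp, wavelength) {
  stopifnot(inherits(comp, "tissue_composition"))
  g <- comp$anisotropy
  if (g == 1) stopf("anisotropy g = 1 gives an undefined scattering coefficient")
  msp <- comp$mus_prime_ref * (wavelength / 800)^(-comp$scatter_power)
  list(mu_s = msp / (1 - g), mu_s_prime = msp, g = g)
}
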