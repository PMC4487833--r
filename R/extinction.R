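# Hemoglobin extinction spectra ------------------------------------------------

#' Build a two-chromophore extinction table
#'
#' Tabulates decadic extinction coefficients of oxy- and deoxyhemoglobin at the
#' measurement wavelengths, in mm^-1 per micromolar, the units in which the
#' absorption volumes are expressed (`mu_a = eps_HbO2 * [HbO2] + eps_Hb * [Hb]`
#' with concentrations in uM).
#'
#' @param wavelength_nm numeric vector of distinct wavelengths (nm).
#' @param eps_hbo2,eps_hb positive extinction coefficients (mm^-1 uM^-1) of
#'   oxy- and deoxyhemoglobin at those wavelengths.
#' @return A data frame of class `extinction_table` with columns
#'   `wavelength_nm`, `eps_hbo2`, `eps_hb`, ordered by wavelength.
#' @seealso [default_extinction()] for the built-in compilation.
#' @export
extinction_table <- function(wavelength_nm, eps_hbo2, eps_hb) {
  dh_assert(length(wavelength_nm) >= 2, "dothisto_spectral_design",
            "at least 2 distinct wavelengths are required")
  dh_assert(length(eps_hbo2) == length(wavelength_nm) &&
              length(eps_hb) == length(wavelength_nm),
            "dothisto_spectral_design", "column lengths differ")
  dh_assert(!anyDuplicated(wavelength_nm), "dothisto_spectral_design",
            "duplicate wavelengths make the spectral design rank-deficient")
  dh_assert(all(eps_hbo2 > 0) && all(eps_hb > 0), "dothisto_spectral_design",
            "all extinction coefficients must be positive")
  ord <- order(wavelength_nm)
  out <- data.frame(wavelength_nm = as.numeric(wavelength_nm[ord]),
                    eps_hbo2 = as.numeric(eps_hbo2[ord]),
                    eps_hb = as.numeric(eps_hb[ord]))
  # full column rank of the 2-column design
  E <- as.matrix(out[, c("eps_hbo2", "eps_hb")])
  dh_assert(qr(E)$rank == 2, "dothisto_spectral_design",
            "extinction design matrix is rank-deficient (collinear spectra)")
  class(out) <- c("extinction_table", "data.frame")
  out
}

#' Default extinction table at the four frequency-domain wavelengths
#'
#' Molar extinction values for HbO2/Hb at 690, 750, 786 and 830 nm from the
#' standard compiled hemoglobin spectra, converted from cm^-1/M (decadic) to
#' mm^-1 uM^-1 via `eps * 2.303e-7` (natural-log absorption convention used by
#' diffuse optics, 0.1 mm/cm, 1e-6 M/uM).  Which compilation a given study
#' used is an input, not a constant; pass your own [extinction_table()] to
#' override.
#'
#' @return An [extinction_table()].
#' @export
default_extinction <- function() {
  molar <- data.frame( # cm^-1 / M, decadic
    wavelength_nm = c(690, 750, 786, 830),
    hbo2 = c(276, 518, 735, 974),
    hb   = c(2052, 1405, 1097, 693)
  )
  k <- log(10) * 1e-7 # to mm^-1 uM^-1, natural-log mu_a
  extinction_table(molar$wavelength_nm, molar$hbo2 * k, molar$hb * k)
}

#' Read an extinction table from CSV
#'
#' Expects columns `wavelength_nm`, `eps_hbo2`, `eps_hb` (mm^-1 uM^-1).
#' @param path CSV file.
#' @return An [extinction_table()].
#' @export
read_extinction_csv <- function(path) {
  d <- read.csv(path)
  dh_assert(all(c("wavelength_nm", "eps_hbo2", "eps_hb") %in% names(d)),
            "dothisto_spectral_design",
            "extinction CSV needs wavelength_nm, eps_hbo2, eps_hb columns")
  extinction_table(d$wavelength_nm, d$eps_hbo2, d$eps_hb)
}
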