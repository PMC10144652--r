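#' Physical constants and unit conversions
#'
#' Internal unit policy: electronic quantities (energies, dipole matrix
#' elements) are held in atomic units, coordinates in nm (the MD
#' convention), and all conversions pass through the constants below so a
#' unit never changes silently. CODATA 2018 values.
#'
#' The rotational strength is formed from an electric transition dipole in
#' atomic units (e*a0) and a magnetic transition dipole in atomic units
#' (e*hbar/m_e); its cgs value is the product of the two single-unit
#' conversions:
#'   e*a0        = 2.5417464731e-18 esu cm
#'   e*hbar/m_e  = 1.85480201566e-20 erg/G
#'   R(cgs)      = R(a.u.) * 4.71443934e-38
#' Dipole strength |mu|^2 converts with (e*a0)^2 = 6.46047555e-36 esu^2 cm^2.
#'
#' The CD extinction prefactor 2.296e-39 converts a binned mean rotational
#' strength (cgs) times frequency (cm^-1) into a molar circular dichroism
#' Delta-epsilon in M^-1 cm^-1; the matching UV relation uses
#' D = 9.184e-39 * integral(eps/nu dnu), i.e. a prefactor four times larger
#' (the standard cgs dipole/rotational strength sum rules, which differ by
#' the factor 4 between absorption and CD).
#'
#' @name pmmcd-constants
#' @keywords internal
NULL

## energy
HARTREE_EV <- 27.211386245988
HARTREE_WAVENUMBER <- 219474.6313632    # cm^-1 per hartree
EV_WAVENUMBER <- HARTREE_WAVENUMBER / HARTREE_EV  # 8065.54 cm^-1 per eV

## length
BOHR_NM <- 0.0529177210903              # nm per bohr

## dipoles, atomic units -> cgs
EA0_ESU_CM <- 2.5417464731e-18          # e*a0 in esu cm
MAG_AU_ERG_G <- 1.85480201566e-20       # e*hbar/m_e in erg/G
ROTSTR_AU_TO_CGS <- EA0_ESU_CM * MAG_AU_ERG_G   # 4.7144e-38
DIPSTR_AU_TO_CGS <- EA0_ESU_CM^2                # 6.4605e-36

## extinction prefactors (cgs sum-rule constants)
CD_PREFACTOR_CGS <- 2.296e-39
UV_PREFACTOR_CGS <- 4 * CD_PREFACTOR_CGS        # 9.184e-39

## thermodynamics
KB_KJMOL <- 0.0083145                   # kJ/mol/K

## wavelength (nm) <-> wavenumber (cm^-1): nu = 1e7 / lambda
WAVENUMBER_PER_NM <- 1e7

#' Convert wavelength in nm to wavenumber in cm^-1 (and back)
#'
#' The same reciprocal relation serves both directions:
#' `nu[cm^-1] = 1e7 / lambda[nm]`.
#'
#' @param x wavelengths in nm, or wavenumbers in cm^-1.
#' @return the reciprocal quantity.
#' @export
nm_to_wavenumber <- function(x) {
  stopifnot(is.numeric(x), all(x > 0))
  WAVENUMBER_PER_NM / x
}

#' @rdname nm_to_wavenumber
#' @export
wavenumber_to_nm <- function(x) nm_to_wavenumber(x)
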