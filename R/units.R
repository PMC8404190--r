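#' Unit conversion constants and helpers
#'
#' All internal computation is done in Hartree atomic units; every
#' user-facing interface takes electronvolts (energies), femtoseconds
#' (times) and bohr (mass-weighted lengths).  The conversion factors are
#' centralized here so they appear exactly once in the code base.
#'
#' @format `HARTREE_EV` is 1 hartree in eV; `AUT_FS` is 1 atomic time unit
#'   in fs; `FWHM_SIGMA` is the full-width-at-half-maximum of a Gaussian
#'   amplitude envelope divided by its standard deviation, `2*sqrt(2*log(2))`.
#' @name units
NULL

#' @rdname units
#' @export
HARTREE_EV <- 27.211386

#' @rdname units
#' @export
AUT_FS <- 0.02418884

#' @rdname units
#' @export
FWHM_SIGMA <- 2 * sqrt(2 * log(2))

#' @rdname units
#' @param x numeric vector.
#' @export
ev_to_au <- function(x) x / HARTREE_EV

#' @rdname units
#' @export
au_to_ev <- function(x) x * HARTREE_EV

#' @rdname units
#' @export
fs_to_au <- function(x) x / AUT_FS

#' @rdname units
#' @export
au_to_fs <- function(x) x * AUT_FS

# hbar = 1 in atomic units; in interface units hbar = HARTREE_EV * AUT_FS
# eV fs (~0.6582) -- used when converting beat frequencies to energies.
HBAR_EV_FS <- HARTREE_EV * AUT_FS
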