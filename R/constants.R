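#' Physical constants for force spectroscopy calculations
#'
#' Bundles the thermal energy scale and unit conversions used throughout the
#' package. Forces are in pN, lengths in nm, energies in pN nm or kcal/mol.
#'
#' @param temperature Absolute temperature in kelvin. The default corresponds
#'   to room temperature (23 degrees C), the condition of the force-ramp
#'   assays this package models.
#' @return An object of class `physical_constants`: a list with elements
#'   `temperature` (K), `kT` (pN nm) and `kcal_per_mol_pn_nm`, the number of
#'   pN nm in one kcal/mol (6.9477).
#' @examples
#' pc <- physical_constants()
#' pc$kT    # ~4.09 pN nm at 296.15 K
#' @export
physical_constants <- function(temperature = 296.15) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            temperature > 0)
  out <- list(
    temperature = temperature,
    kT = 0.0138065 * temperature,
    kcal_per_mol_pn_nm = 6.9477
  )
  class(out) <- "physical_constants"
  out
}

#' @export
print.physical_constants <- function(x, ...) {
  cat(sprintf("Physical constants: T = %.2f K, kT = %.4f pN nm (%.4f kcal/mol)\n",
              x$temperature, x$kT, x$kT / x$kcal_per_mol_pn_nm))
  invisible(x)
}

#' Convert energies between pN nm and kcal/mol
#'
#' @param x Energy values.
#' @param constants A [physical_constants()] object.
#' @return Converted energy values.
#' @export
pn_nm_to_kcal <- function(x, constants = physical_constants()) {
  x / constants$kcal_per_mol_pn_nm
}

#' @rdname pn_nm_to_kcal
#' @export
kcal_to_pn_nm <- function(x, constants = physical_constants()) {
  x * constants$kcal_per_mol_pn_nm
}

# default helical rises (nm per residue)
RISE_SS <- 0.45   # ssDNA contour length per nucleotide
RISE_DS <- 0.338  # dsDNA rise per base pair
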