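#' @useDynLib coildeploy, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd setNames approx t.test shapiro.test var
#' @importFrom utils head tail write.csv
NULL

# Unit system
#
# User-facing quantities are expressed in the units the field prints them in:
# lengths in mm, moduli in GPa, forces in N, rigidities in N (axial/shear)
# and N*mm^2 (flexural), densities in mg/mm^3.
#
# The dynamic solver works in a consistent mm / mg / ms system, in which the
# derived force unit is the microNewton*10^3 = mN and the derived stress unit
# is mN/mm^2 = kPa.  All conversions are centralized here.

#' Unit conversion constants and audit table
#'
#' The package uses mm / mg / ms internally for dynamics (derived force unit
#' mN, derived stress unit kPa) and mm / GPa / N externally for coil
#' mechanics, as is conventional for device specifications.  This function
#' returns the full conversion table so every factor used in the code can be
#' audited in one place.
#'
#' @return A data.frame with columns `quantity`, `external`, `internal`,
#'   and `factor` (multiply external by `factor` to obtain internal).
#' @export
unit_table <- function() {
  data.frame(
    quantity = c("length", "mass", "time", "modulus", "force",
                 "rigidity (axial/shear)", "rigidity (flexural)",
                 "density", "velocity"),
    external = c("mm", "mg", "ms", "GPa = kN/mm^2", "N",
                 "N", "N*mm^2", "mg/mm^3", "mm/ms"),
    internal = c("mm", "mg", "ms", "kPa = mN/mm^2", "mN",
                 "mN", "mN*mm^2", "mg/mm^3", "mm/ms"),
    factor = c(1, 1, 1, 1e6, 1e3, 1e3, 1e3, 1, 1),
    stringsAsFactors = FALSE
  )
}

# multiply GPa by this to get internal stress units (mN/mm^2 = kPa)
GPA_TO_INTERNAL <- 1e6
# multiply GPa*mm^2 (= kN) by this to get N
GPA_MM2_TO_N <- 1e3
# multiply N by this to get internal force units (mN)
N_TO_INTERNAL <- 1e3

stop_domain <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
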