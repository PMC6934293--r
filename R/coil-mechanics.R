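# Helical-spring equivalent mechanics of embolic coils.
#
# An embolic coil has a multiscale structure: a primary platinum wire of
# diameter D1 is tightly wound into a helical secondary structure of outer
# diameter D2, which is heat-set into a tertiary pre-shape of envelope
# diameter D3.  The simulator models the secondary structure as a chain of
# tubular Timoshenko beam elements; realistic softness is obtained by
# equating the rigidity of those beams to the rigidity of the helical
# spring they stand in for.

#' Wire (primary structure) specification
#'
#' @param D1 primary wire diameter (mm)
#' @param Ew wire Young's modulus (GPa)
#' @param Gw wire shear modulus (GPa)
#' @param rho_w wire material density (mg/mm^3); default is the density of
#'   a platinum/tungsten alloy
#' @return An object of class `wire_spec`.
#' @export
wire_spec <- function(D1, Ew, Gw, rho_w = 21.45) {
  if (!is.numeric(D1) || D1 <= 0) stop_domain("D1 must be > 0")
  if (Ew <= 0 || Gw <= 0) stop_domain("wire moduli must be > 0")
  if (Gw >= Ew) stop_domain("Gw must be < Ew for an isotropic metal")
  if (rho_w <= 0) stop_domain("rho_w must be > 0")
  structure(list(D1 = D1, Ew = Ew, Gw = Gw, rho_w = rho_w),
            class = "wire_spec")
}

#' Secondary (helical) structure specification
#'
#' Under the tight-winding closure the coil length equals `n * D1`: adjacent
#' loops of the primary wire touch, so each loop advances the coil by one
#' wire diameter.  When `n` is omitted it is derived from the length via
#' [loops_from_length()].
#'
#' @param D2 secondary (coil) outer diameter (mm)
#' @param l coil length (mm)
#' @param n number of primary wire loops; defaults to `l / D1` of the paired
#'   wire (tight winding)
#' @param wire the paired [wire_spec()] (used for validation and the default
#'   `n`)
#' @return An object of class `secondary_spec`.
#' @export
secondary_spec <- function(D2, l, n = NULL, wire = NULL) {
  if (D2 <= 0 || l <= 0) stop_domain("D2 and l must be > 0")
  if (!is.null(wire)) {
    if (D2 <= wire$D1) stop_domain("D2 must exceed the wire diameter D1")
    if (is.null(n)) n <- loops_from_length(l, wire$D1)
  }
  if (is.null(n)) stop_domain("n must be given when no wire is paired")
  if (n < 1) stop_domain("n must be >= 1")
  structure(list(D2 = D2, l = l, n = n), class = "secondary_spec")
}

#' Loop count from coil length under tight winding
#'
#' A tightly wound coil advances by one wire diameter per loop, so the coil
#' length is `n * D1` and the loop count is `l / D1`.  The value is returned
#' real-valued; rounding, if wanted, is the caller's choice.
#'
#' @param l coil length (mm)
#' @param D1 primary wire diameter (mm)
#' @return Loop count `n = l / D1`.
#' @export
loops_from_length <- function(l, D1) {
  if (!is.numeric(l) || !is.numeric(D1) || any(l <= 0) || any(D1 <= 0))
    stop_domain("l and D1 must be positive")
  l / D1
}

#' Mechanical rigidities of the helical secondary structure
#'
#' Computes the compressive, shearing and flexural rigidities of a helical
#' spring from its geometry and wire material:
#' \deqn{D_{compressive} = G_w D_1^4 l / (8 n D_2^3)}
#' \deqn{D_{shearing}    = E_w D_1^4 l / (8 n D_2^3)}
#' \deqn{D_{flexural}    = E_w G_w D_1^4 l / (16 n D_2 (2 G_w + E_w))}
#' With moduli in GPa and lengths in mm the raw products carry GPa*mm^2 =
#' kN; the returned values are converted to N (and N*mm^2 for the flexural
#' rigidity).
#'
#' The spring diameter enters exactly as the printed outer diameter `D2`.
#' Set `diameter = "mean"` to use the mean helix diameter `D2 - D1` instead,
#' which is the textbook spring convention and is used when cross-checking
#' against a brute-force discretized spring.
#'
#' @param wire a [wire_spec()]
#' @param sec a [secondary_spec()]
#' @param diameter `"outer"` (default, uses `D2`) or `"mean"` (uses
#'   `D2 - D1`)
#' @return Object of class `spring_rigidities` with fields `Dcomp` (N),
#'   `Dshear` (N), `Dflex` (N*mm^2).
#' @export
spring_rigidities <- function(wire, sec, diameter = c("outer", "mean")) {
  diameter <- match.arg(diameter)
  stopifnot(inherits(wire, "wire_spec"), inherits(sec, "secondary_spec"))
  n <- sec$n
  if (n <= 0) stop_domain("loop count n must be positive")
  D <- if (diameter == "outer") sec$D2 else sec$D2 - wire$D1
  if (D <= 0) stop_domain("spring diameter must be positive")
  D1 <- wire$D1; Ew <- wire$Ew; Gw <- wire$Gw; l <- sec$l
  Dcomp  <- GPA_MM2_TO_N * Gw * D1^4 * l / (8 * n * D^3)
  Dshear <- GPA_MM2_TO_N * Ew * D1^4 * l / (8 * n * D^3)
  Dflex  <- GPA_MM2_TO_N * Ew * Gw * D1^4 * l / (16 * n * D * (2 * Gw + Ew))
  structure(list(Dcomp = Dcomp, Dshear = Dshear, Dflex = Dflex,
                 diameter = diameter),
            class = "spring_rigidities")
}

#' Cross-section properties of the coil's beam elements
#'
#' The beam element standing in for the secondary structure is tubular, but
#' the exact section convention behind any particular printed pair of
#' equivalent moduli is ambiguous, so the convention is explicit:
#' \describe{
#'   \item{`ANNULUS_OUTER_D2`}{annulus of wall thickness `D1` with *outer*
#'     diameter `D2` (inner diameter `D2 - 2 D1`)}
#'   \item{`ANNULUS_AROUND_D2`}{annulus of wall thickness `D1` with *inner*
#'     diameter `D2` (outer diameter `D2 + 2 D1`)}
#'   \item{`SOLID_D2`}{solid disc of diameter `D2`}
#' }
#'
#' @param D1 wall thickness / wire diameter (mm)
#' @param D2 reference diameter (mm)
#' @param convention section convention, see Details
#' @param lam Timoshenko shear shape correction factor; approximately 0.5
#'   for a thin tube
#' @return Object of class `beam_section` with `Ab` (mm^2), `Ib` (mm^4),
#'   `J = 2 Ib` (mm^4), `lam`, `convention`.
#' @export
beam_section <- function(D1, D2,
                         convention = c("ANNULUS_AROUND_D2",
                                        "ANNULUS_OUTER_D2", "SOLID_D2"),
                         lam = 0.5) {
  convention <- match.arg(convention)
  if (D1 <= 0 || D2 <= 0) stop_domain("diameters must be positive")
  if (lam <= 0 || lam > 1) stop_domain("lam must lie in (0, 1]")
  if (convention == "ANNULUS_OUTER_D2") {
    if (D2 < 2 * D1)
      stop_domain("degenerate annulus under ANNULUS_OUTER_D2: need D2 >= 2*D1")
    di <- D2 - 2 * D1
    Ab <- pi / 4 * (D2^2 - di^2)
    Ib <- pi / 64 * (D2^4 - di^4)
  } else if (convention == "ANNULUS_AROUND_D2") {
    do <- D2 + 2 * D1
    Ab <- pi / 4 * (do^2 - D2^2)
    Ib <- pi / 64 * (do^4 - D2^4)
  } else {
    Ab <- pi / 4 * D2^2
    Ib <- pi / 64 * D2^4
  }
  structure(list(convention = convention, Ab = Ab, Ib = Ib, J = 2 * Ib,
                 lam = lam),
            class = "beam_section")
}

#' Equivalent elastic moduli of the coil's beam elements
#'
#' Equates beam rigidity to spring rigidity:
#' \deqn{E_b A_b = D_{compressive}} (axial calibration),
#' \deqn{\lambda G_b A_b = D_{shearing}} (shear calibration),
#' \deqn{E_b I_b = D_{flexural}} (flexural calibration).
#'
#' The axial and flexural equations overdetermine `Eb` for any fixed
#' section; the configured `calibration` selects which value is carried as
#' the primary `Eb` (default: flexural, because looping of a deployed coil
#' is bending-dominated).  Both candidates are always recorded.  The shear
#' modulus `Gb` is computed from the shear equation with the (possibly
#' different) section passed as `shear_section`.
#'
#' @param rig a [spring_rigidities()]
#' @param section a [beam_section()] used for the axial/flexural equations
#' @param calibration `"flexural"` (default) or `"axial"`: which equation
#'   supplies the primary `Eb`
#' @param shear_section optional [beam_section()] used for the shear
#'   equation; defaults to `section`
#' @return Object of class `equivalent_material` with `Eb`, `Gb` (GPa),
#'   `Eb_axial`, `Eb_flex`, `source`, and the sections used.
#' @export
equivalent_moduli <- function(rig, section,
                              calibration = c("flexural", "axial"),
                              shear_section = section) {
  calibration <- match.arg(calibration)
  stopifnot(inherits(rig, "spring_rigidities"),
            inherits(section, "beam_section"))
  Eb_axial <- rig$Dcomp / section$Ab / GPA_MM2_TO_N
  Eb_flex  <- rig$Dflex / section$Ib / GPA_MM2_TO_N
  Gb <- rig$Dshear / (shear_section$lam * shear_section$Ab) / GPA_MM2_TO_N
  Eb <- if (calibration == "flexural") Eb_flex else Eb_axial
  structure(list(Eb = Eb, Gb = Gb,
                 Eb_axial = Eb_axial, Eb_flex = Eb_flex,
                 source = c(Eb = calibration, Gb = "shear"),
                 section = section, shear_section = shear_section),
            class = "equivalent_material")
}

#' Effective density of the coil's beam elements
#'
#' The beam replaces the wound wire, so its density is chosen to conserve
#' mass per unit coil length.  Under tight winding the pitch is `D1` and one
#' helix turn of the wire (at mean diameter `D2 - D1`) has length
#' `sqrt((pi (D2 - D1))^2 + D1^2)`, giving a wire length per unit coil
#' length of `sqrt((pi (D2 - D1) / D1)^2 + 1)`; for realistic coils this is
#' within 0.01% of `pi (D2 - D1) / D1` and the simpler ratio is used.
#'
#' @inheritParams spring_rigidities
#' @param section the [beam_section()] whose area normalizes the mass
#' @return Object of class `effective_density` with `rho_eff` (mg/mm^3) and
#'   `mass_per_length` (mg/mm).
#' @export
effective_density <- function(wire, sec, section) {
  stopifnot(inherits(wire, "wire_spec"), inherits(sec, "secondary_spec"),
            inherits(section, "beam_section"))
  pitch <- D1 <- wire$D1
  wire_per_coil <- pi * (sec$D2 - D1) / pitch
  mass_per_length <- wire$rho_w * (pi / 4 * D1^2) * wire_per_coil
  structure(list(rho_eff = mass_per_length / section$Ab,
                 mass_per_length = mass_per_length),
            class = "effective_density")
}

#' Full beam-property bundle for a coil
#'
#' Convenience wrapper running the whole chain: tight-winding loop count,
#' spring rigidities, beam sections under the calibrated conventions,
#' equivalent moduli and effective density.  The default conventions are
#' the package's calibration: flexural `Eb` on an `ANNULUS_AROUND_D2`
#' section, `Gb` on a `SOLID_D2` section with `lam = 0.75`.  See the
#' methods vignette for why the conventions differ.
#'
#' @param D1,D2 wire and coil diameters (mm)
#' @param l coil length (mm)
#' @param Ew,Gw wire moduli (GPa)
#' @param rho_w wire density (mg/mm^3)
#' @param flex_convention section convention for the flexural/axial
#'   equations
#' @param shear_convention,shear_lam section convention and shape factor
#'   for the shear equation
#' @param calibration which equation supplies `Eb` (see
#'   [equivalent_moduli()])
#' @return Object of class `coil_beam_properties` bundling all
#'   intermediates.
#' @export
coil_beam_properties <- function(D1, D2, l, Ew = 230, Gw = 82,
                                 rho_w = 21.45,
                                 flex_convention = "ANNULUS_AROUND_D2",
                                 shear_convention = "SOLID_D2",
                                 shear_lam = 0.75,
                                 calibration = "flexural") {
  wire <- wire_spec(D1, Ew, Gw, rho_w)
  sec <- secondary_spec(D2, l, wire = wire)
  rig <- spring_rigidities(wire, sec)
  section <- beam_section(D1, D2, flex_convention)
  shear_sec <- beam_section(D1, D2, shear_convention, lam = shear_lam)
  mat <- equivalent_moduli(rig, section, calibration, shear_sec)
  dens <- effective_density(wire, sec, section)
  structure(list(wire = wire, secondary = sec, rigidities = rig,
                 section = section, shear_section = shear_sec,
                 material = mat, density = dens),
            class = "coil_beam_properties")
}

#' @export
print.coil_beam_properties <- function(x, ...) {
  cat("Coil beam properties (helical-spring equivalent)\n")
  cat(sprintf("  wire:      D1 = %.4f mm, Ew = %g GPa, Gw = %g GPa\n",
              x$wire$D1, x$wire$Ew, x$wire$Gw))
  cat(sprintf("  secondary: D2 = %.4f mm, l = %g mm, n = %.1f loops\n",
              x$secondary$D2, x$secondary$l, x$secondary$n))
  cat(sprintf("  rigidities: Dcomp = %.4e N, Dshear = %.4e N, Dflex = %.4e N*mm^2\n",
              x$rigidities$Dcomp, x$rigidities$Dshear, x$rigidities$Dflex))
  cat(sprintf("  section (%s): Ab = %.4e mm^2, Ib = %.4e mm^4\n",
              x$section$convention, x$section$Ab, x$section$Ib))
  cat(sprintf("  equivalent moduli: Eb = %.3e GPa (%s), Gb = %.3e GPa\n",
              x$material$Eb, x$material$source[["Eb"]], x$material$Gb))
  cat(sprintf("    candidates: Eb_axial = %.3e GPa, Eb_flex = %.3e GPa\n",
              x$material$Eb_axial, x$material$Eb_flex))
  cat(sprintf("  effective density: %.3f mg/mm^3 (%.3f mg/mm)\n",
              x$density$rho_eff, x$density$mass_per_length))
  invisible(x)
}

#' Read a coil specification file
#'
#' Reads a YAML or JSON coil specification with keys `d1_mm`, `d2_mm`,
#' `d3_mm`, `length_cm`, `E_wire_gpa`, `G_wire_gpa`, `rho_wire`,
#' `section_convention`, `lambda` (missing keys fall back to the Axium bare
#' platinum defaults) and returns the parsed `coil_spec`.
#'
#' @param path file path (`.yaml`, `.yml`, or `.json`)
#' @return Object of class `coil_spec` with fields `D1`, `D2`, `D3` (mm),
#'   `l` (mm), `Ew`, `Gw` (GPa), `rho_w`, plus section configuration.
#' @export
read_coil_spec <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  coil_spec(
    D1 = raw$d1_mm %||% 0.0381,
    D2 = raw$d2_mm %||% 0.2921,
    D3 = raw$d3_mm %||% stop_domain("coil spec needs d3_mm"),
    l = (raw$length_cm %||% stop_domain("coil spec needs length_cm")) * 10,
    Ew = raw$E_wire_gpa %||% 230,
    Gw = raw$G_wire_gpa %||% 82,
    rho_w = raw$rho_wire %||% 21.45,
    flex_convention = raw$section_convention %||% "ANNULUS_AROUND_D2",
    shear_lam = raw$lambda %||% 0.75
  )
}

#' Construct a coil specification
#'
#' @param D1,D2,D3 primary, secondary and tertiary diameters (mm)
#' @param l coil length (mm)
#' @param Ew,Gw,rho_w wire material
#' @param flex_convention,shear_convention,shear_lam,calibration section
#'   calibration, see [coil_beam_properties()]
#' @return Object of class `coil_spec`.
#' @export
coil_spec <- function(D1 = 0.0381, D2 = 0.2921, D3, l,
                      Ew = 230, Gw = 82, rho_w = 21.45,
                      flex_convention = "ANNULUS_AROUND_D2",
                      shear_convention = "SOLID_D2",
                      shear_lam = 0.75, calibration = "flexural") {
  if (D3 <= D2) stop_domain("tertiary diameter D3 must exceed D2")
  structure(list(D1 = D1, D2 = D2, D3 = D3, l = l, Ew = Ew, Gw = Gw,
                 rho_w = rho_w, flex_convention = flex_convention,
                 shear_convention = shear_convention,
                 shear_lam = shear_lam, calibration = calibration),
            class = "coil_spec")
}
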