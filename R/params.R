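# Kinetic parameters and the three reaction fluxes of the reduced metabolic
# model. Canonical unit system throughout the package: um, ms, mM, mV.
# 1 mM = 602,214 molecules/um^3; flux densities are molecules/ms/um^2 of
# membrane.

#' @keywords internal
.FARADAY <- 96485.33212   # C/mol
#' @keywords internal
.RGAS <- 8.31446262       # J/mol/K
#' @keywords internal
.MOLEC_PER_UM3_PER_MM <- 602214  # molecules per um^3 per mM

#' Thermal voltage RT/F in millivolts
#' @param T temperature (K)
#' @return RT/F in mV
#' @keywords internal
.rt_over_f_mV <- function(T) 1000 * .RGAS * T / .FARADAY

#' Kinetic parameter set for the reduced ADP/ATP handling model
#'
#' Bundles every rate constant, binding constant, potential, ionic fraction
#' and diffusivity used by the reduced metabolic model: the adenine
#' nucleotide translocase (ANT) flux, the F1F0-ATP synthase (AS) flux, and
#' the surrogate kinase that cycles ATP/ADP outside the matrix.
#'
#' Printed model constants (membrane potential 172 mV, effective-potential
#' fraction 0.5, kinase rates 0.009 /ms and 1 /mM/ms) are the defaults.
#' Constants that the source model does not print (maximum velocities,
#' binding constants, phosphate, matrix calcium, diffusivities) default to
#' the calibrated set obtained with [calibrate()] against the documented
#' anchors (no-crista maximum synthase flux ~100 molecules/ms/um^2; matrix
#' ADP spanning ~0.18-0.37 mM over the standard condition grid; fitted
#' gradient-steepness k spanning ~1-3.7 /um). See the package vignette.
#'
#' @param V_ANT maximum translocase velocity (molecules/ms/um^2)
#' @param V_AS maximum synthase velocity (molecules/ms/um^2)
#' @param K_ADP,K_ATP,K_Pi synthase binding constants (mM)
#' @param K_Ca_ATP calcium activation constant of the synthase (mM)
#' @param K_V_ATP membrane potential of half-maximal ATP production (mV)
#' @param psi_m inner-membrane electrical potential (mV), held fixed
#' @param f_P fraction of the membrane potential effective for the
#'   translocase (dimensionless, in `[0, 1]`)
#' @param T temperature (K); sets the thermal voltage RT/F
#' @param f_ADP3_m,f_ADP3_e,f_ATP4_m,f_ATP4_e ionic fractions: the fraction
#'   of total ADP (ATP) present as ADP3- (ATP4-) in the matrix (`_m`) and in
#'   the external compartment (`_e`); in `(0, 1]`
#' @param Pi_m matrix phosphate (mM, constant)
#' @param Pi_e external phosphate (mM, constant). `NA` (the default) means
#'   "equilibrium": at solve time Pi_e is set to
#'   `k_f * ATP_cyt / (k_r * ADP_cyt)` so the surrogate kinase is exactly at
#'   equilibrium at the boundary composition.
#' @param Ca_m matrix free calcium (mM, constant)
#' @param k_f kinase forward rate (1/ms)
#' @param k_r kinase reverse rate (1/mM/ms)
#' @param D_ADP,D_ATP diffusivities of total ADP/ATP in the external
#'   compartment (um^2/ms)
#' @param as_denominator grouping of the synthase denominator:
#'   `"grouped"` uses `(1 + ADP/K_ADP)(1 + Pi/K_Pi) + ATP/K_ATP`;
#'   `"flat"` uses `1 + ADP/K_ADP + Pi/K_Pi + ATP/K_ATP`.
#' @return an object of class `kinetic_params` (a validated named list)
#' @examples
#' p <- kinetic_params()
#' ant_flux(solute_state(0.72, 0.44, 0.037, 4.0), p)
#' @export
kinetic_params <- function(V_ANT = 574,
                           V_AS = 298,
                           K_ADP = 0.071,
                           K_ATP = 24,
                           K_Pi = 2.0,
                           K_Ca_ATP = 0.165,
                           K_V_ATP = 131,
                           psi_m = 172,
                           f_P = 0.5,
                           T = 310,
                           f_ADP3_m = 1, f_ADP3_e = 1,
                           f_ATP4_m = 1, f_ATP4_e = 1,
                           Pi_m = 2.0,
                           Pi_e = NA_real_,
                           Ca_m = 0.4,
                           k_f = 0.009,
                           k_r = 1.0,
                           D_ADP = 0.028,
                           D_ATP = 0.028,
                           as_denominator = c("grouped", "flat")) {
  as_denominator <- match.arg(as_denominator)
  p <- list(V_ANT = V_ANT, V_AS = V_AS, K_ADP = K_ADP, K_ATP = K_ATP,
            K_Pi = K_Pi, K_Ca_ATP = K_Ca_ATP, K_V_ATP = K_V_ATP,
            psi_m = psi_m, f_P = f_P, T = T,
            f_ADP3_m = f_ADP3_m, f_ADP3_e = f_ADP3_e,
            f_ATP4_m = f_ATP4_m, f_ATP4_e = f_ATP4_e,
            Pi_m = Pi_m, Pi_e = Pi_e, Ca_m = Ca_m,
            k_f = k_f, k_r = k_r, D_ADP = D_ADP, D_ATP = D_ATP,
            as_denominator = as_denominator)
  class(p) <- "kinetic_params"
  validate_params(p)
  p
}

#' @keywords internal
validate_params <- function(p) {
  pos <- c("V_ANT", "V_AS", "K_ADP", "K_ATP", "K_Pi", "K_Ca_ATP", "K_V_ATP",
           "T", "Pi_m", "Ca_m", "k_f", "k_r", "D_ADP", "D_ATP")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("kinetic_params: '", nm, "' must be a positive finite number",
           call. = FALSE)
  }
  if (!is.na(p$Pi_e) && p$Pi_e <= 0)
    stop("kinetic_params: 'Pi_e' must be positive (or NA for equilibrium)",
         call. = FALSE)
  if (p$f_P < 0 || p$f_P > 1)
    stop("kinetic_params: 'f_P' must lie in [0, 1]", call. = FALSE)
  if (p$psi_m < 0)
    stop("kinetic_params: 'psi_m' must be >= 0", call. = FALSE)
  for (nm in c("f_ADP3_m", "f_ADP3_e", "f_ATP4_m", "f_ATP4_e")) {
    v <- p[[nm]]
    if (v <= 0 || v > 1)
      stop("kinetic_params: ionic fraction '", nm, "' must lie in (0, 1]",
           call. = FALSE)
  }
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameter set (reduced ADP/ATP model)\n")
  cat(sprintf("  V_ANT = %g, V_AS = %g molecules/ms/um^2\n", x$V_ANT, x$V_AS))
  cat(sprintf("  psi_m = %g mV (RT/F = %.3f mV), f_P = %g\n",
              x$psi_m, .rt_over_f_mV(x$T), x$f_P))
  cat(sprintf("  K_ADP = %g, K_ATP = %g, K_Pi = %g mM; K_V = %g mV; K_Ca = %g mM\n",
              x$K_ADP, x$K_ATP, x$K_Pi, x$K_V_ATP, x$K_Ca_ATP))
  cat(sprintf("  Pi_m = %g mM, Pi_e = %s, Ca_m = %g mM\n", x$Pi_m,
              if (is.na(x$Pi_e)) "equilibrium" else paste0(x$Pi_e, " mM"),
              x$Ca_m))
  cat(sprintf("  kinase k_f = %g /ms, k_r = %g /mM/ms\n", x$k_f, x$k_r))
  cat(sprintf("  D_ADP = %g, D_ATP = %g um^2/ms; AS denominator: %s\n",
              x$D_ADP, x$D_ATP, x$as_denominator))
  invisible(x)
}

#' Solute state of the reduced model
#'
#' Total ADP/ATP concentrations in the well-mixed matrix pool (`_m`) and in
#' the external compartment (intracristal space / cytosol, `_e`). External
#' entries may be vectors (one value per spatial node).
#'
#' @param ADP_m,ATP_m matrix totals (mM, scalars)
#' @param ADP_e,ATP_e external totals (mM, scalar or vector)
#' @return an object of class `solute_state`
#' @export
solute_state <- function(ADP_m, ATP_m, ADP_e, ATP_e) {
  if (any(c(ADP_m, ATP_m, ADP_e, ATP_e) < 0))
    stop("solute_state: concentrations must be >= 0", call. = FALSE)
  structure(list(ADP_m = ADP_m, ATP_m = ATP_m,
                 ADP_e = ADP_e, ATP_e = ATP_e),
            class = "solute_state")
}

# Vectorized ANT core; ade/ate may be vectors, adm/atm scalars.
#' @keywords internal
.ant_flux_core <- function(ade, ate, adm, atm, p, deriv = FALSE) {
  a_e <- p$f_ADP3_e * ade
  t_e <- p$f_ATP4_e * ate
  a_m <- p$f_ADP3_m * adm
  t_m <- p$f_ATP4_m * atm
  u <- p$psi_m / .rt_over_f_mV(p$T)
  E1 <- exp(-u)
  E2 <- exp(-p$f_P * u)
  g <- t_e / a_e           # external ATP4-/ADP3- ratio
  rho <- a_m / t_m         # matrix ADP3-/ATP4- ratio
  num <- 1 - g * rho * E1
  den <- (1 + g * E2) * (1 + rho)
  J <- p$V_ANT * num / den
  if (!deriv) return(J)
  # dJ/dg, then chain to external totals (g ~ ATP_e/ADP_e)
  dJdg <- -p$V_ANT * (rho * E1 * (1 + g * E2) + num * E2) /
    ((1 + g * E2)^2 * (1 + rho))
  list(J = J,
       dJ_dADPe = dJdg * (-g / ade),   # >= 0
       dJ_dATPe = dJdg * (g / ate))    # <= 0
}

#' Adenine nucleotide translocase flux density
#'
#' Electrogenic 1:1 ADP(in)/ATP(out) exchange flux across the inner
#' membrane. Positive sign means forward exchange: external ADP into the
#' matrix, matrix ATP out. The ionic species entering the rate law are
#' fixed fractions of the totals in `state`.
#'
#' @param state a [solute_state()]; external entries may be vectors
#' @param p a [kinetic_params()]
#' @return flux density (molecules/ms/um^2), same length as the external
#'   entries of `state`
#' @export
ant_flux <- function(state, p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (any(state$ADP_e <= 0))
    stop("ant_flux: external ADP ([ADP3-]e) appears in a denominator and must be > 0",
         call. = FALSE)
  if (any(state$ATP_m <= 0))
    stop("ant_flux: matrix ATP ([ATP4-]m) appears in a denominator and must be > 0",
         call. = FALSE)
  .ant_flux_core(state$ADP_e, state$ATP_e, state$ADP_m, state$ATP_m, p)
}

#' F1F0-ATP synthase flux density
#'
#' Phosphorylation of matrix ADP driven by the membrane potential, with a
#' Hill-type potential activation (exponent 8) and saturating calcium
#' activation. Positive sign means net ATP synthesis (matrix ADP + Pi ->
#' matrix ATP).
#'
#' @inheritParams ant_flux
#' @return flux density (molecules/ms/um^2)
#' @export
as_flux <- function(state, p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (any(c(state$ADP_m, state$ATP_m) < 0))
    stop("as_flux: negative matrix concentrations", call. = FALSE)
  .as_flux_core(state$ADP_m, state$ATP_m, p)
}

#' @keywords internal
.as_flux_core <- function(adm, atm, p) {
  num <- (adm / p$K_ADP) * (p$Pi_m / p$K_Pi) - atm / p$K_ATP
  den <- if (p$as_denominator == "grouped")
    (1 + adm / p$K_ADP) * (1 + p$Pi_m / p$K_Pi) + atm / p$K_ATP
  else
    1 + adm / p$K_ADP + p$Pi_m / p$K_Pi + atm / p$K_ATP
  vfac <- p$psi_m^8 / (p$K_V_ATP^8 + p$psi_m^8)
  cafac <- 1 - exp(-p$Ca_m / p$K_Ca_ATP)
  p$V_AS * num / den * vfac * cafac
}

#' Surrogate kinase rate
#'
#' Mass-action ATP <-> ADP cycling outside the matrix, standing in for
#' adenylate/creatine kinase activity. Positive sign converts external ATP
#' to external ADP.
#'
#' @param ATP_e,ADP_e external totals (mM; scalar or vector)
#' @param Pi_e external phosphate (mM)
#' @param p a [kinetic_params()] (supplies `k_f`, `k_r`)
#' @return volumetric rate (mM/ms)
#' @export
surrogate_kinase_rate <- function(ATP_e, ADP_e, Pi_e, p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (any(c(ATP_e, ADP_e, Pi_e) < 0))
    stop("surrogate_kinase_rate: concentrations must be >= 0", call. = FALSE)
  p$k_f * ATP_e - p$k_r * ADP_e * Pi_e
}

#' Convert a cellular ATP turnover rate to a membrane flux density
#'
#' Converts a whole-cell volumetric rate (mM ATP per second per liter of
#' cells) into a flux density per unit inner-membrane area, given the
#' mitochondrial volume fraction of the cell and the inner-membrane
#' surface-to-volume ratio.
#'
#' @param rate volumetric rate (mM/s per liter of cells)
#' @param mito_vol_frac mitochondrial volume fraction of the cell (0-1)
#' @param sv_ratio inner-membrane surface-to-volume ratio (um^2 per um^3 of
#'   mitochondrion)
#' @return flux density (molecules/ms/um^2)
#' @examples
#' convert_cell_rate_to_area_flux(1.3, 0.30, 37)  # ~70
#' @export
convert_cell_rate_to_area_flux <- function(rate, mito_vol_frac, sv_ratio) {
  if (rate < 0) stop("convert_cell_rate_to_area_flux: rate must be >= 0",
                     call. = FALSE)
  if (mito_vol_frac <= 0 || sv_ratio <= 0)
    stop("convert_cell_rate_to_area_flux: volume fraction and S/V ratio must be > 0",
         call. = FALSE)
  # mM/s per cell volume -> molecules/um^3/ms per mito volume -> per um^2 IM
  rate * .MOLEC_PER_UM3_PER_MM / 1000 / (mito_vol_frac * sv_ratio)
}

#' Effective external phosphate for the surrogate kinase
#'
#' Resolves `Pi_e`: a fixed value if the parameter set carries one, else the
#' equilibrium value `k_f * ATP_cyt / (k_r * ADP_cyt)` at the boundary
#' composition.
#' @keywords internal
.resolve_Pi_e <- function(p, bc) {
  if (!is.na(p$Pi_e)) p$Pi_e else p$k_f * bc$ATP_cyt / (p$k_r * bc$ADP_cyt)
}

#' Read / write a kinetic parameter set as annotated YAML
#'
#' The YAML carries every parameter with its unit and a provenance tag
#' (`printed` for values stated in the literature source of the model,
#' `calibrated` for values fixed by the calibration protocol).
#'
#' @param p a [kinetic_params()]
#' @param path file path
#' @param provenance optional named character vector of provenance tags
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   [kinetic_params()] with a `provenance` attribute.
#' @export
write_params <- function(p, path, provenance = NULL) {
  stopifnot(inherits(p, "kinetic_params"))
  units <- c(V_ANT = "molecules/ms/um^2", V_AS = "molecules/ms/um^2",
             K_ADP = "mM", K_ATP = "mM", K_Pi = "mM", K_Ca_ATP = "mM",
             K_V_ATP = "mV", psi_m = "mV", f_P = "dimensionless", T = "K",
             f_ADP3_m = "dimensionless", f_ADP3_e = "dimensionless",
             f_ATP4_m = "dimensionless", f_ATP4_e = "dimensionless",
             Pi_m = "mM", Pi_e = "mM", Ca_m = "mM",
             k_f = "1/ms", k_r = "1/mM/ms",
             D_ADP = "um^2/ms", D_ATP = "um^2/ms",
             as_denominator = "choice")
  out <- list()
  for (nm in names(units)) {
    ent <- list(value = p[[nm]], unit = units[[nm]])
    if (!is.null(provenance) && nm %in% names(provenance))
      ent$provenance <- unname(provenance[[nm]])
    out[[nm]] <- ent
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  vals <- lapply(raw, function(e) if (is.list(e)) e$value else e)
  vals <- vals[names(vals) %in% names(formals(kinetic_params))]
  if (!is.null(vals$Pi_e) && (is.null(vals$Pi_e) || identical(vals$Pi_e, "equilibrium")))
    vals$Pi_e <- NA_real_
  if (!is.null(vals$Pi_e) && is.character(vals$Pi_e)) vals$Pi_e <- NA_real_
  p <- do.call(kinetic_params, vals)
  prov <- vapply(raw, function(e)
    if (is.list(e) && !is.null(e$provenance)) e$provenance else NA_character_,
    character(1))
  attr(p, "provenance") <- prov
  p
}

#' The bundled calibrated parameter set
#'
#' Returns the parameter set shipped with the package
#' (`inst/extdata/params-calibrated-2025.yaml`): printed constants plus the
#' calibrated values for the unprinted ones (see [calibrate()] and the
#' vignette).
#'
#' @return a [kinetic_params()]
#' @export
default_params <- function() {
  path <- system.file("extdata", "params-calibrated-2025.yaml",
                      package = "cristaflux")
  if (nzchar(path)) read_params(path) else kinetic_params()
}
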