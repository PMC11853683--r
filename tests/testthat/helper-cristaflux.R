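# Shared fixtures: small, fast parameter sets and models for unit tests.
# Tests that exercise solver behavior use coarse grids (h = 4 nm) and short
# cristae; the acceptance suite runs the production resolutions.

# A light, uncalibrated parameter set (unit ionic fractions) for tests of
# mechanics rather than calibrated physiology.
test_params <- function(...) {
  args <- utils::modifyList(
    list(V_ANT = 500, V_AS = 400, K_ADP = 0.15, K_ATP = 8,
         f_ADP3_m = 1, f_ADP3_e = 1, f_ATP4_m = 1, f_ATP4_e = 1,
         D_ADP = 0.1, D_ATP = 0.1),
    list(...))
  do.call(kinetic_params, args)
}

# Construct an adp_profile object directly from vectors (for fit/quadrature
# tests that need exact synthetic profiles).
synthetic_profile <- function(x, adp, L = max(x) + x[1], cj = "both_ends") {
  structure(list(x = x, adp = adp, ADP0 = adp[1], L = L,
                 crista = 1L, cj = cj),
            class = "adp_profile")
}

# A hand-built flux_curves object with known analytic curves, for census
# scoring tests that must not depend on 3-D solves.
fake_curves <- function() {
  Ls <- c(0.1, 0.5, 1.0, 1.5)
  mk <- function(vals) stats::splinefun(Ls, vals, method = "monoH.FC")
  tabs <- list(
    no_cj = c(0.60, 0.60, 0.60, 0.60),
    one_narrow = c(0.92, 0.78, 0.66, 0.62),
    one_wide = c(0.97, 0.90, 0.80, 0.74))
  tab <- do.call(rbind, lapply(names(tabs), function(cl)
    data.frame(class = cl, L = Ls, j_rel = tabs[[cl]])))
  structure(list(table = tab,
                 funs = lapply(tabs, mk),
                 ranges = lapply(tabs, function(v) range(Ls)),
                 J_MAX = 100, bc = boundary_conditions(0.037)),
            class = "flux_curves")
}
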