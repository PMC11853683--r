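# Flux decomposition, diffusion penalty, speed zones, flux-versus-length
# curves, and census-based whole-mitochondrion scoring.

#' Diffusion penalty
#'
#' Fractional reduction of ATP synthase flux relative to the flux in the
#' absence of cristae (`J_max`), caused by restricted intracristal ADP
#' diffusion.
#'
#' @param J_model model flux
#' @param J_max flux of the matching no-crista model
#' @return `(J_max - J_model) / J_max`
#' @export
diffusion_penalty <- function(J_model, J_max) {
  if (any(J_max <= 0)) stop("diffusion_penalty: J_max must be > 0",
                            call. = FALSE)
  (J_max - J_model) / J_max
}

#' Decompose a model flux into its crista-membrane contribution
#'
#' Splits the per-area steady flux of a model into IBM and crista
#' contributions using the surface-area ledger: with the IBM operating at
#' `J_max`, the topology-dependent crista contribution is
#' `J_CRIS = (S_IM/S_CRIS) J_model - (S_IBM/S_CRIS) J_max`.
#'
#' @param J_model per-area model flux
#' @param J_max per-area no-crista flux
#' @param ledger list with `S_IBM`, `S_CRIS`, `S_IM` (from
#'   [surface_ledger()])
#' @return per-area crista-membrane flux `J_CRIS`
#' @export
decompose_flux <- function(J_model, J_max, ledger) {
  if (ledger$S_CRIS <= 0)
    stop("decompose_flux: S_CRIS = 0 (use the no-crista baseline instead)",
         call. = FALSE)
  (ledger$S_IM / ledger$S_CRIS) * J_model -
    (ledger$S_IBM / ledger$S_CRIS) * J_max
}

#' @rdname decompose_flux
#' @param J_cris per-area crista-membrane flux
#' @export
recompose_flux <- function(J_cris, J_max, ledger) {
  (ledger$S_IBM / ledger$S_IM) * J_max +
    (ledger$S_CRIS / ledger$S_IM) * J_cris
}

#' IBM correction of a crista-only relative flux
#'
#' Adds the inner-boundary-membrane contribution (unaffected by intracristal
#' diffusion, so operating at relative flux 1) to a crista-only relative
#' flux: `s * j + (1 - s)`, where `s` is the crista fraction of the IM
#' surface area.
#'
#' @param j_rel_cris crista-only relative flux (J/J_MAX, in `[0, 1]`)
#' @param s_cris_frac crista membrane fraction of total IM area (in `[0, 1]`)
#' @return whole-membrane relative flux
#' @examples
#' ibm_correction(0.70, 0.92)  # 0.72 at the printed precision
#' @export
ibm_correction <- function(j_rel_cris, s_cris_frac) {
  if (any(j_rel_cris < 0 | j_rel_cris > 1) ||
      any(s_cris_frac < 0 | s_cris_frac > 1))
    stop("ibm_correction: inputs must lie in [0, 1]", call. = FALSE)
  s_cris_frac * j_rel_cris + (1 - s_cris_frac)
}

#' Speed-zone classification of a relative flux
#'
#' `fast` for `j >= 0.9`, `moderate` for `0.75 <= j < 0.9`, `slow` for
#' `j < 0.75` (boundaries closed below).
#'
#' @param j_rel relative flux J/J_MAX in `[0, 1]` (vectorized)
#' @return character vector in `{"fast", "moderate", "slow"}`
#' @export
speed_zone <- function(j_rel) {
  if (any(j_rel < 0 | j_rel > 1))
    stop("speed_zone: relative flux must lie in [0, 1]", call. = FALSE)
  ifelse(j_rel >= 0.9, "fast", ifelse(j_rel >= 0.75, "moderate", "slow"))
}

#' Build flux-versus-length curves from 3-D lamellar simulations
#'
#' Runs 3-D steady-state simulations for detached (`no_cj`), one-narrow-CJ
#' and one-wide-CJ lamellar cristae over a set of lengths, decomposes each
#' flux into its crista contribution (see [decompose_flux()]) relative to
#' the no-crista maximum, and attaches monotone shape-preserving
#' interpolants. Two-CJ (trans) classes are synthesized by the Rule of 2:
#' the two-CJ curve at length `L` equals the one-CJ curve at `L/2`, so the
#' one-CJ classes are additionally sampled at the half-lengths.
#'
#' @param lengths crista lengths to sample (um)
#' @param p a [kinetic_params()]
#' @param bc a [boundary_conditions()]; the reference workload is
#'   `ADP_cyt = 0.037` mM
#' @param classes topology classes to include
#' @param h 3-D grid spacing (um)
#' @return object of class `flux_curves`: sampled `(L, J/J_MAX)` per class
#'   plus interpolants; evaluate with [flux_curve_value()] or `predict()`
#' @export
build_flux_curves <- function(lengths = c(0.15, 0.45, 0.9),
                              p = default_params(),
                              bc = boundary_conditions(0.037),
                              classes = c("no_cj", "one_narrow", "one_wide",
                                          "two_narrow", "two_wide"),
                              h = 0.005) {
  classes <- match.arg(classes, several.ok = TRUE)
  base0 <- build_lamellar_3d(0, "none", h = h)
  st0 <- solve_steady_state(base0, p, bc)
  J_MAX <- st0$J_AS

  need_half <- any(c("two_narrow", "two_wide") %in% classes)
  one_lengths <- sort(unique(c(lengths, if (need_half) lengths / 2)))
  base_classes <- intersect(c("no_cj", "one_narrow", "one_wide"),
    unique(c(classes,
             if ("two_narrow" %in% classes) "one_narrow",
             if ("two_wide" %in% classes) "one_wide")))

  solve_class <- function(cls, Ls) {
    mode <- switch(cls, no_cj = "none", one_narrow = "narrow",
                   one_wide = "wide")
    vapply(Ls, function(L) {
      mod <- build_lamellar_3d(L, mode, h = h)
      st <- solve_steady_state(mod, p, bc)
      jc <- decompose_flux(st$J_AS, J_MAX, st$S)
      min(max(jc / J_MAX, 1e-6), 1)
    }, numeric(1))
  }

  tab <- list()
  for (cls in base_classes) {
    Ls <- if (cls == "no_cj") sort(unique(lengths)) else one_lengths
    tab[[cls]] <- data.frame(class = cls, L = Ls, j_rel = solve_class(cls, Ls))
  }
  for (cls in intersect(c("two_narrow", "two_wide"), classes)) {
    src <- tab[[sub("two", "one", cls)]]
    Ls <- sort(unique(lengths))
    j <- stats::approx(src$L, src$j_rel, xout = Ls / 2, rule = 2)$y
    tab[[cls]] <- data.frame(class = cls, L = Ls, j_rel = j)
  }
  tab <- tab[intersect(c("no_cj", "one_narrow", "one_wide",
                         "two_narrow", "two_wide"), names(tab))]
  df <- do.call(rbind, tab)
  rownames(df) <- NULL
  funs <- lapply(tab, function(d) {
    if (nrow(d) >= 3L)
      stats::splinefun(d$L, d$j_rel, method = "monoH.FC")
    else
      stats::approxfun(d$L, d$j_rel, rule = 2)
  })
  structure(list(table = df, funs = funs, ranges = lapply(tab, function(d)
    range(d$L)), J_MAX = J_MAX, bc = bc),
    class = "flux_curves")
}

#' Evaluate a flux-versus-length curve
#'
#' Lengths outside the sampled range are flat-clamped to the nearest
#' sampled endpoint.
#'
#' @param curves a `flux_curves` object
#' @param class topology class name
#' @param L crista length(s) (um)
#' @return relative flux J/J_MAX
#' @export
flux_curve_value <- function(curves, class, L) {
  stopifnot(inherits(curves, "flux_curves"))
  f <- curves$funs[[class]]
  if (is.null(f))
    stop("flux_curve_value: unknown topology class '", class, "'",
         call. = FALSE)
  r <- curves$ranges[[class]]
  pmin(pmax(f(pmin(pmax(L, r[1]), r[2])), 0), 1)
}

#' @export
predict.flux_curves <- function(object, class, L, ...) {
  flux_curve_value(object, class, L)
}

#' @export
print.flux_curves <- function(x, ...) {
  cat("Flux-versus-length curves (J/J_MAX vs L_CRIS)\n")
  cat(sprintf("  J_MAX = %.3f molecules/ms/um^2 at ADP_cyt = %g mM\n",
              x$J_MAX, x$bc$ADP_cyt))
  print(stats::reshape(x$table, idvar = "L", timevar = "class",
                       direction = "wide"), row.names = FALSE)
  invisible(x)
}

#' @export
plot.flux_curves <- function(x, ...) {
  Ls <- seq(min(x$table$L), max(x$table$L), length.out = 100)
  graphics::plot(NULL, xlim = range(Ls), ylim = c(0, 1),
                 xlab = "L_CRIS (um)", ylab = "J/J_MAX", ...)
  graphics::rect(min(Ls), 0.9, max(Ls), 1, col = "#ccffcc", border = NA)
  graphics::rect(min(Ls), 0.75, max(Ls), 0.9, col = "#ffffcc", border = NA)
  graphics::rect(min(Ls), 0, max(Ls), 0.75, col = "#ffcccc", border = NA)
  cls <- names(x$funs)
  for (i in seq_along(cls))
    graphics::lines(Ls, flux_curve_value(x, cls[i], Ls), col = i, lwd = 2,
                    lty = if (grepl("^two", cls[i])) 2 else 1)
  graphics::legend("bottomleft", legend = cls, col = seq_along(cls),
                   lwd = 2, bg = "white")
  invisible(x)
}

#' Whole-mitochondrion relative flux from a crista census
#'
#' Weighted sum of per-crista relative fluxes: each crista is mapped to a
#' flux-versus-length curve by its CJ connectivity (`cj_ends`: cristae with
#' CJs at both ends are scored by the Rule-of-2 transformed curve, i.e. the
#' one-CJ curve at half length; one-end cristae use the one-CJ curve at
#' full length; detached cristae use the no-CJ curve) and CJ width class
#' (`class`: `"narrow"` or `"wide"`; `"detached"` forces the no-CJ curve).
#' Weights are relative summed segment lengths (`seg_length_total_um` if
#' present, else `length_um`).
#'
#' @param census a `crista_census` data frame (see [read_census()])
#' @param curves a `flux_curves` object
#' @return relative flux J/J_MAX (scalar), with the per-crista breakdown in
#'   attribute `"per_crista"`
#' @export
census_score <- function(census, curves) {
  census <- validate_census(census)
  if (nrow(census) == 0L)
    stop("census_score: empty census", call. = FALSE)
  seg <- if ("seg_length_total_um" %in% names(census))
    census$seg_length_total_um else census$length_um
  f <- seg / sum(seg)
  cls_col <- if ("class" %in% names(census)) census$class
             else rep("narrow", nrow(census))
  curve_cls <- ifelse(census$cj_ends == "none" | cls_col == "detached",
                      "no_cj",
                      ifelse(cls_col == "wide", "one_wide", "one_narrow"))
  L_eff <- ifelse(curve_cls != "no_cj" & census$cj_ends == "both",
                  census$length_um / 2, census$length_um)
  v <- vapply(seq_len(nrow(census)), function(i)
    flux_curve_value(curves, curve_cls[i], L_eff[i]), numeric(1))
  out <- sum(f * v)
  attr(out, "per_crista") <- data.frame(crista_id = census$crista_id,
                                        weight = f, curve = curve_cls,
                                        L_eff = L_eff, j_rel = v)
  out
}
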