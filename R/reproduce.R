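# End-to-end reproduction workflows for the headline analyses.

#' Run a named end-to-end analysis
#'
#' Orchestrates the standard analyses of the package against their
#' documented reference values:
#'
#' * `"conversions"`: the cell-rate unit conversion (1.3 mM/s per liter of
#'   cells, 30% mitochondrial volume, S/V 37 -> ~70 molecules/ms/um^2) and
#'   the three IBM corrections at a 92% crista surface fraction
#'   (0.58 -> 0.61, 0.70 -> 0.72, 0.93 -> 0.94).
#' * `"grid18"`: the 18-condition 2-D grid; reports quadratic-law fits,
#'   steepness and matrix-ADP ranges, and the worst short-to-long flux
#'   drops for one and two CJs.
#' * `"cjwidth3d"`: 3-D flux-versus-length curves for the CJ-width study,
#'   including the one-wide vs. trans-two-narrow equivalence.
#' * `"branching"`: the variable-topology branched model at
#'   `ADP_cyt = 0.0185` mM; trunk and short-branch depletions.
#' * `"census_score"`: flux curves plus census scoring of the bundled
#'   observed-like census (observed / all-detached / all-baffle).
#'
#' @param experiment experiment name
#' @param p a [kinetic_params()]
#' @param h2,h3 grid spacings for the 2-D and 3-D solves (um)
#' @param curves optional precomputed `flux_curves` (for
#'   `"census_score"` / `"cjwidth3d"`)
#' @param out_dir optional directory; results are written as CSV/JSON with
#'   a provenance sidecar
#' @return a named list of results (invisibly printed components vary by
#'   experiment)
#' @export
reproduce_experiment <- function(experiment = c("conversions", "grid18",
                                                "cjwidth3d", "branching",
                                                "census_score"),
                                 p = default_params(),
                                 h2 = 0.002, h3 = 0.005,
                                 curves = NULL, out_dir = NULL) {
  experiment <- tryCatch(match.arg(experiment), error = function(e)
    stop("reproduce_experiment: unknown experiment; choose one of: ",
         "conversions, grid18, cjwidth3d, branching, census_score",
         call. = FALSE))
  res <- switch(experiment,
    conversions = {
      list(area_flux = convert_cell_rate_to_area_flux(1.3, 0.30, 37),
           ibm_detached = ibm_correction(0.58, 0.92),
           ibm_observed = ibm_correction(0.70, 0.92),
           ibm_baffle = ibm_correction(0.93, 0.92))
    },
    grid18 = {
      gr <- run_condition_grid(p, h = h2)
      both <- gr[gr$cj_config == "both_ends" & gr$ok, ]
      drop_pct <- function(cfg) {
        g <- gr[gr$cj_config == cfg & gr$ok, ]
        max(vapply(unique(g$ADP_cyt), function(a) {
          js <- g$J_AS[g$ADP_cyt == a]
          ls <- g$L_CRIS[g$ADP_cyt == a]
          100 * (js[which.min(ls)] - js[which.max(ls)]) / js[which.min(ls)]
        }, numeric(1)))
      }
      list(table = gr,
           R2_min_both_ends = min(both$R2),
           k_range = range(both$k),
           ADP_m_range = range(gr$ADP_m, na.rm = TRUE),
           max_drop_one_cj_pct = drop_pct("one_end"),
           max_drop_two_cj_pct = drop_pct("both_ends"))
    },
    cjwidth3d = {
      if (is.null(curves)) curves <- build_flux_curves(p = p, h = h3)
      tb <- curves$table
      Ls <- sort(unique(tb$L[tb$class == "two_narrow"]))
      dev <- max(abs(flux_curve_value(curves, "one_wide", Ls) -
                     flux_curve_value(curves, "two_narrow", Ls)) /
                 flux_curve_value(curves, "one_wide", Ls))
      list(curves = curves, table = tb,
           wide_vs_trans_max_rel_dev = dev)
    },
    branching = {
      m <- build_variable_2d(0.9, h = h2)
      st <- solve_steady_state(m, p, boundary_conditions(0.0185))
      list(steady = st,
           trunk_depletion = depletion(adp_profile(st, 1L)),
           branch_third_depletion = depletion(adp_profile(st, 2L)),
           branch_quarter_depletion = depletion(adp_profile(st, 3L)))
    },
    census_score = {
      if (is.null(curves)) curves <- build_flux_curves(p = p, h = h3)
      census <- observed_census()
      detached <- census; detached$cj_ends <- "none"
      baffle <- census; baffle$cj_ends <- "both"; baffle$class <- "wide"
      s_obs <- census_score(census, curves)
      s_det <- census_score(detached, curves)
      s_baf <- census_score(baffle, curves)
      list(curves = curves,
           observed = as.numeric(s_obs),
           all_detached = as.numeric(s_det),
           all_baffle = as.numeric(s_baf),
           modulation_span_pct = 100 * (as.numeric(s_baf) -
                                          as.numeric(s_det)) /
                                   as.numeric(s_det))
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    flat <- res[vapply(res, function(x)
      is.numeric(x) && length(x) <= 2, logical(1))]
    jsonlite::write_json(flat, file.path(out_dir,
                                         paste0(experiment, ".json")),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(res$table))
      utils::write.csv(res$table, file.path(out_dir,
                                            paste0(experiment, ".csv")),
                       row.names = FALSE)
    prov <- list(experiment = experiment,
                 package_version = as.character(utils::packageVersion("cristaflux")),
                 params = unclass(p)[vapply(p, is.numeric, logical(1))])
    jsonlite::write_json(prov, file.path(out_dir,
                                         paste0(experiment, "_provenance.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
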