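# Profile analysis and the topology layer: quadratic law, depletion,
# penalties, decomposition, speed zones, curves and census scoring.

test_that("quadratic law fit recovers an exact parabola", {
  L <- 0.8; ADP0 <- 0.035; a <- 0.04
  x <- seq(0, L, length.out = 81)
  pr <- synthetic_profile(x, ADP0 - a * x * (L - x), L = L)
  fit <- fit_quadratic(pr)
  expect_equal(fit$a, a, tolerance = 1e-10)
  expect_equal(fit$R2, 1, tolerance = 1e-12)
  expect_equal(fit$k, a * L / ADP0, tolerance = 1e-10)
  expect_equal(unname(coef(fit)["k"]), fit$k)
  expect_error(fit_quadratic(synthetic_profile(x[1:3], rep(ADP0, 3))),
               "4 profile points")
})

test_that("area-based depletion behaves as an average deficit", {
  x <- seq(0, 0.64, by = 0.01)
  flat <- synthetic_profile(x, rep(0.03, length(x)), L = 0.64)
  expect_equal(depletion(flat), 0, tolerance = 1e-12)
  # parabola with steepness k: depletion = k L / 6
  L <- 0.64; ADP0 <- 0.03; k <- 2.5; a <- k * ADP0 / L
  par <- synthetic_profile(x, ADP0 - a * x * (L - x), L = L)
  expect_equal(depletion(par), k * L / 6, tolerance = 0.001)
  zero <- synthetic_profile(x, rep(0, length(x)), L = 0.64)
  expect_error(depletion(zero), "ADP0")
})

test_that("mirrored one-CJ profiles reproduce their source on both halves", {
  x <- seq(0.01, 0.31, by = 0.02)
  pr <- synthetic_profile(x, 0.03 - 0.02 * x, L = 0.32, cj = "one_end")
  m <- mirror_profile(pr)
  expect_equal(m$L, 0.64)
  expect_equal(m$adp[seq_along(x)], pr$adp)
  expect_equal(rev(m$adp)[seq_along(x)], pr$adp)
  expect_true(all(diff(m$x) > 0))
})

test_that("rule-of-two check is zero for matching profiles and validates lengths", {
  x1 <- seq(0.01, 0.31, by = 0.02)
  quad <- function(x, L) 0.03 - 0.05 * x * (L - x)
  p1 <- synthetic_profile(x1, quad(x1, 0.64), L = 0.32, cj = "one_end")
  x2 <- seq(0.01, 0.63, by = 0.02)
  p2 <- synthetic_profile(x2, quad(x2, 0.64), L = 0.64)
  expect_equal(rule_of_two_check(p1, p2), 0, tolerance = 1e-12)
  expect_error(rule_of_two_check(p2, p2), "twice as long")
})

test_that("diffusion penalty and flux decomposition are exact algebra", {
  expect_equal(diffusion_penalty(80, 100), 0.2)
  expect_equal(diffusion_penalty(100, 100), 0)
  expect_error(diffusion_penalty(1, 0), "J_max")
  led <- list(S_IBM = 0.3, S_CRIS = 1.2, S_IM = 1.5)
  # identity: a model running at J_max has crista flux J_max
  expect_equal(decompose_flux(100, 100, led), 100)
  # round trip with the recomposition (inverse pair)
  expect_equal(recompose_flux(decompose_flux(73.2, 101.5, led), 101.5, led),
               73.2, tolerance = 1e-12)
  # random ledgers against a direct formula oracle
  set.seed(42)
  for (i in 1:20) {
    S_cris <- runif(1, 0.1, 3); S_ibm <- runif(1, 0.05, 1)
    lg <- list(S_IBM = S_ibm, S_CRIS = S_cris, S_IM = S_ibm + S_cris)
    jm <- runif(1, 50, 150); jmax <- runif(1, 80, 160)
    oracle <- ((S_ibm + S_cris) * jm - S_ibm * jmax) / S_cris
    expect_equal(decompose_flux(jm, jmax, lg), oracle, tolerance = 1e-12)
  }
  expect_error(decompose_flux(1, 1, list(S_IBM = 1, S_CRIS = 0, S_IM = 1)),
               "S_CRIS")
})

test_that("IBM correction reproduces the printed whole-membrane fluxes", {
  expect_equal(round(ibm_correction(0.58, 0.92), 2), 0.61)
  expect_equal(round(ibm_correction(0.70, 0.92), 2), 0.72)
  expect_equal(round(ibm_correction(0.93, 0.92), 2), 0.94)
  expect_equal(ibm_correction(0.4, 1.0), 0.4)   # no IBM: unchanged
  expect_error(ibm_correction(1.2, 0.9), "0, 1")
})

test_that("speed zones partition [0,1] with closed-below boundaries", {
  expect_equal(speed_zone(0.95), "fast")
  expect_equal(speed_zone(0.9), "fast")
  expect_equal(speed_zone(0.75), "moderate")
  expect_equal(speed_zone(0.60), "slow")      # detached-crista regime
  js <- seq(0, 1, by = 0.001)
  z <- speed_zone(js)
  expect_true(all(z %in% c("fast", "moderate", "slow")))
  # exactly one zone per value, no gaps at the documented boundaries
  expect_equal(unname(table(z)["fast"]), sum(js >= 0.9))
  expect_equal(unname(table(z)["moderate"]), sum(js >= 0.75 & js < 0.9))
  expect_error(speed_zone(1.2), "0, 1")
})

test_that("census scoring is a weighted average of curve values", {
  curves <- fake_curves()
  one <- data.frame(crista_id = "C1", length_um = 0.8, n_segments = 2,
                    cjs_per_segment = 2, cj_ends = "one", class = "narrow")
  expect_equal(as.numeric(census_score(one, curves)),
               flux_curve_value(curves, "one_narrow", 0.8))
  # random census all on one curve: equals the length-weighted mean
  set.seed(7)
  n <- 12
  cen <- data.frame(crista_id = paste0("C", 1:n),
                    length_um = runif(n, 0.2, 1.4),
                    n_segments = 2, cjs_per_segment = 2,
                    cj_ends = "one", class = "narrow")
  oracle <- sum(cen$length_um / sum(cen$length_um) *
                  sapply(cen$length_um, function(L)
                    flux_curve_value(curves, "one_narrow", L)))
  expect_equal(as.numeric(census_score(cen, curves)), oracle,
               tolerance = 1e-12)
  # invariant to row order and to uniform rescaling of segment weights
  cen2 <- cen[sample(n), ]
  expect_equal(as.numeric(census_score(cen2, curves)),
               as.numeric(census_score(cen, curves)))
  cen3 <- cen; cen3$seg_length_total_um <- cen3$length_um * 1000
  expect_equal(as.numeric(census_score(cen3, curves)),
               as.numeric(census_score(cen, curves)))
  # both-end connectivity scores via the Rule-of-2 transformed curve
  both <- one; both$cj_ends <- "both"
  expect_equal(as.numeric(census_score(both, curves)),
               flux_curve_value(curves, "one_narrow", 0.4))
  # lengths beyond the sampled range flat-clamp
  far <- one; far$length_um <- 5
  expect_equal(as.numeric(census_score(far, curves)),
               flux_curve_value(curves, "one_narrow", 1.5))
  expect_error(census_score(cen[0, ], curves), "empty")
})
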