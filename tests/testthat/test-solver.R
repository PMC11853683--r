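# Steady-state solver: exactness checks, conservation laws, symmetry,
# analytic oracle, determinism and cross-validation of the two solution
# paths.

test_that("no-crista model at kinase equilibrium gives uniform fields", {
  p <- test_params()   # Pi_e NA => kinase exactly at equilibrium at the bc
  m <- build_uniform_2d(0, "one_end", domain_w = 0.04, h = 0.004)
  st <- solve_steady_state(m, p, boundary_conditions(0.037))
  # fields uniform at the boundary values up to the tiny IBM sink
  expect_lt(diff(range(st$ADP_e)) / 0.037, 0.01)
  expect_lt(max(abs(st$ATP_e - 4.0)) / 4.0, 0.01)
  # identical translocase flux on every membrane element
  jm <- st$J_ANT[st$mem_area > 0]
  expect_lt(diff(range(jm)) / mean(jm), 1e-4)
  expect_true(st$converged)
})

test_that("matrix adenine total is conserved and the balance closes", {
  p <- test_params()
  m <- build_uniform_2d(0.16, "one_end", domain_w = 0.04, h = 0.004)
  st <- solve_steady_state(m, p, boundary_conditions(0.037))
  expect_equal(st$ADP_m + st$ATP_m, 0.72 + 0.44, tolerance = 1e-12)
  # total ANT uptake equals total synthase flux at steady state
  expect_lt(abs(st$J_ANT_total - st$J_AS_total) / st$J_AS_total, 1e-8)
  expect_lt(st$residuals$field, 1e-8)
})

test_that("with equal diffusivities the sum field is spatially uniform", {
  p <- test_params()
  m <- build_uniform_2d(0.32, "both_ends", domain_w = 0.04, h = 0.004)
  st <- solve_steady_state(m, p, boundary_conditions(0.037))
  s <- st$ADP_e + st$ATP_e
  expect_lt(diff(range(s)) / (0.037 + 4.0), 1e-12)
  expect_equal(mean(s), 4.037, tolerance = 1e-12)
})

test_that("both-ends steady fields are mirror-symmetric about the midpoint", {
  p <- test_params()
  m <- build_uniform_2d(0.32, "both_ends", domain_w = 0.04, h = 0.004)
  st <- solve_steady_state(m, p, boundary_conditions(0.037))
  pr <- adp_profile(st)
  expect_equal(pr$adp, rev(pr$adp), tolerance = 1e-7)
})

test_that("dead-end channel with linearized kinetics matches the cosh solution", {
  # negligible translocase: the ADP equation becomes linear,
  # D A'' + k_f (s - A) - k_r Pi_e A = 0, whose dead-end solution is a
  # catenary about the closed tip. Solved and derived profiles must agree
  # to better than 1%.
  p <- test_params(V_ANT = 1e-9, Pi_e = 2, k_f = 0.009, k_r = 1,
                   D_ADP = 0.05, D_ATP = 0.05)
  L <- 0.32
  m <- build_uniform_2d(L, "one_end", domain_w = 0.04, h = 0.002)
  st <- solve_steady_state(m, p, boundary_conditions(0.037))
  pr <- adp_profile(st)
  s <- 4.037
  lam <- p$k_f + p$k_r * 2
  A_inf <- p$k_f * s / lam
  mu <- sqrt(lam / p$D_ADP)
  x1 <- pr$x[1]
  A0 <- pr$adp[1]
  analytic <- A_inf + (A0 - A_inf) * cosh(mu * (L - pr$x)) /
    cosh(mu * (L - x1))
  expect_lt(max(abs(pr$adp - analytic)) / A0, 0.01)
})

test_that("the Rule of 2 holds to a small, grid-stable deviation", {
  # the one-CJ crista carries membrane on its closed tip while the two-CJ
  # midpoint is a bare symmetry plane, so the agreement has a small
  # physical floor; it must be well under 5% and stable under refinement
  p <- test_params()
  devs <- vapply(c(0.004, 0.002, 0.001), function(h) {
    st1 <- solve_steady_state(
      build_uniform_2d(0.16, "one_end", domain_w = 0.04, h = h), p,
      boundary_conditions(0.037))
    st2 <- solve_steady_state(
      build_uniform_2d(0.32, "both_ends", domain_w = 0.04, h = h), p,
      boundary_conditions(0.037))
    rule_of_two_check(adp_profile(st1), adp_profile(st2))
  }, numeric(1))
  expect_true(all(devs < 0.05))
  expect_lt(diff(range(devs)) / mean(devs), 0.2)
})

test_that("synthase flux is monotone in crista length and workload", {
  p <- test_params()
  j_by_L <- vapply(c(0.16, 0.32, 0.48), function(L)
    solve_steady_state(build_uniform_2d(L, "one_end", domain_w = 0.04,
                                        h = 0.004),
                       p, boundary_conditions(0.037))$J_AS, numeric(1))
  expect_true(all(diff(j_by_L) < 0))
  j_by_adp <- vapply(c(0.0185, 0.037, 0.074), function(a)
    solve_steady_state(build_uniform_2d(0.32, "one_end", domain_w = 0.04,
                                        h = 0.004),
                       p, boundary_conditions(a))$J_AS, numeric(1))
  expect_true(all(diff(j_by_adp) > 0))
})

test_that("halving the grid spacing changes J(AS) by < 2%", {
  p <- test_params()
  j <- vapply(c(0.004, 0.002), function(h)
    solve_steady_state(build_uniform_2d(0.32, "one_end", domain_w = 0.04,
                                        h = h),
                       p, boundary_conditions(0.037))$J_AS, numeric(1))
  expect_lt(abs(j[1] - j[2]) / j[2], 0.02)
})

test_that("repeated solves are bit-identical", {
  p <- test_params()
  m <- build_uniform_2d(0.16, "both_ends", domain_w = 0.04, h = 0.004)
  s1 <- solve_steady_state(m, p, boundary_conditions(0.037))
  s2 <- solve_steady_state(m, p, boundary_conditions(0.037))
  expect_identical(s1$J_AS, s2$J_AS)
  expect_identical(s1$ADP_e, s2$ADP_e)
})

test_that("detached lumens equilibrate at the cytosolic adenine total", {
  p <- test_params()
  m <- build_uniform_2d(0.16, "none", domain_w = 0.04, h = 0.004)
  st <- solve_steady_state(m, p, boundary_conditions(0.037))
  lum <- st$model$region[st$ext] > 0
  expect_equal(mean(st$ADP_e[lum] + st$ATP_e[lum]), 4.037, tolerance = 1e-9)
  # a detached crista supports less synthase flux than an attached one
  sta <- solve_steady_state(
    build_uniform_2d(0.16, "one_end", domain_w = 0.04, h = 0.004), p,
    boundary_conditions(0.037))
  expect_lt(st$J_AS, sta$J_AS)
  # unequal diffusivities are rejected for detached compartments
  expect_error(solve_steady_state(m, test_params(D_ATP = 0.11),
                                  boundary_conditions(0.037)),
               "detached")
})

test_that("coupled two-species path agrees with the equal-D reduction", {
  m <- build_uniform_2d(0.16, "one_end", domain_w = 0.04, h = 0.004)
  bc <- boundary_conditions(0.037)
  st_eq <- solve_steady_state(m, test_params(), bc)
  # D_ATP differing by 1 part in 1e6 forces the coupled Newton path
  st_cp <- solve_steady_state(m, test_params(D_ATP = 0.1 * (1 + 1e-6)), bc)
  expect_equal(st_cp$J_AS, st_eq$J_AS, tolerance = 1e-4)
  expect_equal(st_cp$ADP_m, st_eq$ADP_m, tolerance = 1e-4)
  expect_lt(st_cp$residuals$field, 1e-6)
  # genuinely unequal diffusivities break the sum-field uniformity
  st_un <- solve_steady_state(m, test_params(D_ATP = 0.05), bc)
  expect_gt(diff(range(st_un$ADP_e + st_un$ATP_e)), 1e-6)
})

test_that("3-D lamellar models solve and order by CJ topology", {
  p <- test_params()
  bc <- boundary_conditions(0.037)
  js <- vapply(c("none", "narrow", "wide"), function(mode)
    solve_steady_state(build_lamellar_3d(0.3, mode, h = 0.005), p, bc)$J_AS,
    numeric(1))
  expect_true(js[["none"]] < js[["narrow"]])
  expect_true(js[["narrow"]] < js[["wide"]])
})
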