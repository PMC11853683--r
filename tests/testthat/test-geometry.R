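# Spatial model construction and the surface-area ledger.

# Independent brute-force ledger: loop over every cell and neighbor with
# plain nested indexing (no shared helpers with the package internals).
brute_ledger <- function(m) {
  mask <- m$mask; region <- m$region
  dims <- dim(mask); nd <- length(dims)
  fa <- if (m$dim == 2L) m$h * m$depth else m$h^2
  S_cris <- S_ibm <- 0
  idx <- which(mask == 1L)
  for (cell in idx) {
    pos <- arrayInd(cell, dims)
    for (d in seq_len(nd)) for (s in c(-1L, 1L)) {
      q <- pos; q[d] <- q[d] + s
      if (q[d] < 1L || q[d] > dims[d]) next
      nb <- if (nd == 2L) mask[q[1], q[2]] else mask[q[1], q[2], q[3]]
      if (nb == 2L) {
        if (region[cell] > 0L) S_cris <- S_cris + fa else S_ibm <- S_ibm + fa
      }
    }
  }
  list(S_IBM = S_ibm + m$extra_ibm, S_CRIS = S_cris)
}

test_that("uniform arrays pack floor(domain_w / pitch) cristae", {
  m <- build_uniform_2d(0.32, "one_end", domain_w = 0.76, h = 0.004)
  expect_equal(m$meta$n_cristae, 19)           # floor(0.76 / 0.04)
  expect_equal(length(m$cristae), 19)
  m2 <- build_uniform_2d(0.32, "one_end", domain_w = 0.1, h = 0.004)
  expect_equal(m2$meta$n_cristae, 2)
  expect_error(build_uniform_2d(0.32, "one_end", domain_w = 0.03, h = 0.004),
               "domain")
})

test_that("zero-length cristae degenerate to the no-crista model", {
  m <- build_uniform_2d(0, "one_end", domain_w = 0.04, h = 0.004)
  led <- surface_ledger(m)
  expect_equal(led$S_CRIS, 0)
  expect_equal(led$S_IM, led$S_IBM)
  expect_length(m$cristae, 0)
})

test_that("the standard 2-D domain dimensions are accepted and recorded", {
  m <- build_uniform_2d(0.2, "both_ends", domain_w = 0.76, domain_h = 0.30,
                        h = 0.004)
  expect_equal(m$meta$domain_w, 0.76)
  expect_equal(m$meta$domain_h, 0.30)
  expect_error(build_uniform_2d(0.5, "both_ends", domain_h = 0.30, h = 0.004),
               "does not fit")
})

test_that("surface ledger equals brute-force element summation", {
  models <- list(
    build_uniform_2d(0.16, "one_end", domain_w = 0.08, h = 0.004),
    build_uniform_2d(0.16, "both_ends", domain_w = 0.04, h = 0.004),
    build_variable_2d(0.3, h = 0.004),
    build_lamellar_3d(0.15, "narrow", h = 0.005))
  for (m in models) {
    led <- surface_ledger(m)
    bl <- brute_ledger(m)
    expect_equal(led$S_CRIS, bl$S_CRIS)
    expect_equal(led$S_IBM, bl$S_IBM)
    expect_equal(led$S_IM, led$S_IBM + led$S_CRIS)
  }
})

test_that("ledger areas match hand-computed wall lengths", {
  # one crista, both ends open: two walls of length L, no tips
  m <- build_uniform_2d(0.16, "both_ends", domain_w = 0.04, h = 0.004)
  expect_equal(surface_ledger(m)$S_CRIS, 2 * 0.16)
  # one end: two walls plus the closed tip (lumen width 0.02)
  m1 <- build_uniform_2d(0.16, "one_end", domain_w = 0.04, h = 0.004)
  expect_equal(surface_ledger(m1)$S_CRIS, 2 * 0.16 + 0.02)
})

test_that("ledger is discretization-stable under grid refinement", {
  for (builder in list(
    function(h) build_uniform_2d(0.32, "one_end", domain_w = 0.04, h = h),
    function(h) build_variable_2d(0.32, h = h))) {
    a <- surface_ledger(builder(0.004))
    b <- surface_ledger(builder(0.002))
    expect_lt(abs(a$S_CRIS - b$S_CRIS) / b$S_CRIS, 0.02)
    expect_lt(abs(a$S_IBM - b$S_IBM) / b$S_IBM, 0.02)
  }
})

test_that("both-ends geometry is mirror-symmetric about the crista midpoint", {
  m <- build_uniform_2d(0.24, "both_ends", domain_w = 0.04, h = 0.004)
  expect_identical(m$mask, m$mask[, rev(seq_len(ncol(m$mask)))])
})

test_that("variable-topology model has the documented branch lengths", {
  m <- build_variable_2d(0.9, h = 0.002)
  expect_equal(m$cristae[[1]]$L, 0.9)
  expect_equal(m$cristae[[2]]$L, 0.9 / 3, tolerance = 0.002 / 0.3)
  expect_equal(m$cristae[[3]]$L, 0.9 / 4, tolerance = 0.002 / 0.225)
  # lumen regions are disjoint labels; every midline stays in its own region
  for (k in 1:3)
    expect_true(all(m$region[as.vector(m$cristae[[k]]$midline)] == k))
  # crista membrane equals the hand-summed wall lengths: trunk walls minus
  # the two branch openings, plus both branch walls
  led <- surface_ledger(m)
  expected <- 2 * m$cristae[[1]]$L - 2 * 0.02 +
    2 * m$cristae[[2]]$L + 2 * m$cristae[[3]]$L
  expect_equal(led$S_CRIS, expected, tolerance = 1e-9)
})

test_that("3-D lamellar CJ modes give the documented aperture widths", {
  h <- 0.005
  count_neck <- function(m) {
    # aperture cells sit in the base slab (x-planes between boundary layer
    # and lumen); count distinct y columns that are external there
    xneck <- 1L + 4L + 1L   # first base-slab plane (blayer = 4 cells)
    sum(m$mask[xneck, , ] == 1L) / 4   # z-thickness of lumen = 4 cells
  }
  mn <- build_lamellar_3d(0.3, "narrow", h = h)
  expect_equal(count_neck(mn) * h, 0.02)
  mw <- build_lamellar_3d(0.3, "wide", h = h)
  expect_equal(count_neck(mw) * h, 0.15)
  m2 <- build_lamellar_3d(0.3, "n_cis", n_cj = 3, h = h)
  expect_equal(count_neck(m2) * h, 0.06)
  md <- build_lamellar_3d(0.3, "none", h = h)
  expect_equal(count_neck(md), 0)
  expect_error(build_lamellar_3d(0.3, "n_cis", n_cj = 10, h = h), "fit")
})

test_that("3-D crista-to-IBM surface ratios follow the nominal range", {
  for (L in c(0.15, 0.45, 0.9)) {
    led <- surface_ledger(build_lamellar_3d(L, "narrow", h = 0.005))
    r <- led$S_CRIS / led$S_IBM
    expect_gte(r, 0.99)
    expect_lte(r, 1.81)
  }
})

test_that("external cells connect to the boundary unless the crista is detached", {
  su <- cristaflux:::.solver_setup(
    build_uniform_2d(0.16, "one_end", domain_w = 0.04, h = 0.004))
  expect_true(all(su$reach))
  sud <- cristaflux:::.solver_setup(
    build_uniform_2d(0.16, "none", domain_w = 0.04, h = 0.004))
  expect_true(any(!sud$reach))      # lumen isolated
  expect_true(any(sud$reach))       # boundary layer still connected
})
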