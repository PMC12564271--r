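# Channel geometry validation and staggered grid construction.

test_that("part I height is derived from the step height", {
  g <- channel_geometry(b1 = 4, h3 = 0.06, b2 = 5, h2 = 0.15)
  expect_equal(g$h1, 0.09)
  expect_equal(channel_geometry(h2 = 0.15, h3 = 0.03)$h1, 0.12)
  expect_equal(g$L_total, 24.5)
})

test_that("geometry invariants are enforced with named errors", {
  expect_error(channel_geometry(h3 = 0.15, h2 = 0.15), "h3 must be < h2")
  expect_error(channel_geometry(b1 = 6, b2 = 5), "b1 must be <= b2")
  expect_error(channel_geometry(b2 = -1), "b2 must be > 0")
  expect_error(channel_geometry(x_step = 40), "x_step")
})

test_that("build_geometry fills defaults and rejects unknown keys", {
  g <- build_geometry(list(b1 = 4, h3 = 0.06, b2 = 5, h2 = 0.15))
  expect_equal(g$L1, 13.5)
  expect_equal(g$x_step, 14)
  expect_equal(g$R, 0.5)
  expect_error(build_geometry(list(b1 = 4, h3 = 0.06, b2 = 5, hh2 = 1)),
               "unknown geometry keys: hh2")
})

test_that("grid mask reproduces the step exactly and is connected", {
  g <- channel_geometry(b1 = 4, h3 = 0.06, b2 = 5)
  gr <- do.call(build_grid, c(list(g), coarse_grid_opts))
  # the solid region is exactly the step rectangle (center rasterization)
  expected <- outer(gr$xc < gr$x_step, gr$yc < -0.15e-3 + 0.06e-3, "&")
  expect_identical(gr$solid, expected)
  # >= 6 cells across h3
  expect_gte(sum(gr$yc < -0.15e-3 + 0.06e-3 & gr$yc > -0.15e-3), 6L)
  # cell types partition the domain
  expect_setequal(unique(as.vector(gr$cell_type)),
                  c("fluid", "solid", "inlet", "outlet", "wall"))
})

test_that("a step-free geometry produces no solid cells", {
  g <- channel_geometry(b1 = 4, h3 = 0, b2 = 5)
  gr <- do.call(build_grid, c(list(g), coarse_grid_opts))
  expect_false(any(gr$solid))
})

test_that("under-resolved steps are refused", {
  g <- channel_geometry(b1 = 4, h3 = 0.03, b2 = 5)
  expect_error(build_grid(g, base_dy = 7.5e-6),
               "insufficient step resolution")
})

test_that("refinement factor controls the window cell count only", {
  g <- channel_geometry(b1 = 4, h3 = 0.06, b2 = 5)
  g1 <- build_grid(g, base_dx = 5e-4, base_dy = 7.5e-6, refine_factor = 10)
  g2 <- build_grid(g, base_dx = 5e-4, base_dy = 7.5e-6, refine_factor = 20)
  in_win <- function(gr) sum(gr$xc >= 13.5e-3 & gr$xc <= 14.5e-3)
  out_win <- function(gr) sum(gr$xc < 13.5e-3 | gr$xc > 14.5e-3)
  expect_equal(in_win(g2), 2L * in_win(g1))
  # graded transition zones change only marginally
  expect_lt(abs(out_win(g2) - out_win(g1)), 10L)
  expect_equal(g1$ny, g2$ny)
})

test_that("discrete fluid area matches the mid-plane polygon area", {
  g <- channel_geometry(b1 = 4, h3 = 0.06, b2 = 5)
  gr <- do.call(build_grid, c(list(g), coarse_grid_opts))
  fa <- fluid_area(gr)
  expect_lt(abs(fa$discrete - fa$analytic), fa$max_cell)
})
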