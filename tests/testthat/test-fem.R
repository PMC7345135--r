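coarse_fem <- function(...) meshing_options(max_element_size = 2e-6, ...)

test_that("element stiffness matches the closed-form P1 stencil", {
  # unit right triangle, sigma* = 1: the standard linear-triangle
  # Laplacian stencil [[1, -.5, -.5], [-.5, .5, 0], [-.5, 0, .5]]
  coords <- rbind(c(0, 0), c(1, 0), c(0, 1))
  Ke <- element_stiffness(coords, 1 + 0i)
  ref <- rbind(c(1, -0.5, -0.5), c(-0.5, 0.5, 0), c(-0.5, 0, 0.5))
  expect_equal(Ke, ref + 0i, tolerance = 1e-14)
  # linearity in sigma*
  expect_equal(element_stiffness(coords, 3 - 2i), (3 - 2i) * Ke,
               tolerance = 1e-14)
  expect_error(element_stiffness(coords[c(1, 3, 2), ], 1), "positive")
})

test_that("two-triangle unit square reproduces the linear potential", {
  m <- rect_mesh(nx = 2, ny = 2)
  sys <- assemble(fem_problem(m, list(medium = saline()), 1e6,
                              u_top = 10, u_bottom = 0))
  sol <- solve_fem(sys)
  expect_equal(sol$potentials, complex(real = 10 * m$nodes[, 2]),
               tolerance = 1e-12)
})

test_that("homogeneous media are reproduced exactly (P1 exactness)", {
  m <- generate_mesh(build_geometry(reference_cell(2), 0.035), coarse_fem())
  mats <- list(medium = saline(), membrane = saline(), cytoplasm = saline())
  sys <- assemble(fem_problem(m, mats, 1e6))
  sol <- solve_fem(sys)
  eff <- effective_conductivity(sol, sys)
  expect_equal(eff$sigma_r, 1, tolerance = 1e-10)
  expect_equal(eff$eps_r, 80, tolerance = 1e-8)
  # discrete maximum principle on the Dirichlet data
  expect_lte(max(Re(sol$potentials)), 10 + 1e-9)
  expect_gte(min(Re(sol$potentials)), -1e-9)
  # exact current for the uniform field: I = sigma U W / L
  I <- total_current(sol, sys)
  expect_equal(Re(I), 1 * 10 * eff$S / eff$L, tolerance = 1e-10)
})

test_that("electrode fluxes balance and match the cut-line diagnostic", {
  # default resolution: the cut-line estimator is an accuracy diagnostic
  m <- generate_mesh(build_geometry(reference_cell(2), 0.035))
  sys <- assemble(fem_problem(m, reference_cell(2), 1e6))
  sol <- solve_fem(sys)
  It <- total_current(sol, sys, "top")
  Ib <- total_current(sol, sys, "bottom")
  expect_lt(Mod(It - Ib) / Mod(Ib), 1e-12)
  for (y0 in c(0, 1e-5)) {
    Ic <- cut_line_current(sol, sys, y0 = y0)
    expect_lt(Mod(Ic - Ib) / Mod(Ib), 1e-3)
  }
  expect_error(cut_line_current(sol, sys, y0 = 1), "outside the domain")
})

test_that("solutions match a dense-matrix brute-force solve", {
  # small hand-built meshes, both homogeneous and two-region
  for (m in list(rect_mesh(4, 4),
                 rect_mesh(5, 4, split = 0.4, lower = "cytoplasm"))) {
    mats <- list(medium = saline(), cytoplasm = material(0.01, 5))
    f <- 5e5
    sys <- assemble(fem_problem(m, mats, f))
    sol <- solve_fem(sys)
    u_ref <- dense_potentials(m, mats, f)
    expect_lt(max(Mod(sol$potentials - u_ref)) / max(Mod(u_ref)), 1e-12)
  }
})

test_that("DC effective conductivity obeys the Wiener bounds", {
  m <- generate_mesh(build_geometry(reference_cell(2), 0.035), coarse_fem())
  mats <- list(medium = material(1, 1), membrane = material(0.2, 1),
               cytoplasm = material(3, 1))
  sys <- assemble(fem_problem(m, mats, 1e-3 + 1))   # ~DC, real sigma
  eff <- effective_conductivity(solve_fem(sys), sys)
  a <- triangle_areas(m)
  w <- vapply(split(a, m$region), sum, 0) / sum(a)
  sig <- c(medium = 1, membrane = 0.2, cytoplasm = 3)
  lo <- 1 / sum(w / sig)          # harmonic (series) bound
  hi <- sum(w * sig)              # arithmetic (parallel) bound
  expect_gte(eff$sigma_r, lo - 1e-9)
  expect_lte(eff$sigma_r, hi + 1e-9)
})

test_that("an insulating disc matches the 2D dilute closed form", {
  g <- build_geometry(reference_cell(2), 0.035)
  m <- generate_mesh(g)   # default resolution: this is an accuracy check
  mats <- list(medium = saline(), membrane = material(0, 5),
               cytoplasm = material(0, 5))
  sys <- assemble(fem_problem(m, mats, 1e3))
  eff <- effective_conductivity(solve_fem(sys), sys)
  # oracle uses the meshed polygon's area fraction
  a <- triangle_areas(m)
  P <- sum(a[m$region != "medium"]) / sum(a)
  expect_equal(eff$sigma_r, (1 - P) / (1 + P), tolerance = 5e-3)
})

test_that("warm-started sweeps agree with cold starts", {
  m <- generate_mesh(build_geometry(reference_cell(2), 0.035),
                     coarse_fem())
  geometry <- betadisp:::fem_geometry(m)
  f1 <- 1e5; f2 <- 2e5
  sys1 <- assemble(fem_problem(m, reference_cell(2), f1), geometry)
  sys2 <- assemble(fem_problem(m, reference_cell(2), f2), geometry)
  cold <- solve_fem(sys2, method = "bicgstab", tol = 1e-11)
  s1 <- solve_fem(sys1, method = "bicgstab", tol = 1e-11)
  warm <- solve_fem(sys2, method = "bicgstab", tol = 1e-11,
                    x0 = s1$potentials[sys1$free])
  expect_lt(max(Mod(warm$potentials - cold$potentials)) /
              max(Mod(cold$potentials)), 1e-8)
  # and the sweep-level spectra agree between solver paths
  fs <- default_frequencies(5)
  sp_d <- fem_sweep(m, reference_cell(2), fs, method = "direct")
  sp_b <- suppressMessages(
    fem_sweep(m, reference_cell(2), fs, method = "bicgstab"))
  expect_equal(sp_b$sigma_star, sp_d$sigma_star, tolerance = 1e-6)
})

test_that("degenerate problems raise informative errors", {
  m <- rect_mesh(3, 3)
  m$boundary_edges$tag[] <- "side"    # no electrodes anywhere
  expect_error(assemble(fem_problem(m, list(medium = saline()), 1e6)),
               "singular|electrode")
  m2 <- rect_mesh(3, 3)
  expect_error(assemble(fem_problem(m2, list(membrane = saline()), 1e6)),
               "medium")
  sys <- assemble(fem_problem(m2, list(medium = saline()), 1e6,
                              u_top = 0, u_bottom = 0))
  expect_error(effective_conductivity(solve_fem(sys), sys), "zero")
})

test_that("effective conductivity is mesh-converged at the default size", {
  g <- build_geometry(reference_cell(2), 0.035)
  cell <- reference_cell(2)
  s_h <- local({
    m <- generate_mesh(g, meshing_options(max_element_size = 1e-6))
    sys <- assemble(fem_problem(m, cell, 1e6))
    effective_conductivity(solve_fem(sys), sys)$sigma_star
  })
  s_d <- local({
    m <- generate_mesh(g)   # default, half the coarse size
    sys <- assemble(fem_problem(m, cell, 1e6))
    effective_conductivity(solve_fem(sys), sys)$sigma_star
  })
  expect_lt(Mod(s_d - s_h) / Mod(s_d), 1e-3)
})
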