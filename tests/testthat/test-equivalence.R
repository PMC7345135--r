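test_that("equivalence identities: no added layer, no contrast", {
  m1 <- material(1e-7, 5)
  m2 <- material(1, 80)
  f <- default_frequencies(12)
  # l2 = 0: the equivalent conductivity is the membrane's own
  s0 <- equivalence_spec(5e-9, 0, m1, m2)
  expect_crel(equivalent_conductivity(s0, f),
              complex_conductivity(m1, f), 1e-14)
  # identical materials: any split leaves sigma* unchanged
  s1 <- equivalence_spec(5e-9, 37e-9, m1, m1)
  expect_crel(equivalent_conductivity(s1, f),
              complex_conductivity(m1, f), 1e-14)
  # l2 = 0 on the cell transform is the exact identity
  cell <- reference_cell(2)
  expect_identical(equivalent_cell(cell, 0), cell)
  expect_error(equivalent_cell(cell, 5e-6), "smaller than")
})

test_that("equivalent conductivity matches brute-force series arithmetic", {
  # frozen from direct evaluation of the series-impedance formula at
  # 1 MHz, l1 = 5 nm membrane + l2 = 15 nm cytoplasm-like layer
  se <- equivalent_conductivity(
    equivalence_spec(5e-9, 15e-9, material(1e-7, 5), material(1, 80)), 1e6)
  expect_equal(Re(se), 1.32846274865e-06, tolerance = 1e-9)
  expect_equal(Im(se), 1.11264448085e-03, tolerance = 1e-9)
  # the equivalent relative permittivity is ~ 4 eps_m = 20
  expect_equal(Im(se) / (2 * pi * 1e6 * EPS0), 20, tolerance = 1e-3)
})

test_that("flat-slab substitution is exact at every frequency", {
  m1 <- material(1e-7, 5); m2 <- material(1, 80)
  l1 <- 5e-9; l2 <- 15e-9
  spec <- equivalence_spec(l1, l2, m1, m2)
  for (f in default_frequencies(15)) {
    z_stack <- stack_impedance(c(l1, l2), list(m1, m2), f)
    z_equiv <- (l1 + l2) / equivalent_conductivity(spec, f)
    expect_crel(z_equiv, z_stack, 1e-13)
    # and inside a full three-layer stack (medium | membrane | cytoplasm)
    med <- material(1, 80)
    z3 <- stack_impedance(c(1e-6, l1, 2e-6), list(med, m1, m2), f)
    z3e <- stack_impedance(c(1e-6, 2e-6 - l2), list(med, m2), f) +
      (l1 + l2) / equivalent_conductivity(spec, f)
    expect_crel(z3e, z3, 1e-13)
  }
})

test_that("membrane capacitance per unit area is preserved within 1%", {
  # at 1 MHz the cytoplasm-like layer is a good conductor and the
  # membrane a good insulator: eps_e (l1+l2) capacitance = eps_1/l1 one
  se <- equivalent_conductivity(
    equivalence_spec(5e-9, 15e-9, material(1e-7, 5), material(1, 80)), 1e6)
  eps_e <- Im(se) / (2 * pi * 1e6 * EPS0)
  cm_equiv <- eps_e * EPS0 / 20e-9
  cm_true <- 5 * EPS0 / 5e-9
  expect_equal(cm_equiv, cm_true, tolerance = 0.01)
  expect_equal(cm_true, 8.8541878128e-3, tolerance = 1e-12)
})

test_that("analytical spectra of original and equivalent models agree", {
  cell <- reference_cell(2)
  f <- default_frequencies(15)
  full <- analytical_sweep(cell, 0.035, f)
  maxdev <- function(l2) {
    red <- analytical_sweep(equivalent_cell(cell, l2), 0.035, f)
    max(abs(red$sigma_r - full$sigma_r) / full$sigma_r,
        abs(red$eps_r - full$eps_r) / full$eps_r)
  }
  d <- vapply(c(5e-9, 15e-9, 45e-9), maxdev, 0)
  # 1:3 thickening stays within ~0.3%, 1:1 strictly better, and the
  # approximation error grows monotonically with the added thickness
  expect_lt(d[2], 0.003)
  expect_lt(d[1], d[2])
  expect_true(all(diff(d) > 0))
})

test_that("the equivalent cell carries the thickened geometry", {
  cell <- reference_cell(2)
  eq <- equivalent_cell(cell, 15e-9)
  expect_equal(eq$membrane_thickness, 20e-9)
  expect_equal(shell_factor(eq), (1 - 20e-9 / 5e-6)^2)
  # its membrane dielectric is the frequency-dependent sigma_e*
  expect_crel(eq$membrane_model(1e6),
              equivalent_conductivity(
                equivalence_spec(5e-9, 15e-9, cell$membrane,
                                 cell$cytoplasm), 1e6), 1e-15)
  # applying the transform twice is rejected
  expect_error(equivalent_cell(eq, 5e-9), "already carries")
})
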