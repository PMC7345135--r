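test_that("single-shell model reduces to its algebraic limits", {
  f <- c(1e3, 1e5, 1e7)
  # vanishing shell (v -> 1): equivalent permittivity equals the cytoplasm
  thin <- cell_model(radius = 5e-6, membrane_thickness = 1e-20,
                     dimension = 2, membrane = material(1e-7, 5),
                     cytoplasm = saline(), medium = saline())
  expect_crel(single_shell_permittivity(thin, f),
              complex_permittivity(saline(), f), 1e-6)
  # no contrast: membrane identical to cytoplasm
  same <- cell_model(radius = 5e-6, membrane_thickness = 5e-9,
                     dimension = 3, membrane = saline(),
                     cytoplasm = saline(), medium = saline())
  expect_crel(single_shell_permittivity(same, f),
              complex_permittivity(saline(), f), 1e-12)
})

test_that("single-shell value matches brute-force evaluation at 10 kHz", {
  # frozen from direct complex arithmetic of the shell formula (n = 2,
  # canonical materials): membrane-dominated plateau ~ 7.5e3
  ep <- single_shell_permittivity(reference_cell(2), 1e4)
  expect_equal(Re(ep), 7491.37290735, tolerance = 1e-9)
  expect_equal(Im(ep), -300.608800012, tolerance = 1e-9)
})

test_that("Wagner mixture interpolates exactly at P = 0 and P = 1", {
  ea <- complex_permittivity(saline(), 1e6)
  ep <- single_shell_permittivity(reference_cell(2), 1e6)
  expect_crel(wagner_mixture(ep, ea, 0), ea, 1e-14)
  expect_crel(wagner_mixture(ep, ea, 1), ep, 1e-14)
  expect_error(wagner_mixture(ep, ea, 1.2), "\\[0, 1\\]")
  expect_error(wagner_mixture(ep, ea, -0.1), "\\[0, 1\\]")
})

test_that("insulating-inclusion DC limit of the mixture is 2(1-P)/(2+P)", {
  P <- 0.035
  ea <- 80 + 1 / (1i * 2 * pi * 1e-2 * EPS0)   # medium at f -> 0
  lim <- wagner_mixture(0 + 0i, ea, P)
  expect_equal(Mod(lim / ea), 2 * (1 - P) / (2 + P), tolerance = 1e-8)
  expect_equal(2 * (1 - P) / (2 + P), 0.9484029, tolerance = 1e-6)
})

test_that("analytical sweep shows the beta dispersion for the canonical cell", {
  f <- default_frequencies(15)
  sp <- analytical_sweep(reference_cell(2), P = 0.035, f)
  # conductivity non-decreasing, permittivity non-increasing across the band
  expect_true(all(diff(sp$sigma_r) >= -1e-12 * sp$sigma_r[-1]))
  expect_true(all(diff(sp$eps_r) <= 1e-12 * sp$eps_r[-1]))
  # high-frequency permittivity plateau at the fluid value
  expect_equal(sp$eps_r[15], 80, tolerance = 0.01)
  # low-frequency conductivity at the insulating-cell limit (n = 3 too)
  sp3 <- analytical_sweep(reference_cell(3), P = 0.035, f)
  expect_equal(sp3$sigma_r[1], 2 * (1 - 0.035) / (2 + 0.035),
               tolerance = 1e-4)
  # spectrum invariants: decomposition consistent with sigma*
  w <- 2 * pi * sp$frequency_hz
  expect_equal(sp$sigma_r, Re(sp$sigma_star), tolerance = 0)
  expect_equal(sp$eps_r, Im(sp$sigma_star) / (w * EPS0), tolerance = 0)
})

test_that("zero volume fraction gives a flat medium spectrum", {
  f <- default_frequencies(10)
  sp <- analytical_sweep(reference_cell(2), P = 0, f)
  expect_crel(sp$sigma_star, complex_conductivity(saline(), f), 1e-14)
})

test_that("spectrum CSV serialization round-trips losslessly", {
  sp <- analytical_sweep(reference_cell(2), P = 0.035,
                         default_frequencies(9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(sp, path)
  hdr <- readLines(path, n = 1)
  expect_identical(hdr, "frequency_hz,sigma_re,sigma_im,sigma_r,eps_r")
  sp2 <- read_spectrum(path)
  expect_equal(sp2$sigma_star, sp$sigma_star, tolerance = 1e-15)
  expect_equal(sp2$frequency_hz, sp$frequency_hz, tolerance = 1e-15)
  expect_error(read_spectrum(withr::local_tempfile(lines = "a,b\n1,2")),
               "spectrum CSV")
})
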