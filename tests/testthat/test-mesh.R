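# coarse options keep the mesh tests fast; correctness is size-independent
coarse <- function(...) meshing_options(max_element_size = 2e-6, ...)

test_that("geometry sizing hits the requested area fraction", {
  g <- build_geometry(reference_cell(2), P = 0.035)
  expect_equal(g$W, sqrt(pi * (5e-6)^2 / 0.035), tolerance = 1e-12)
  expect_equal(g$W, 47.37e-6, tolerance = 1e-3)
  ge <- build_geometry(deformed_cell(), P = 0.035)
  expect_equal(ge$W, sqrt(pi * 12e-6 * 2e-6 / 0.035), tolerance = 1e-12)
  expect_equal(ge$W, 46.41e-6, tolerance = 1e-3)
  # exact round trip of the fraction
  expect_equal(area_fraction(g), 0.035, tolerance = 1e-12)
  expect_equal(area_fraction(ge), 0.035, tolerance = 1e-12)
  # an inclusion that cannot fit is rejected with the required minimum
  expect_error(build_geometry(deformed_cell(), P = 0.4), "does not fit")
  expect_error(build_geometry(reference_cell(2), P = 0.7), "area fraction")
})

test_that("generated meshes satisfy the mesh invariants", {
  for (cell in list(reference_cell(2), deformed_cell())) {
    g <- build_geometry(cell, 0.035)
    m <- generate_mesh(g, coarse())
    expect_true(validate_mesh(m))  # conforming, positive areas, boundary
    a <- triangle_areas(m)
    expect_true(all(a > 0))
    expect_equal(sum(a), g$W * g$L, tolerance = 1e-12)
    # all three regions present, membrane band has >= layer count rows
    rc <- region_counts(m)
    counts <- setNames(rc$elements, rc$region)
    expect_true(all(counts[c("medium", "membrane", "cytoplasm")] > 0))
    expect_identical(counts[["total"]],
                     sum(counts[c("medium", "membrane", "cytoplasm")]))
    nseg <- counts[["membrane"]] / (2 * coarse()$membrane_layers)
    expect_identical(counts[["membrane"]],
                     as.integer(2 * nseg * coarse()$membrane_layers))
    # both electrodes tagged
    expect_true(all(c("top_electrode", "bottom_electrode", "side") %in%
                      as.character(m$boundary_edges$tag)))
  }
})

test_that("meshing is deterministic", {
  g <- build_geometry(reference_cell(2), 0.035)
  m1 <- generate_mesh(g, coarse())
  m2 <- generate_mesh(g, coarse())
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$triangles, m2$triangles)
  expect_identical(m1$region, m2$region)
})

test_that("thicker membranes need fewer elements", {
  sizes <- vapply(c(5e-9, 10e-9, 20e-9), function(dm) {
    g <- build_geometry(reference_cell(2, membrane_thickness = dm), 0.035)
    nrow(generate_mesh(g, coarse())$triangles)
  }, 0L)
  expect_true(all(diff(sizes) < 0))
})

test_that("tmesh text format round-trips exactly", {
  m <- generate_mesh(build_geometry(reference_cell(2), 0.035), coarse())
  path <- withr::local_tempfile(fileext = ".tmesh")
  write_mesh(m, path)
  m2 <- read_mesh(path)
  expect_identical(m2$nodes, m$nodes)
  expect_identical(m2$triangles, m$triangles)
  expect_identical(as.character(m2$region), as.character(m$region))
  expect_identical(m2$boundary_edges$tag, m$boundary_edges$tag)
})

test_that("malformed mesh files are rejected with a line number", {
  path <- withr::local_tempfile(lines = c("tmesh 1", "nodes 2", "0 0",
                                          "1 bad"))
  expect_error(read_mesh(path), "line 4")
  path2 <- withr::local_tempfile(lines = c("not a mesh"))
  expect_error(read_mesh(path2), "not a tmesh")
})

test_that("meshes with hanging nodes are rejected", {
  # a 2x2 square split into two triangles, plus a third triangle whose
  # vertex sits in the middle of the shared boundary edge of the square
  lines <- c("tmesh 1",
             "nodes 5",
             "0 0", "1 0", "1 1", "0 1", "0.5 0",
             "triangles 3",
             "0 1 2 medium", "0 2 3 medium", "0 4 2 cytoplasm",
             "boundary 4",
             "0 1 bottom_electrode", "1 2 side", "2 3 top_electrode",
             "3 0 side")
  path <- withr::local_tempfile(lines = lines)
  expect_error(read_mesh(path), "conforming|hanging")
})

test_that("MSH v2 export re-imports with regions and tags preserved", {
  m <- generate_mesh(build_geometry(deformed_cell(), 0.035), coarse())
  path <- withr::local_tempfile(fileext = ".msh")
  write_mesh_msh2(m, path)
  # spot-check the format header
  expect_identical(readLines(path, n = 2), c("$MeshFormat", "2.2 0 8"))
  m2 <- read_mesh(path)
  expect_equal(m2$nodes, m$nodes, tolerance = 1e-15)
  expect_identical(as.character(m2$region), as.character(m$region))
  expect_setequal(paste(m2$boundary_edges$n1, m2$boundary_edges$n2,
                        m2$boundary_edges$tag),
                  paste(m$boundary_edges$n1, m$boundary_edges$n2,
                        m$boundary_edges$tag))
})

test_that("sub-resolution membranes are rejected with advice", {
  cellkm <- cell_model(radius = 5e-3, membrane_thickness = 5e-18,
                       dimension = 2, membrane = material(1e-7, 5),
                       cytoplasm = saline(), medium = saline())
  g <- build_geometry(cellkm, 0.035)
  expect_error(generate_mesh(g, coarse()), "rescale")
})
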