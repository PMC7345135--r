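# canonical single-shell suspension: km = 1e-7 S/m, ka = kc = 1 S/m,
# eps_m = 5, eps_a = eps_c = 80, R = 5 um, dm = 5 nm
reference_cell <- function(dimension = 2, membrane_thickness = 5e-9) {
  cell_model(radius = 5e-6, membrane_thickness = membrane_thickness,
             dimension = dimension,
             membrane = material(1e-7, 5),
             cytoplasm = material(1, 80),
             medium = material(1, 80))
}

# oval (deformed) cell with the same materials, a = 12 um, b = 2 um
deformed_cell <- function() {
  cell_model(a = 12e-6, b = 2e-6, membrane_thickness = 5e-9, dimension = 2,
             membrane = material(1e-7, 5),
             cytoplasm = material(1, 80),
             medium = material(1, 80))
}

# hand-built structured rectangular grid mesh on [0,W]x[0,L] with nx x ny
# nodes; triangles below y = split are tagged `lower`, the rest `upper`
rect_mesh <- function(nx = 3, ny = 3, W = 1, L = 1, split = -Inf,
                      lower = "cytoplasm", upper = "medium") {
  xs <- seq(0, W, length.out = nx)
  ys <- seq(0, L, length.out = ny)
  nodes <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  id <- function(i, j) (j - 1L) * nx + i
  tri <- list(); reg <- character(0)
  for (j in seq_len(ny - 1L)) for (i in seq_len(nx - 1L)) {
    a <- id(i, j); b <- id(i + 1L, j); cc <- id(i + 1L, j + 1L)
    d <- id(i, j + 1L)
    tri[[length(tri) + 1L]] <- c(a, b, cc)
    tri[[length(tri) + 1L]] <- c(a, cc, d)
  }
  triangles <- do.call(rbind, tri)
  cy <- (nodes[triangles[, 1], 2] + nodes[triangles[, 2], 2] +
           nodes[triangles[, 3], 2]) / 3
  region <- ifelse(cy < split, lower, upper)
  be <- list()
  for (i in seq_len(nx - 1L)) {
    be[[length(be) + 1L]] <- c(id(i, 1L), id(i + 1L, 1L), "bottom_electrode")
    be[[length(be) + 1L]] <- c(id(i, ny), id(i + 1L, ny), "top_electrode")
  }
  for (j in seq_len(ny - 1L)) {
    be[[length(be) + 1L]] <- c(id(1L, j), id(1L, j + 1L), "side")
    be[[length(be) + 1L]] <- c(id(nx, j), id(nx, j + 1L), "side")
  }
  bem <- do.call(rbind, be)
  boundary_edges <- data.frame(
    n1 = as.integer(bem[, 1]), n2 = as.integer(bem[, 2]),
    tag = factor(bem[, 3],
                 levels = c("top_electrode", "bottom_electrode", "side")))
  structure(list(nodes = nodes, triangles = triangles,
                 region = factor(region,
                                 levels = c("medium", "membrane",
                                            "cytoplasm")),
                 boundary_edges = boundary_edges, geom = NULL,
                 mid_curve = NULL),
            class = "tri_mesh")
}

# brute-force dense complex FEM solve, independent of the package's
# assembly path: P1 gradients from the inverse of the vertex matrix
dense_potentials <- function(mesh, materials, f, u_top = 10, u_bottom = 0) {
  n <- nrow(mesh$nodes)
  regions <- levels(droplevels(mesh$region))
  sig <- lapply(materials[regions], function(m)
    if (inherits(m, "material"))
      m$conductivity + 1i * 2 * pi * f * 8.8541878128e-12 * m$rel_permittivity
    else as.complex(m))
  K <- matrix(0 + 0i, n, n)
  for (e in seq_len(nrow(mesh$triangles))) {
    idx <- mesh$triangles[e, ]
    V <- cbind(1, mesh$nodes[idx, , drop = FALSE])
    area <- abs(det(V)) / 2
    G <- solve(V)[2:3, , drop = FALSE]     # gradients of the 3 hat functions
    Ke <- sig[[as.character(mesh$region[e])]] * area * (t(G) %*% G)
    K[idx, idx] <- K[idx, idx] + Ke
  }
  be <- mesh$boundary_edges
  top <- unique(c(be$n1[be$tag == "top_electrode"],
                  be$n2[be$tag == "top_electrode"]))
  bottom <- unique(c(be$n1[be$tag == "bottom_electrode"],
                     be$n2[be$tag == "bottom_electrode"]))
  fixed <- c(top, bottom)
  ud <- c(rep(u_top, length(top)), rep(u_bottom, length(bottom)))
  free <- setdiff(seq_len(n), fixed)
  u <- complex(n)
  u[fixed] <- ud
  u[free] <- solve(K[free, free], -K[free, fixed, drop = FALSE] %*% ud)
  u
}

saline <- function() material(1, 80)

# relative comparison of complex vectors in modulus; componentwise
# checks are meaningless when Re and Im differ by orders of magnitude
expect_crel <- function(actual, expected, tol = 1e-12) {
  expect_lt(max(Mod(actual - expected) / pmax(Mod(expected), 1e-300)), tol)
}
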