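#' P1 element stiffness matrix
#'
#' Stiffness contribution of one linear (3-node) triangle with constant
#' complex conductivity: K_e = sigma* (b b' + c c') / (4A), where b and c
#' are the usual shape-function gradient coefficients and A the area.
#'
#' @param coords 3 x 2 matrix of vertex coordinates (m).
#' @param sigma_star Complex conductivity of the element (S/m).
#' @return 3 x 3 complex matrix.
#' @export
element_stiffness <- function(coords, sigma_star) {
  stopifnot(is.matrix(coords), all(dim(coords) == c(3, 2)))
  x <- coords[, 1]; y <- coords[, 2]
  b <- c(y[2] - y[3], y[3] - y[1], y[1] - y[2])
  cc <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1])
  a2 <- (x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1])
  if (a2 <= 0) stop("triangle must have positive (CCW) area", call. = FALSE)
  sigma_star * (outer(b, b) + outer(cc, cc)) / (2 * a2)
}

# per-mesh geometric data reused across frequencies: COO triplet pattern
# of the stiffness matrix with unit conductivity, grouped per element
fem_geometry <- function(mesh) {
  tri <- mesh$triangles
  x1 <- mesh$nodes[tri[, 1], 1]; y1 <- mesh$nodes[tri[, 1], 2]
  x2 <- mesh$nodes[tri[, 2], 1]; y2 <- mesh$nodes[tri[, 2], 2]
  x3 <- mesh$nodes[tri[, 3], 1]; y3 <- mesh$nodes[tri[, 3], 2]
  a2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  b <- cbind(y2 - y3, y3 - y1, y1 - y2)
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1)
  m <- nrow(tri)
  ii <- jj <- matrix(0L, m, 9L)
  gg <- matrix(0, m, 9L)
  col <- 0L
  for (p in 1:3) for (q in 1:3) {
    col <- col + 1L
    ii[, col] <- tri[, p]
    jj[, col] <- tri[, q]
    gg[, col] <- (b[, p] * b[, q] + cc[, p] * cc[, q]) / (2 * a2)
  }
  list(i = as.vector(ii), j = as.vector(jj), g = gg,
       region = mesh$region, n_nodes = nrow(mesh$nodes))
}

# nodes on each electrode
electrode_nodes <- function(mesh, tag) {
  be <- mesh$boundary_edges
  sort(unique(c(be$n1[be$tag == tag], be$n2[be$tag == tag])))
}

#' Define a finite-element problem on a tagged mesh
#'
#' Quasi-static complex-conductivity problem
#' div((sigma + j omega eps) grad U) = 0 with Dirichlet potentials on the
#' top and bottom electrodes and natural (insulating) side walls.
#'
#' @param mesh A `tri_mesh`.
#' @param materials Either a [cell_model()] (its medium / membrane /
#'   cytoplasm materials are mapped onto the mesh regions, honouring an
#'   equivalent-membrane override) or a named list mapping every region
#'   tag present in the mesh to a [material()], a function
#'   `f -> complex sigma*`, or a fixed complex conductivity.
#' @param frequency Frequency in Hz (> 0), scalar.
#' @param u_top,u_bottom Electrode potentials in V (defaults 10 and 0).
#' @return An object of class `fem_problem`.
#' @export
fem_problem <- function(mesh, materials, frequency, u_top = 10,
                        u_bottom = 0) {
  stopifnot(inherits(mesh, "tri_mesh"))
  check_frequency(frequency)
  stopifnot(length(frequency) == 1L)
  present <- levels(droplevels(mesh$region))
  sig <- resolve_materials(materials, present, frequency)
  if (all(Mod(unlist(sig)) == 0))
    stop("all regions have zero complex conductivity", call. = FALSE)
  structure(list(mesh = mesh, sigma = sig, frequency = frequency,
                 u_top = u_top, u_bottom = u_bottom),
            class = "fem_problem")
}

resolve_materials <- function(materials, regions, f) {
  if (inherits(materials, "cell_model"))
    return(region_sigma_star(materials, f)[regions])
  if (!is.list(materials) || is.null(names(materials)))
    stop("'materials' must be a cell_model or a named list", call. = FALSE)
  missing <- setdiff(regions, names(materials))
  if (length(missing))
    stop("no material mapped for region(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- lapply(materials[regions], function(m) {
    if (inherits(m, "material")) complex_conductivity(m, f)
    else if (is.function(m)) as.complex(m(f))
    else as.complex(m)
  })
  stats::setNames(out, regions)
}

#' Assemble the linear system of a FEM problem
#'
#' Piecewise-linear Galerkin assembly with element-constant complex
#' conductivity. The complex-symmetric stiffness matrix K = Kr + i Ki is
#' stored as two real sparse matrices; Dirichlet rows are handled by
#' reduction to the free nodes (the full matrix is kept for reaction
#' currents).
#'
#' @param problem A [fem_problem()].
#' @param geometry Optional precomputed [fem_geometry] data (internal
#'   cache used by [fem_sweep()]).
#' @return An object of class `fem_system`.
#' @export
assemble <- function(problem, geometry = NULL) {
  stopifnot(inherits(problem, "fem_problem"))
  mesh <- problem$mesh
  if (is.null(geometry)) geometry <- fem_geometry(mesh)
  sig <- problem$sigma
  missing <- setdiff(levels(droplevels(geometry$region)), names(sig))
  if (length(missing))
    stop("no material mapped for region(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  se <- unlist(sig)[as.character(geometry$region)]
  n <- geometry$n_nodes
  xr <- as.vector(geometry$g * Re(se))
  xi <- as.vector(geometry$g * Im(se))
  Kr <- Matrix::sparseMatrix(i = geometry$i, j = geometry$j, x = xr,
                             dims = c(n, n))
  Ki <- Matrix::sparseMatrix(i = geometry$i, j = geometry$j, x = xi,
                             dims = c(n, n))
  top <- electrode_nodes(mesh, "top_electrode")
  bottom <- electrode_nodes(mesh, "bottom_electrode")
  if (length(top) == 0L || length(bottom) == 0L)
    stop("singular system: mesh has no electrode (Dirichlet) nodes",
         call. = FALSE)
  fixed <- c(top, bottom)
  u_fixed <- c(rep(problem$u_top, length(top)),
               rep(problem$u_bottom, length(bottom)))
  free <- setdiff(seq_len(n), fixed)
  # right-hand side on free nodes: -K_fd u_d
  rhs <- -complex(
    real = as.numeric(Kr[free, fixed, drop = FALSE] %*% u_fixed),
    imaginary = as.numeric(Ki[free, fixed, drop = FALSE] %*% u_fixed))
  structure(list(Kr = Kr, Ki = Ki, free = free, fixed = fixed,
                 u_fixed = u_fixed, rhs = rhs,
                 top = top, bottom = bottom, problem = problem),
            class = "fem_system")
}

# complex sparse mat-vec using the real/imaginary parts
cmatvec <- function(Kr, Ki, x) {
  xr <- Re(x); xi <- Im(x)
  re <- as.numeric(Kr %*% xr) - as.numeric(Ki %*% xi)
  im <- as.numeric(Kr %*% xi) + as.numeric(Ki %*% xr)
  complex(real = re, imaginary = im)
}

# direct solve of the reduced complex system via the real 2n x 2n block
# embedding [[Kr, -Ki], [Ki, Kr]]; sparse LU plus iterative refinement
solve_direct <- function(system) {
  f <- system$free
  Arr <- system$Kr[f, f, drop = FALSE]
  Aii <- system$Ki[f, f, drop = FALSE]
  B <- rbind(cbind(Arr, -Aii), cbind(Aii, Arr))
  rhs <- c(Re(system$rhs), Im(system$rhs))
  fac <- Matrix::lu(B)
  x <- as.numeric(Matrix::solve(fac, rhs))
  bn <- sqrt(sum(rhs^2))
  for (it in 1:3) {
    r <- rhs - as.numeric(B %*% x)
    if (sqrt(sum(r^2)) <= 1e-15 * bn) break
    x <- x + as.numeric(Matrix::solve(fac, r))
  }
  nf <- length(f)
  complex(real = x[seq_len(nf)], imaginary = x[nf + seq_len(nf)])
}

# Jacobi-preconditioned BiCGSTAB for the reduced complex system
solve_bicgstab <- function(system, x0 = NULL, tol = 1e-10,
                           max_iter = 2000L) {
  f <- system$free
  Arr <- system$Kr[f, f, drop = FALSE]
  Aii <- system$Ki[f, f, drop = FALSE]
  b <- system$rhs
  d <- complex(real = Matrix::diag(Arr), imaginary = Matrix::diag(Aii))
  d[Mod(d) == 0] <- 1
  Av <- function(x) cmatvec(Arr, Aii, x)
  prec <- function(x) x / d
  x <- if (is.null(x0)) rep(0 + 0i, length(b)) else as.complex(x0)
  r <- b - Av(x)
  bnorm <- sqrt(sum(Mod(b)^2))
  if (bnorm == 0) return(list(x = x, iterations = 0L, converged = TRUE,
                              residual = 0))
  r0 <- r
  rho <- alpha <- omega <- 1 + 0i
  v <- p <- rep(0 + 0i, length(b))
  converged <- FALSE
  it <- 0L
  cdot <- function(a, b) sum(Conj(a) * b)
  while (it < max_iter) {
    it <- it + 1L
    rho1 <- cdot(r0, r)
    if (Mod(rho1) < 1e-300) break
    beta <- (rho1 / rho) * (alpha / omega)
    rho <- rho1
    p <- r + beta * (p - omega * v)
    ph <- prec(p)
    v <- Av(ph)
    alpha <- rho / cdot(r0, v)
    s <- r - alpha * v
    if (sqrt(sum(Mod(s)^2)) / bnorm < tol) {
      x <- x + alpha * ph
      converged <- TRUE
      break
    }
    sh <- prec(s)
    t <- Av(sh)
    omega <- cdot(t, s) / cdot(t, t)
    x <- x + alpha * ph + omega * sh
    r <- s - omega * t
    if (sqrt(sum(Mod(r)^2)) / bnorm < tol) { converged <- TRUE; break }
    if (Mod(omega) < 1e-300) break
  }
  res <- sqrt(sum(Mod(b - Av(x))^2)) / bnorm
  list(x = x, iterations = it, converged = converged && res <= 10 * tol,
       residual = res)
}

#' Solve an assembled FEM system
#'
#' The default path is a sparse direct factorization of the
#' complex-symmetric system (via its real block embedding). The
#' `"bicgstab"` path is a Jacobi-preconditioned stabilised bi-conjugate
#' gradient iteration that accepts a warm start (`x0`, typically the
#' previous frequency's solution in a sweep) and falls back to the direct
#' solver, with a message, if it does not reach the residual tolerance.
#'
#' @param system A [assemble()]d `fem_system`.
#' @param method `"direct"` (default) or `"bicgstab"`.
#' @param x0 Optional complex warm-start vector for the free nodes.
#' @param tol Relative residual tolerance.
#' @return An object of class `fem_solution`: complex nodal `potentials`
#'   (full vector; Dirichlet nodes carry exactly the prescribed values),
#'   `frequency`, relative `residual`, `method` actually used and
#'   iteration count.
#' @export
solve_fem <- function(system, method = c("direct", "bicgstab"), x0 = NULL,
                      tol = 1e-10) {
  stopifnot(inherits(system, "fem_system"))
  method <- match.arg(method)
  iterations <- 0L
  used <- method
  if (method == "bicgstab") {
    it <- solve_bicgstab(system, x0 = x0, tol = tol)
    if (it$converged) {
      xf <- it$x
      iterations <- it$iterations
    } else {
      message(sprintf(paste0("bicgstab did not converge after %d iterations ",
                             "(residual %.3g); falling back to direct solve"),
                      it$iterations, it$residual))
      xf <- solve_direct(system)
      used <- "direct (fallback)"
    }
  } else {
    xf <- solve_direct(system)
  }
  rhsn <- sqrt(sum(Mod(system$rhs)^2))
  f <- system$free
  res <- sqrt(sum(Mod(system$rhs -
                        cmatvec(system$Kr[f, f, drop = FALSE],
                                system$Ki[f, f, drop = FALSE], xf))^2)) /
    max(rhsn, .Machine$double.xmin)
  n <- nrow(system$problem$mesh$nodes)
  u <- rep(0 + 0i, n)
  u[system$fixed] <- system$u_fixed
  u[f] <- xf
  structure(list(potentials = u, frequency = system$problem$frequency,
                 residual = res, method = used, iterations = iterations),
            class = "fem_solution")
}

#' @export
print.fem_solution <- function(x, ...) {
  cat(sprintf("<fem_solution> %d nodes at %.4g Hz, %s, rel. residual %.2e\n",
              length(x$potentials), x$frequency, x$method, x$residual))
  invisible(x)
}

#' Total current through the suspension
#'
#' Primary estimator: the reaction of the eliminated Dirichlet rows at
#' the bottom electrode, I = -sum over bottom nodes of (K u); this is
#' exactly conservative in the discrete sense (top and bottom electrode
#' fluxes sum to zero up to solver residual). Units are A per metre of
#' depth (2D convention). Positive current flows from the top electrode
#' to the bottom electrode.
#'
#' @param solution A [solve_fem()] result.
#' @param system The matching `fem_system`.
#' @param electrode `"bottom"` (default) or `"top"`.
#' @return Complex current in A/m.
#' @export
total_current <- function(solution, system, electrode = c("bottom", "top")) {
  stopifnot(inherits(solution, "fem_solution"),
            inherits(system, "fem_system"))
  electrode <- match.arg(electrode)
  r <- cmatvec(system$Kr, system$Ki, solution$potentials)
  if (electrode == "bottom") -sum(r[system$bottom]) else sum(r[system$top])
}

#' Diagnostic current across a horizontal cut line
#'
#' Integrates the vertical component of sigma* grad U along the line
#' y = y0 (elementwise-constant current density times intersected
#' x-extent). By current conservation this should agree with the
#' electrode-reaction estimator on any full horizontal cut; it is exposed
#' as a diagnostic.
#'
#' @param solution A [solve_fem()] result.
#' @param system The matching `fem_system`.
#' @param y0 Height of the cut line in m (default mid-height); must lie
#'   inside the domain.
#' @return Complex current in A/m (positive top-to-bottom).
#' @export
cut_line_current <- function(solution, system, y0 = 0) {
  mesh <- system$problem$mesh
  ymin <- min(mesh$nodes[, 2]); ymax <- max(mesh$nodes[, 2])
  if (y0 <= ymin || y0 >= ymax)
    stop(sprintf("cut line y0 = %g is outside the domain (%g, %g)",
                 y0, ymin, ymax), call. = FALSE)
  # nudge the line off mesh nodes so no element edge lies on it (a cut
  # through a node row would double-count the adjacent element strips)
  H <- ymax - ymin
  while (any(abs(mesh$nodes[, 2] - y0) < 1e-13 * H))
    y0 <- y0 + 1.3e-10 * H
  tri <- mesh$triangles
  u <- solution$potentials
  y <- matrix(mesh$nodes[tri, 2], ncol = 3)
  x <- matrix(mesh$nodes[tri, 1], ncol = 3)
  crossed <- which(apply(y, 1, min) < y0 & apply(y, 1, max) >= y0)
  sig <- unlist(system$problem$sigma)[as.character(mesh$region[crossed])]
  total <- 0 + 0i
  for (idx in seq_along(crossed)) {
    e <- crossed[idx]
    xi <- x[e, ]; yi <- y[e, ]; ui <- u[tri[e, ]]
    a2 <- (xi[2] - xi[1]) * (yi[3] - yi[1]) - (xi[3] - xi[1]) * (yi[2] - yi[1])
    cc <- c(xi[3] - xi[2], xi[1] - xi[3], xi[2] - xi[1])
    dudy <- sum(cc * ui) / a2
    # x-extent of the intersection of y = y0 with the triangle
    xs <- numeric(0)
    for (p in 1:3) {
      q <- if (p < 3) p + 1 else 1
      if ((yi[p] - y0) * (yi[q] - y0) <= 0 && yi[p] != yi[q]) {
        s <- (y0 - yi[p]) / (yi[q] - yi[p])
        xs <- c(xs, xi[p] + s * (xi[q] - xi[p]))
      }
    }
    if (length(xs) >= 2) {
      len <- max(xs) - min(xs)
      total <- total + sig[idx] * dudy * len
    }
  }
  total
}

#' Effective complex conductivity of the suspension
#'
#' Converts the electrode current into the effective property of the
#' whole domain, sigma* = (L / S) (I / U), with L the electrode spacing,
#' S the electrode width times unit depth (2D per-unit-depth convention)
#' and U the electrode voltage difference. The real conductivity and
#' relative permittivity follow from sigma* = sigma_r + j omega eps0
#' eps_r.
#'
#' @param solution A [solve_fem()] result.
#' @param system The matching `fem_system`.
#' @return An object of class `effective_property` with fields
#'   `sigma_star`, `sigma_r`, `eps_r`, `current`, `L`, `S`, `frequency`.
#' @export
effective_conductivity <- function(solution, system) {
  mesh <- system$problem$mesh
  U <- system$problem$u_top - system$problem$u_bottom
  if (U == 0) stop("electrode voltage difference is zero", call. = FALSE)
  xw <- range(mesh$nodes[, 1]); yw <- range(mesh$nodes[, 2])
  L <- diff(yw); S <- diff(xw)
  I <- total_current(solution, system)
  sigma_star <- (L / S) * (I / U)
  w <- 2 * pi * solution$frequency
  structure(list(sigma_star = sigma_star, sigma_r = Re(sigma_star),
                 eps_r = Im(sigma_star) / (w * EPS0), current = I,
                 L = L, S = S, frequency = solution$frequency),
            class = "effective_property")
}

#' @export
print.effective_property <- function(x, ...) {
  cat(sprintf("<effective_property> f = %.4g Hz: sigma_r = %.6g S/m, eps_r = %.6g\n",
              x$frequency, x$sigma_r, x$eps_r))
  invisible(x)
}

#' Frequency sweep of the FEM forward model
#'
#' Re-assembles the system at each frequency (materials, including a
#' frequency-dependent equivalent membrane, are re-evaluated), solves,
#' and collects the effective complex conductivity into a spectrum. The
#' geometric part of the assembly is computed once per mesh. With
#' `method = "bicgstab"` each frequency is warm-started from the previous
#' solution.
#'
#' @param mesh A `tri_mesh`.
#' @param materials As in [fem_problem()].
#' @param frequencies Strictly increasing frequencies in Hz.
#' @param u_top,u_bottom Electrode potentials in V.
#' @param method Solver path, `"direct"` (default) or `"bicgstab"`.
#' @param verbose Emit per-frequency residual logs via [message()].
#' @return A [spectrum()] with attribute `"diagnostics"` (data frame of
#'   residuals, solver path and iterations per frequency).
#' @export
fem_sweep <- function(mesh, materials,
                      frequencies = default_frequencies(),
                      u_top = 10, u_bottom = 0,
                      method = c("direct", "bicgstab"), verbose = FALSE) {
  method <- match.arg(method)
  geometry <- fem_geometry(mesh)
  sig <- vector("complex", length(frequencies))
  diag_ <- data.frame(frequency_hz = frequencies, residual = NA_real_,
                      method = NA_character_, iterations = NA_integer_)
  x0 <- NULL
  for (i in seq_along(frequencies)) {
    prob <- fem_problem(mesh, materials, frequencies[i], u_top, u_bottom)
    sys <- assemble(prob, geometry = geometry)
    sol <- solve_fem(sys, method = method, x0 = x0)
    if (method == "bicgstab") x0 <- sol$potentials[sys$free]
    eff <- effective_conductivity(sol, sys)
    sig[i] <- eff$sigma_star
    diag_$residual[i] <- sol$residual
    diag_$method[i] <- sol$method
    diag_$iterations[i] <- sol$iterations
    if (verbose)
      message(sprintf("f = %.4g Hz: %s, residual %.2e", frequencies[i],
                      sol$method, sol$residual))
  }
  sp <- spectrum(frequencies, sig)
  attr(sp, "diagnostics") <- diag_
  sp
}
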