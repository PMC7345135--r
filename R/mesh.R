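REGION_LEVELS <- c("medium", "membrane", "cytoplasm")
BOUNDARY_LEVELS <- c("top_electrode", "bottom_electrode", "side")

# boundary point / inward-normal samplers for the inclusion outline
outline_point <- function(geom, t) {
  if (geom$shape == "circle") cbind(geom$R * cos(t), geom$R * sin(t))
  else cbind(geom$a * cos(t), geom$b * sin(t))
}

outline_inward_normal <- function(geom, t) {
  if (geom$shape == "circle") return(cbind(-cos(t), -sin(t)))
  nx <- geom$b * cos(t); ny <- geom$a * sin(t)
  nn <- sqrt(nx^2 + ny^2)
  cbind(-nx / nn, -ny / nn)
}

# parameters of the four points whose centre-ray passes through a corner
corner_params <- function(geom) {
  t1 <- if (geom$shape == "circle") pi / 4 else atan2(geom$a, geom$b)
  c(t1, pi - t1, pi + t1, 2 * pi - t1)
}

# arc-length-uniform parameter samples of the outline, with the four
# corner-direction parameters inserted exactly (nearest sample replaced)
outline_params <- function(geom, n) {
  if (geom$shape == "circle") {
    tt <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  } else {
    fine <- seq(0, 2 * pi, length.out = 16384L)
    p <- outline_point(geom, fine)
    seg <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
    cum <- c(0, cumsum(seg))
    target <- cum[length(cum)] * (0:(n - 1L)) / n
    tt <- stats::approx(cum, fine, xout = target, ties = "ordered")$y
  }
  for (tc in corner_params(geom)) {
    d <- abs(tt - tc); d <- pmin(d, 2 * pi - d)
    tt[which.min(d)] <- tc
  }
  sort(tt)
}

# radial size ladder: geometric growth from the band thickness, clamped
# to [smin, smax], accumulated until the largest ray is covered
size_ladder <- function(t0, growth, smin, smax, need) {
  sizes <- numeric(0)
  s <- t0; cum <- 0
  while (cum < need) {
    s <- s * growth
    si <- min(max(s, smin), smax)
    sizes <- c(sizes, si)
    cum <- cum + si
    if (length(sizes) > 1e6)
      stop("radial ladder did not converge; check meshing options",
           call. = FALSE)
  }
  sizes
}

#' Generate a tagged triangular mesh of the suspension domain
#'
#' Deterministic structured "O-grid" triangulation: the inclusion outline
#' is sampled uniformly in arc length (spacing set by
#' `max_element_size`, with the four corner-direction samples inserted
#' exactly so the outer boundary tiles the square); the membrane band is
#' a structured annulus of `membrane_layers` quadrilateral rings split
#' into triangles; inward of the membrane and outward to the square
#' boundary, radial node layers grow geometrically at
#' `max_growth_rate` from the band thickness, clamped to the element-size
#' bounds. Two calls with identical inputs produce identical meshes.
#'
#' @param geom A [build_geometry()] result.
#' @param opts A [meshing_options()].
#' @return An object of class `tri_mesh`: list with `nodes` (N x 2,
#'   metres), `triangles` (M x 3, 1-based, counter-clockwise), `region`
#'   (factor per triangle: medium/membrane/cytoplasm), `boundary_edges`
#'   (data frame `n1`, `n2`, `tag`), and the generating `geom`.
#' @export
generate_mesh <- function(geom, opts = meshing_options()) {
  stopifnot(inherits(geom, "geometry2d"), inherits(opts, "meshing_options"))
  W <- geom$W; L <- geom$L; tb <- geom$t
  if (tb < 64 * .Machine$double.eps * W)
    stop("membrane thickness is below the floating-point resolution of ",
         "node coordinates at this domain size; rescale coordinates",
         call. = FALSE)
  perim <- if (geom$shape == "circle") 2 * pi * geom$R else {
    fine <- seq(0, 2 * pi, length.out = 16384L)
    p <- outline_point(geom, fine)
    sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2))
  }
  n <- max(32L, as.integer(ceiling(perim / opts$max_element_size)))
  tt <- outline_params(geom, n)
  B <- outline_point(geom, tt)              # outer membrane curve
  NV <- outline_inward_normal(geom, tt)
  I <- B + tb * NV                          # inner membrane curve

  # --- medium: rays from B through the square boundary -----------------
  rB <- sqrt(rowSums(B^2))
  u <- B / rB
  s_hit <- (W / 2) / pmax(abs(u[, 1]), abs(u[, 2]))
  Q <- u * s_hit
  # snap onto the square exactly
  snap <- function(q) {
    for (d in 1:2) {
      hit <- abs(abs(q[, d]) - W / 2) <= 1e-9 * W
      q[hit, d] <- sign(q[hit, d]) * W / 2
    }
    q
  }
  Q <- snap(Q)
  dist_out <- s_hit - rB
  lad_out <- size_ladder(tb, opts$max_growth_rate, opts$min_element_size,
                         opts$max_element_size, max(dist_out))
  cum_out <- cumsum(lad_out)
  m_out <- length(lad_out)
  scale_out <- dist_out / cum_out[m_out]

  # --- cytoplasm: scaled copies of the inner curve ----------------------
  rI <- sqrt(rowSums(I^2))
  lad_in <- size_ladder(tb, opts$max_growth_rate, opts$min_element_size,
                        opts$max_element_size, max(rI))
  cum_in <- cumsum(lad_in)
  m_in <- length(lad_in)

  # --- node rings, ordered from the square boundary inward --------------
  rings <- vector("list", (m_out + 1L) + (opts$membrane_layers - 1L) + 1L +
                           (m_in - 1L))
  r <- 0L
  rings[[r <- r + 1L]] <- Q
  if (m_out > 1L) for (i in (m_out - 1L):1L)
    rings[[r <- r + 1L]] <- B + u * (cum_out[i] * scale_out)
  rings[[r <- r + 1L]] <- B
  nl <- opts$membrane_layers
  for (j in seq_len(nl - 1L))
    rings[[r <- r + 1L]] <- B + (tb * j / nl) * NV
  rings[[r <- r + 1L]] <- I
  if (m_in > 1L) for (i in seq_len(m_in - 1L))
    rings[[r <- r + 1L]] <- I * (1 - cum_in[i] / cum_in[m_in])
  nr <- r
  nodes <- do.call(rbind, rings)
  centre_id <- nr * n + 1L
  nodes <- rbind(nodes, c(0, 0))

  # --- triangles ---------------------------------------------------------
  gap_region <- c(rep("medium", m_out), rep("membrane", nl),
                  rep("cytoplasm", m_in - 1L))
  k <- seq_len(n); k2 <- c(seq_len(n)[-1L], 1L)
  tris <- vector("list", nr)
  regs <- vector("list", nr)
  for (g in seq_len(nr - 1L)) {
    o <- (g - 1L) * n; i2 <- g * n
    a <- o + k; b2 <- o + k2; cc <- i2 + k2; d <- i2 + k
    tris[[g]] <- rbind(cbind(a, b2, cc), cbind(a, cc, d))
    regs[[g]] <- rep(gap_region[g], 2L * n)
  }
  o <- (nr - 1L) * n
  tris[[nr]] <- cbind(o + k, o + k2, centre_id)
  regs[[nr]] <- rep("cytoplasm", n)
  triangles <- do.call(rbind, tris)
  dimnames(triangles) <- NULL
  storage.mode(triangles) <- "integer"
  region <- factor(unlist(regs), levels = REGION_LEVELS)

  # enforce counter-clockwise orientation
  a2 <- signed_areas(nodes, triangles)
  flip <- which(a2 < 0)
  if (length(flip))
    triangles[flip, 2:3] <- triangles[flip, 3:2]

  # --- boundary edges on the square --------------------------------------
  n1 <- k; n2 <- k2
  y1 <- nodes[n1, 2]; y2 <- nodes[n2, 2]
  tol <- 1e-7 * W
  tag <- rep("side", n)
  tag[abs(y1 - W / 2) < tol & abs(y2 - W / 2) < tol] <- "top_electrode"
  tag[abs(y1 + W / 2) < tol & abs(y2 + W / 2) < tol] <- "bottom_electrode"
  boundary_edges <- data.frame(n1 = n1, n2 = n2,
                               tag = factor(tag, levels = BOUNDARY_LEVELS))

  mesh <- structure(list(nodes = nodes, triangles = triangles,
                         region = region, boundary_edges = boundary_edges,
                         geom = geom,
                         mid_curve = B + (tb / 2) * NV),
                    class = "tri_mesh")
  validate_mesh(mesh)
  mesh
}

# twice the signed area of each triangle
signed_areas <- function(nodes, triangles) {
  x1 <- nodes[triangles[, 1], 1]; y1 <- nodes[triangles[, 1], 2]
  x2 <- nodes[triangles[, 2], 1]; y2 <- nodes[triangles[, 2], 2]
  x3 <- nodes[triangles[, 3], 1]; y3 <- nodes[triangles[, 3], 2]
  (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
}

#' Triangle areas of a mesh
#' @param mesh A `tri_mesh`.
#' @return Numeric vector of element areas in m^2.
#' @export
triangle_areas <- function(mesh) {
  signed_areas(mesh$nodes, mesh$triangles) / 2
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d nodes, %d triangles (%s)\n",
              nrow(x$nodes), nrow(x$triangles),
              paste(sprintf("%s %d", levels(x$region), table(x$region)),
                    collapse = ", ")))
  invisible(x)
}

#' Validate a triangular mesh
#'
#' Checks index ranges, strictly positive element areas, conformity
#' (every interior edge shared by exactly two triangles, every
#' once-appearing edge present in the boundary list) and the absence of
#' hanging nodes on boundary edges. If the mesh carries its generating
#' geometry, also checks that region areas tile the domain.
#'
#' @param mesh A `tri_mesh`.
#' @return `TRUE` invisibly; otherwise an error describing the defect.
#' @export
validate_mesh <- function(mesh) {
  nodes <- mesh$nodes; tri <- mesh$triangles
  nN <- nrow(nodes)
  if (any(tri < 1L) || any(tri > nN))
    stop("triangle node index out of range", call. = FALSE)
  if (!all(seq_len(nN) %in% tri))
    stop("mesh has unreferenced nodes", call. = FALSE)
  a2 <- signed_areas(nodes, tri)
  if (any(a2 <= 0))
    stop(sprintf("%d triangles have non-positive area", sum(a2 <= 0)),
         call. = FALSE)
  # edge incidence
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt > 2L))
    stop("non-conforming mesh: an edge is shared by more than two triangles",
         call. = FALSE)
  once <- names(cnt)[cnt == 1L]
  be <- mesh$boundary_edges
  bkey <- paste(pmin(be$n1, be$n2), pmax(be$n1, be$n2))
  if (!setequal(once, bkey))
    stop("non-conforming mesh: free edges do not match the boundary list ",
         "(hanging node or missing boundary edge)", call. = FALSE)
  # hanging nodes strictly inside a boundary edge
  if (nrow(be)) {
    p1 <- nodes[be$n1, , drop = FALSE]; p2 <- nodes[be$n2, , drop = FALSE]
    for (i in seq_len(nrow(be))) {
      d <- p2[i, ] - p1[i, ]
      len2 <- sum(d^2)
      s <- ((nodes[, 1] - p1[i, 1]) * d[1] + (nodes[, 2] - p1[i, 2]) * d[2]) /
        len2
      on_seg <- s > 1e-9 & s < 1 - 1e-9
      px <- p1[i, 1] + s * d[1]; py <- p1[i, 2] + s * d[2]
      perp <- (nodes[, 1] - px)^2 + (nodes[, 2] - py)^2
      if (any(on_seg & perp < 1e-18 * len2))
        stop("hanging node detected on a boundary edge", call. = FALSE)
    }
  }
  if (!is.null(mesh$geom)) {
    tot <- sum(a2) / 2
    ref <- mesh$geom$W * mesh$geom$L
    if (abs(tot - ref) > 1e-9 * ref)
      stop("region areas do not tile the domain", call. = FALSE)
  }
  invisible(TRUE)
}

#' Element counts per region
#'
#' Tabulates triangles per region (medium, membrane, cytoplasm, total)
#' and, when the mesh carries its generating geometry, the number of
#' elements whose centroid lies within 5 membrane-thicknesses of the
#' membrane mid-line (the "near-membrane band").
#'
#' @param mesh A `tri_mesh`.
#' @return A data frame with columns `region` and `elements`.
#' @export
region_counts <- function(mesh) {
  tab <- table(mesh$region)
  out <- data.frame(region = c(names(tab), "total"),
                    elements = c(as.integer(tab), nrow(mesh$triangles)))
  if (!is.null(mesh$mid_curve)) {
    tb <- mesh$geom$t
    cx <- (mesh$nodes[mesh$triangles[, 1], 1] +
             mesh$nodes[mesh$triangles[, 2], 1] +
             mesh$nodes[mesh$triangles[, 3], 1]) / 3
    cy <- (mesh$nodes[mesh$triangles[, 1], 2] +
             mesh$nodes[mesh$triangles[, 2], 2] +
             mesh$nodes[mesh$triangles[, 3], 2]) / 3
    # prefilter with the outline's implicit equation before exact
    # point-to-polyline distances
    near <- if (mesh$geom$shape == "circle") {
      rr <- sqrt(cx^2 + cy^2)
      abs(rr - mesh$geom$R) < 20 * tb + mesh$geom$R * 0.05
    } else {
      q <- (cx / mesh$geom$a)^2 + (cy / mesh$geom$b)^2
      q > 0.8 & q < 1.25
    }
    idx <- which(near)
    dmin <- rep(Inf, length(idx))
    mc <- mesh$mid_curve
    nseg <- nrow(mc)
    for (i in seq_len(nseg)) {
      jj <- if (i < nseg) i + 1L else 1L
      d <- mc[jj, ] - mc[i, ]
      len2 <- sum(d^2)
      s <- pmin(1, pmax(0, ((cx[idx] - mc[i, 1]) * d[1] +
                              (cy[idx] - mc[i, 2]) * d[2]) / len2))
      dd <- (cx[idx] - mc[i, 1] - s * d[1])^2 +
        (cy[idx] - mc[i, 2] - s * d[2])^2
      dmin <- pmin(dmin, dd)
    }
    band <- sum(sqrt(dmin) <= 5 * tb)
    out <- rbind(out, data.frame(region = "near_membrane_band",
                                 elements = band))
  }
  out
}

#' Write / read a mesh in the package's plain-text format
#'
#' The `.tmesh` format is line oriented:
#' \preformatted{
#' tmesh 1
#' nodes <N>
#' <x> <y>                       (N lines, metres)
#' triangles <M>
#' <i> <j> <k> <region>          (M lines, 0-based node indices)
#' boundary <B>
#' <n1> <n2> <tag>               (B lines, 0-based node indices)
#' }
#' Node indices are 0-based on disk; in memory R's 1-based convention is
#' used. The write/read round trip is lossless. `read_mesh()` also
#' accepts Gmsh MSH v2 files (see [write_mesh_msh2()]); the format is
#' detected from the file content.
#'
#' @param mesh A `tri_mesh`.
#' @param path File path.
#' @return `read_mesh()` returns a validated `tri_mesh`;
#'   `write_mesh()` returns `path` invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("tmesh 1", con)
  writeLines(sprintf("nodes %d", nrow(mesh$nodes)), con)
  writeLines(sprintf("%.17g %.17g", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("triangles %d", nrow(mesh$triangles)), con)
  writeLines(sprintf("%d %d %d %s", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L,
                     as.character(mesh$region)), con)
  be <- mesh$boundary_edges
  writeLines(sprintf("boundary %d", nrow(be)), con)
  writeLines(sprintf("%d %d %s", be$n1 - 1L, be$n2 - 1L,
                     as.character(be$tag)), con)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  if (length(lines) && startsWith(lines[1], "$MeshFormat"))
    return(read_mesh_msh2_lines(lines))
  ln <- 0L
  fail <- function(msg) stop(sprintf("%s (line %d of %s)", msg, ln, path),
                             call. = FALSE)
  nxt <- function() { ln <<- ln + 1L
    if (ln > length(lines)) fail("unexpected end of file"); lines[ln] }
  hdr <- nxt()
  if (!identical(trimws(hdr), "tmesh 1")) fail("not a tmesh file")
  expect_count <- function(word) {
    f <- strsplit(trimws(nxt()), "\\s+")[[1]]
    if (length(f) != 2L || f[1] != word || is.na(n <- as.integer(f[2])) ||
        n < 0) fail(sprintf("expected '%s <count>'", word))
    n
  }
  nN <- expect_count("nodes")
  nodes <- matrix(NA_real_, nN, 2)
  for (i in seq_len(nN)) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(nxt()), "\\s+")[[1]]))
    if (length(f) != 2L || any(!is.finite(f))) fail("malformed node line")
    nodes[i, ] <- f
  }
  nM <- expect_count("triangles")
  triangles <- matrix(NA_integer_, nM, 3)
  region <- character(nM)
  for (i in seq_len(nM)) {
    f <- strsplit(trimws(nxt()), "\\s+")[[1]]
    if (length(f) != 4L) fail("malformed triangle line")
    idx <- suppressWarnings(as.integer(f[1:3]))
    if (any(is.na(idx))) fail("malformed triangle line")
    if (!f[4] %in% REGION_LEVELS) fail(sprintf("unknown region '%s'", f[4]))
    triangles[i, ] <- idx + 1L
    region[i] <- f[4]
  }
  nB <- expect_count("boundary")
  be <- data.frame(n1 = integer(nB), n2 = integer(nB),
                   tag = character(nB))
  for (i in seq_len(nB)) {
    f <- strsplit(trimws(nxt()), "\\s+")[[1]]
    if (length(f) != 3L) fail("malformed boundary line")
    idx <- suppressWarnings(as.integer(f[1:2]))
    if (any(is.na(idx))) fail("malformed boundary line")
    if (!f[3] %in% BOUNDARY_LEVELS) fail(sprintf("unknown tag '%s'", f[3]))
    be$n1[i] <- idx[1] + 1L; be$n2[i] <- idx[2] + 1L; be$tag[i] <- f[3]
  }
  be$tag <- factor(be$tag, levels = BOUNDARY_LEVELS)
  mesh <- structure(list(nodes = nodes, triangles = triangles,
                         region = factor(region, levels = REGION_LEVELS),
                         boundary_edges = be, geom = NULL, mid_curve = NULL),
                    class = "tri_mesh")
  validate_mesh(mesh)
  mesh
}

# physical-group ids used in the MSH export
MSH_REGION_IDS <- c(medium = 1L, membrane = 2L, cytoplasm = 3L)
MSH_BOUNDARY_IDS <- c(top_electrode = 11L, bottom_electrode = 12L,
                      side = 13L)

#' Export a mesh as Gmsh MSH v2
#'
#' Writes ASCII MSH 2.2 with the three regions as 2D physical groups and
#' the boundary tags as 1D physical groups (named in `$PhysicalNames`).
#'
#' @param mesh A `tri_mesh`.
#' @param path File path.
#' @return `path` invisibly.
#' @export
write_mesh_msh2 <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"), con)
  writeLines("$PhysicalNames", con)
  writeLines(sprintf("%d", length(MSH_REGION_IDS) + length(MSH_BOUNDARY_IDS)),
             con)
  writeLines(sprintf("2 %d \"%s\"", MSH_REGION_IDS, names(MSH_REGION_IDS)),
             con)
  writeLines(sprintf("1 %d \"%s\"", MSH_BOUNDARY_IDS,
                     names(MSH_BOUNDARY_IDS)), con)
  writeLines("$EndPhysicalNames", con)
  writeLines("$Nodes", con)
  writeLines(sprintf("%d", nrow(mesh$nodes)), con)
  writeLines(sprintf("%d %.17g %.17g 0", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines("$EndNodes", con)
  be <- mesh$boundary_edges
  writeLines("$Elements", con)
  writeLines(sprintf("%d", nrow(be) + nrow(mesh$triangles)), con)
  btag <- MSH_BOUNDARY_IDS[as.character(be$tag)]
  writeLines(sprintf("%d 1 2 %d %d %d %d", seq_len(nrow(be)), btag, btag,
                     be$n1, be$n2), con)
  rtag <- MSH_REGION_IDS[as.character(mesh$region)]
  writeLines(sprintf("%d 2 2 %d %d %d %d %d",
                     nrow(be) + seq_len(nrow(mesh$triangles)), rtag, rtag,
                     mesh$triangles[, 1], mesh$triangles[, 2],
                     mesh$triangles[, 3]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

read_mesh_msh2_lines <- function(lines) {
  sect <- function(name) {
    i0 <- match(paste0("$", name), trimws(lines))
    i1 <- match(paste0("$End", name), trimws(lines))
    if (is.na(i0) || is.na(i1) || i1 <= i0)
      stop(sprintf("malformed MSH file: missing $%s section", name),
           call. = FALSE)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- strsplit(trimws(sect("MeshFormat")[1]), "\\s+")[[1]]
  if (substr(fmt[1], 1, 1) != "2")
    stop("only MSH v2 ASCII is supported", call. = FALSE)
  # physical names (optional)
  phys2 <- MSH_REGION_IDS; phys1 <- MSH_BOUNDARY_IDS
  if (any(trimws(lines) == "$PhysicalNames")) {
    pn <- sect("PhysicalNames")[-1L]
    phys2 <- integer(0); phys1 <- integer(0)
    for (l in pn) {
      f <- strsplit(trimws(l), "\\s+")[[1]]
      nm <- gsub('"', "", paste(f[-(1:2)], collapse = " "))
      if (f[1] == "2") phys2[nm] <- as.integer(f[2])
      else phys1[nm] <- as.integer(f[2])
    }
  }
  nd <- sect("Nodes")
  nN <- as.integer(nd[1])
  nm <- do.call(rbind, lapply(nd[1L + seq_len(nN)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  o <- order(nm[, 1])
  nodes <- nm[o, 2:3, drop = FALSE]
  id_map <- integer(max(nm[, 1])); id_map[nm[o, 1]] <- seq_len(nN)
  el <- sect("Elements")
  nE <- as.integer(el[1])
  tri <- list(); reg <- list(); bed <- list()
  r2 <- stats::setNames(names(phys2), phys2)
  r1 <- stats::setNames(names(phys1), phys1)
  for (l in el[1L + seq_len(nE)]) {
    f <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    typ <- f[2]; ntags <- f[3]; ptag <- f[4]
    nn <- f[-(seq_len(3 + ntags))]
    if (typ == 2L) {
      tri[[length(tri) + 1L]] <- id_map[nn]
      reg[[length(reg) + 1L]] <- r2[[as.character(ptag)]]
    } else if (typ == 1L) {
      bed[[length(bed) + 1L]] <- c(id_map[nn], ptag)
    }
  }
  triangles <- do.call(rbind, tri)
  bem <- do.call(rbind, bed)
  be <- data.frame(n1 = bem[, 1], n2 = bem[, 2],
                   tag = factor(r1[as.character(bem[, 3])],
                                levels = BOUNDARY_LEVELS))
  a2 <- signed_areas(nodes, triangles)
  flip <- which(a2 < 0)
  if (length(flip)) triangles[flip, 2:3] <- triangles[flip, 3:2]
  mesh <- structure(list(nodes = nodes, triangles = triangles,
                         region = factor(unlist(reg),
                                         levels = REGION_LEVELS),
                         boundary_edges = be, geom = NULL,
                         mid_curve = NULL),
                    class = "tri_mesh")
  validate_mesh(mesh)
  mesh
}
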