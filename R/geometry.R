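# Computational domain: tetrahedral left-ventricular-wall-like meshes with
# endocardium / epicardium / base surface tags, lumped node volumes and the
# harmonic transmural coordinate used to modulate the intramyocardial pressure.
#
# Coordinates are in mm throughout; conversions to SI happen in the FEM
# assembly only.

new_wall_mesh <- function(nodes, tets, facets, facet_tags) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  tets <- as.matrix(tets); storage.mode(tets) <- "integer"
  dimnames(nodes) <- NULL; dimnames(tets) <- NULL
  tets <- orient_tets(nodes, tets)
  geo <- tet_geometry(nodes, tets)
  nv <- numeric(nrow(nodes))
  add <- geo$volume / 4
  for (a in 1:4) {
    s <- tapply(add, tets[, a], sum)
    nv[as.integer(names(s))] <- nv[as.integer(names(s))] + s
  }
  structure(list(
    nodes = nodes,
    tets = tets,
    facets = facets,                 # F x 3 integer matrix of boundary triangles
    facet_tags = facet_tags,         # character vector, length F
    node_volumes = nv,               # mm^3, lumped
    total_volume = sum(geo$volume),  # mm^3
    transmural = NULL,               # filled by compute_transmural_coordinate
    tet_volume = geo$volume,
    tet_grads = geo$grads            # gradients of P1 basis, 1/mm
  ), class = "wall_mesh")
}

# Per-element P1 geometry: volumes and basis gradients.
tet_geometry <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  p2 <- nodes[tets[, 2], , drop = FALSE]
  p3 <- nodes[tets[, 3], , drop = FALSE]
  p4 <- nodes[tets[, 4], , drop = FALSE]
  a <- p2 - p1; b <- p3 - p1; c <- p4 - p1
  cr <- cbind(
    b[, 2] * c[, 3] - b[, 3] * c[, 2],
    b[, 3] * c[, 1] - b[, 1] * c[, 3],
    b[, 1] * c[, 2] - b[, 2] * c[, 1]
  )
  det6 <- rowSums(a * cr)
  vol <- det6 / 6
  if (any(vol <= 0)) rlang::abort("tet_geometry: inverted or degenerate tetrahedra")
  # gradient of barycentric basis: grad(phi_k) = n_k / (6 V), with n_k the
  # inward-scaled normal of the face opposite node k
  cross3 <- function(u, v) cbind(
    u[, 2] * v[, 3] - u[, 3] * v[, 2],
    u[, 3] * v[, 1] - u[, 1] * v[, 3],
    u[, 1] * v[, 2] - u[, 2] * v[, 1]
  )
  g2 <- cross3(b, c) / det6
  g3 <- cross3(c, a) / det6
  g4 <- cross3(a, b) / det6
  g1 <- -(g2 + g3 + g4)
  list(volume = vol, grads = list(g1, g2, g3, g4))
}

orient_tets <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  a <- nodes[tets[, 2], , drop = FALSE] - p1
  b <- nodes[tets[, 3], , drop = FALSE] - p1
  c <- nodes[tets[, 4], , drop = FALSE] - p1
  det <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
    a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
    a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  flip <- det < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  tets
}

# All boundary faces (those belonging to exactly one tet), as an F x 3 matrix.
boundary_faces <- function(tets) {
  fidx <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  faces <- do.call(rbind, lapply(1:4, function(k) tets[, fidx[k, ], drop = FALSE]))
  key <- apply(faces, 1, function(r) paste(sort(r), collapse = "-"))
  tab <- table(key)
  faces[key %in% names(tab)[tab == 1], , drop = FALSE]
}

# 6-tet decomposition of a structured hex grid, conforming across cells.
hex_to_tets <- function(idx, nx, ny, nz) {
  # idx: function(i,j,k) -> global node id, i in 0..nx, etc.
  cells <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(nz - 1))
  c000 <- idx(cells$i, cells$j, cells$k)
  c100 <- idx(cells$i + 1, cells$j, cells$k)
  c010 <- idx(cells$i, cells$j + 1, cells$k)
  c110 <- idx(cells$i + 1, cells$j + 1, cells$k)
  c001 <- idx(cells$i, cells$j, cells$k + 1)
  c101 <- idx(cells$i + 1, cells$j, cells$k + 1)
  c011 <- idx(cells$i, cells$j + 1, cells$k + 1)
  c111 <- idx(cells$i + 1, cells$j + 1, cells$k + 1)
  rbind(
    cbind(c000, c100, c110, c111),
    cbind(c000, c110, c010, c111),
    cbind(c000, c010, c011, c111),
    cbind(c000, c011, c001, c111),
    cbind(c000, c001, c101, c111),
    cbind(c000, c101, c100, c111)
  )
}

#' Generate an idealized left-ventricular-wall mesh
#'
#' Builds a conforming tetrahedral mesh of one of two idealized wall shapes,
#' with endocardial, epicardial and base surface facets tagged by construction
#' and the harmonic transmural coordinate precomputed:
#' * `"slab"`: a rectangular block `dimensions = c(Lx, Ly, Lz)` (mm) whose
#'   z = 0 face is the endocardium, z = Lz face the epicardium, and the four
#'   lateral faces the base (truncation) surface;
#' * `"half_ellipsoid_shell"`: a truncated half-ellipsoidal shell with inner
#'   semi-axes `dimensions = c(a, b, c)` (mm) and wall `thickness` (mm); the
#'   inner surface is the endocardium, the outer the epicardium, and the
#'   equatorial truncation plane the base.
#'
#' @param shape `"slab"` or `"half_ellipsoid_shell"`.
#' @param dimensions numeric length-3 (mm), see above.
#' @param h target edge length, mm.
#' @param thickness wall thickness for the shell shape, mm.
#' @param seed integer; recorded for provenance (generation is deterministic).
#' @return a `wall_mesh` object.
#' @examples
#' m <- generate_idealized_wall("slab", c(20, 20, 10), h = 4)
#' m$total_volume # 4000 exactly
#' @export
generate_idealized_wall <- function(shape = c("slab", "half_ellipsoid_shell"),
                                    dimensions, h = 1.5, thickness = 10,
                                    seed = 1L) {
  shape <- match.arg(shape)
  dimensions <- as.numeric(dimensions)
  if (length(dimensions) != 3 || any(!is.finite(dimensions)) || any(dimensions <= 0)) {
    rlang::abort("dimensions must be three positive numbers (mm)")
  }
  if (!is.finite(h) || h <= 0) rlang::abort("h must be positive")
  mesh <- if (shape == "slab") {
    generate_slab(dimensions, h)
  } else {
    if (!is.finite(thickness) || thickness <= 0) rlang::abort("thickness must be positive")
    generate_half_ellipsoid_shell(dimensions, thickness, h)
  }
  mesh$shape <- shape
  mesh$seed <- as.integer(seed)
  mesh$transmural <- compute_transmural_coordinate(mesh)
  mesh
}

generate_slab <- function(dims, h) {
  n <- pmax(1L, as.integer(round(dims / h)))
  xs <- seq(0, dims[1], length.out = n[1] + 1)
  ys <- seq(0, dims[2], length.out = n[2] + 1)
  zs <- seq(0, dims[3], length.out = n[3] + 1)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  idx <- function(i, j, k) 1L + i + j * (n[1] + 1L) + k * (n[1] + 1L) * (n[2] + 1L)
  tets <- hex_to_tets(idx, n[1], n[2], n[3])
  faces <- boundary_faces(tets)
  tol <- 1e-9 * max(dims)
  z <- nodes[, 3]
  on_endo <- abs(z) < tol
  on_epi <- abs(z - dims[3]) < tol
  tag_face <- function(f) {
    if (all(on_endo[f])) "endocardium"
    else if (all(on_epi[f])) "epicardium"
    else "base"
  }
  tags <- apply(faces, 1, tag_face)
  new_wall_mesh(nodes, tets, faces, tags)
}

generate_half_ellipsoid_shell <- function(inner, thickness, h) {
  outer <- inner + thickness
  # structured (transmural r, polar phi from apex, azimuth theta) grid
  nr <- max(2L, as.integer(round(thickness / h)))
  nphi <- max(6L, as.integer(round((pi / 2) * mean(inner + thickness / 2) / h)))
  ntheta <- max(24L, as.integer(round(2 * pi * mean(inner[1:2] + thickness / 2) / h)))
  # node ids: apex ring collapses to a single node per r-layer
  # regular nodes: phi index 1..nphi (phi>0), theta 0..(ntheta-1), r 0..nr
  nid <- array(0L, dim = c(ntheta, nphi, nr + 1))
  apex <- integer(nr + 1)
  cnt <- 0L
  coords <- list()
  for (ir in 0:nr) {
    s <- ir / nr
    ax <- (1 - s) * inner + s * outer
    cnt <- cnt + 1L
    apex[ir + 1] <- cnt
    coords[[cnt]] <- c(0, 0, -ax[3])        # apex (phi = 0), z negative
    for (ip in 1:nphi) {
      phi <- (ip / nphi) * (pi / 2)
      for (it in 0:(ntheta - 1)) {
        th <- 2 * pi * it / ntheta
        cnt <- cnt + 1L
        nid[it + 1, ip, ir + 1] <- cnt
        coords[[cnt]] <- c(
          ax[1] * sin(phi) * cos(th),
          ax[2] * sin(phi) * sin(th),
          -ax[3] * cos(phi)
        )
      }
    }
  }
  nodes <- do.call(rbind, coords)
  tets <- list()
  wrap <- function(it) (it %% ntheta) + 1L
  for (ir in 1:nr) for (ip in 1:nphi) for (it in 0:(ntheta - 1)) {
    if (ip == 1) {
      # prism between apex nodes and first phi ring -> 3 tets per theta wedge
      a0 <- apex[ir]; a1 <- apex[ir + 1]
      b0 <- nid[wrap(it), 1, ir]; c0 <- nid[wrap(it + 1), 1, ir]
      b1 <- nid[wrap(it), 1, ir + 1]; c1 <- nid[wrap(it + 1), 1, ir + 1]
      # 3-tet prism split whose quad diagonals match the hex decomposition
      # of the next phi ring and the neighbouring theta wedges
      tets[[length(tets) + 1]] <- rbind(
        c(a0, c0, b0, a1),
        c(c0, b0, a1, c1),
        c(b0, a1, c1, b1)
      )
    } else {
      v000 <- nid[wrap(it), ip - 1, ir];     v100 <- nid[wrap(it + 1), ip - 1, ir]
      v010 <- nid[wrap(it), ip, ir];         v110 <- nid[wrap(it + 1), ip, ir]
      v001 <- nid[wrap(it), ip - 1, ir + 1]; v101 <- nid[wrap(it + 1), ip - 1, ir + 1]
      v011 <- nid[wrap(it), ip, ir + 1];     v111 <- nid[wrap(it + 1), ip, ir + 1]
      tets[[length(tets) + 1]] <- rbind(
        c(v000, v100, v110, v111),
        c(v000, v110, v010, v111),
        c(v000, v010, v011, v111),
        c(v000, v011, v001, v111),
        c(v000, v001, v101, v111),
        c(v000, v101, v100, v111)
      )
    }
  }
  tets <- do.call(rbind, tets)
  faces <- boundary_faces(tets)
  # classify via construction layers
  layer <- integer(nrow(nodes))           # r layer of each node
  for (ir in 0:nr) {
    layer[apex[ir + 1]] <- ir
    layer[as.vector(nid[, , ir + 1])] <- ir
  }
  zb <- nodes[, 3]
  tolz <- 1e-9 * max(outer)
  tag_face <- function(f) {
    if (all(layer[f] == 0L)) "endocardium"
    else if (all(layer[f] == nr)) "epicardium"
    else "base"
  }
  tags <- apply(faces, 1, tag_face)
  bad <- tags == "base" & apply(faces, 1, function(f) any(abs(zb[f]) > tolz))
  if (any(bad)) rlang::abort("shell generation produced untagged interior faces")
  new_wall_mesh(nodes, tets, faces, tags)
}

#' Nodes lying on a tagged boundary surface
#'
#' @param mesh a `wall_mesh`.
#' @param tag one of `"endocardium"`, `"epicardium"`, `"base"`.
#' @return sorted integer vector of node indices.
#' @export
surface_nodes <- function(mesh, tag) {
  sel <- mesh$facet_tags == tag
  sort(unique(as.vector(mesh$facets[sel, , drop = FALSE])))
}

# Sparse P1 stiffness matrix with a per-element scalar coefficient (defaults
# to 1).  Coordinates in mm: entries carry coef * mm (grad in 1/mm, vol mm^3);
# callers scale units as needed.
assemble_stiffness <- function(mesh, coef = 1) {
  nt <- nrow(mesh$tets)
  if (length(coef) == 1) coef <- rep(coef, nt)
  vol <- mesh$tet_volume
  g <- mesh$tet_grads
  ii <- jj <- xx <- vector("list", 16)
  n <- 0
  for (a in 1:4) for (b in 1:4) {
    n <- n + 1
    ii[[n]] <- mesh$tets[, a]
    jj[[n]] <- mesh$tets[, b]
    xx[[n]] <- coef * vol * rowSums(g[[a]] * g[[b]])
  }
  Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(nrow(mesh$nodes), nrow(mesh$nodes))
  )
}

#' Harmonic transmural coordinate
#'
#' Solves the Laplace problem on the wall with lambda = 0 on the endocardium,
#' lambda = 1 on the epicardium and zero flux on the base, with piecewise
#' linear finite elements.  The maximum principle keeps lambda in [0, 1]; on a
#' slab the linear profile depth/thickness is reproduced to solver precision.
#' Nodes tagged on both surfaces are clamped to 0.
#'
#' @param mesh a `wall_mesh`.
#' @return numeric per-node coordinate in [0, 1] (0 endocardium, 1 epicardium).
#' @export
compute_transmural_coordinate <- function(mesh) {
  endo <- surface_nodes(mesh, "endocardium")
  epi <- surface_nodes(mesh, "epicardium")
  if (length(endo) == 0 && length(epi) == 0) {
    rlang::abort("transmural coordinate needs endocardium and epicardium tags")
  }
  # one surface only (e.g. everything tagged endocardial): the harmonic
  # solution is the constant boundary value

  n <- nrow(mesh$nodes)
  K <- assemble_stiffness(mesh)
  lam <- numeric(n)
  lam[epi] <- 1
  lam[endo] <- 0                     # endocardium wins on doubly tagged nodes
  fixed <- sort(unique(c(endo, epi)))
  free <- setdiff(seq_len(n), fixed)
  if (length(free) > 0) {
    rhs <- -K[free, fixed, drop = FALSE] %*% lam[fixed]
    sol <- Matrix::solve(K[free, free], rhs)
    lam[free] <- as.numeric(sol)
  }
  pmin(1, pmax(0, lam))
}

#' @export
print.wall_mesh <- function(x, ...) {
  cat("<wall_mesh>", nrow(x$nodes), "nodes,", nrow(x$tets), "tets,",
      nrow(x$facets), "boundary facets\n")
  cat(sprintf("  total volume %.4g mm^3; tags: %s\n", x$total_volume,
              paste(names(table(x$facet_tags)), table(x$facet_tags),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# Edge list of the tet mesh with Euclidean lengths (mm); used by the eikonal
# territory assignment.
mesh_edges <- function(mesh) {
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  e <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    cbind(mesh$tets[, pairs[k, 1]], mesh$tets[, pairs[k, 2]])
  }))
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  len <- sqrt(rowSums((mesh$nodes[e[, 1], , drop = FALSE] -
                         mesh$nodes[e[, 2], , drop = FALSE])^2))
  list(from = e[, 1], to = e[, 2], length = len)
}

#' Mesh quality summary
#'
#' @param mesh a `wall_mesh`.
#' @return a tibble with tet count, volume, minimum dihedral angle (degrees)
#'   and edge-length range.
#' @export
mesh_quality <- function(mesh) {
  ed <- mesh_edges(mesh)
  # minimum dihedral angle per tet from face normals
  dihedrals <- function(tet) {
    p <- mesh$nodes[tet, ]
    fidx <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
    nrm <- t(apply(fidx, 1, function(f) {
      u <- p[f[2], ] - p[f[1], ]; v <- p[f[3], ] - p[f[1], ]
      c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
    }))
    nrm <- nrm / sqrt(rowSums(nrm^2))
    combs <- utils::combn(4, 2)
    ang <- apply(combs, 2, function(cc) {
      a <- acos(pmin(1, pmax(-1, sum(nrm[cc[1], ] * nrm[cc[2], ]))))
      pi - a
    })
    min(ang)
  }
  ns <- min(nrow(mesh$tets), 500L)   # sample for large meshes
  sel <- unique(as.integer(seq(1, nrow(mesh$tets), length.out = ns)))
  mind <- min(vapply(sel, function(t) dihedrals(mesh$tets[t, ]), numeric(1)))
  tibble::tibble(
    nodes = nrow(mesh$nodes),
    tets = nrow(mesh$tets),
    total_volume_mm3 = mesh$total_volume,
    min_dihedral_deg = mind * 180 / pi,
    min_edge_mm = min(ed$length),
    max_edge_mm = max(ed$length)
  )
}
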