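test_that("slab mesh is exact in volume, tagged, and deterministic", {
  m <- generate_idealized_wall("slab", c(20, 20, 10), h = 1.5, seed = 3)
  expect_equal(m$total_volume, 4000, tolerance = 1e-12)
  expect_equal(sum(m$node_volumes), m$total_volume, tolerance = 1e-10)
  expect_setequal(unique(m$facet_tags), c("endocardium", "epicardium", "base"))
  # every boundary facet carries exactly one tag by construction
  expect_equal(length(m$facet_tags), nrow(m$facets))
  m2 <- generate_idealized_wall("slab", c(20, 20, 10), h = 1.5, seed = 3)
  expect_identical(m$nodes, m2$nodes)
  expect_identical(m$tets, m2$tets)
  expect_error(generate_idealized_wall("slab", c(20, -1, 10), h = 1.5), "positive")
  expect_error(generate_idealized_wall("slab", c(20, 20, 10), h = 0), "positive")
})

test_that("half-ellipsoid shell volume converges to the closed form", {
  inner <- c(20, 20, 40); th <- 10
  va <- 2 * pi / 3 * (prod(inner + th) - prod(inner))
  m <- generate_idealized_wall("half_ellipsoid_shell", inner, h = 3, thickness = th)
  expect_lt(abs(m$total_volume - va) / va, 0.02)
  # refinement moves the polyhedral volume monotonically toward the analytic one
  m2 <- generate_idealized_wall("half_ellipsoid_shell", inner, h = 1.5, thickness = th)
  expect_lt(abs(m2$total_volume - va), abs(m$total_volume - va))
  expect_lt(m$total_volume, va)   # inscribed polyhedron
  q <- mesh_quality(m)
  expect_gt(q$min_dihedral_deg, 1)
  expect_true(all(m$tet_volume > 0))  # no inverted tets
})

test_that("transmural coordinate solves the Laplace problem between tagged surfaces", {
  m <- test_slab()
  # slab: piecewise-linear elements reproduce the linear profile exactly
  expect_lt(max(abs(m$transmural - m$nodes[, 3] / 10)), 1e-10)
  expect_true(all(m$transmural >= 0 & m$transmural <= 1))
  expect_equal(m$transmural[surface_nodes(m, "endocardium")],
               rep(0, length(surface_nodes(m, "endocardium"))))
  expect_equal(m$transmural[surface_nodes(m, "epicardium")],
               rep(1, length(surface_nodes(m, "epicardium"))))
  # concentric shell: harmonic solution is radially monotone along node rays
  sh <- generate_idealized_wall("half_ellipsoid_shell", c(20, 20, 20), h = 4,
                                thickness = 8)
  r <- sqrt(rowSums(sh$nodes^2))
  # bin nodes by direction and check lambda increases with radius
  dirs <- round(sh$nodes / pmax(r, 1e-9), 2)
  key <- apply(dirs, 1, paste, collapse = ",")
  for (k in unique(key)[1:20]) {
    sel <- which(key == k)
    if (length(sel) >= 3) {
      o <- order(r[sel])
      expect_true(all(diff(sh$transmural[sel][o]) >= -1e-8))
    }
  }
  # degenerate tagging: everything endocardial -> identically zero
  m0 <- m
  m0$facet_tags[m0$facet_tags == "epicardium"] <- "endocardium"
  expect_equal(compute_transmural_coordinate(m0), rep(0, nrow(m0$nodes)))
})

test_that("VTU round-trip preserves connectivity, tags and nodal fields", {
  m <- generate_idealized_wall("slab", c(10, 10, 5), h = 2.5)
  f <- withr::local_tempfile(fileext = ".vtu")
  write_vtu(m, f, point_data = list(demo = seq_len(nrow(m$nodes)) * 1.0))
  m2 <- read_wall_mesh(f)
  expect_equal(m2$nodes, m$nodes, tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(m2$tets, m$tets)
  expect_identical(sort(m2$facet_tags), sort(m$facet_tags))
  expect_equal(m2$total_volume, m$total_volume, tolerance = 1e-9)
  expect_equal(m2$transmural, m$transmural, tolerance = 1e-8)
})

test_that("mesh readers reject unsupported or incompletely tagged files", {
  m <- generate_idealized_wall("slab", c(10, 10, 5), h = 2.5)
  f <- withr::local_tempfile(fileext = ".vtu")
  write_vtu(m, f)
  # drop the base facets: reader must name the missing tag
  txt <- readLines(f)
  tagline <- grep("surface_tag", txt)[1] + 1
  txt[tagline] <- gsub("\\b3\\b", "2", txt[tagline])
  writeLines(txt, f)
  expect_error(read_wall_mesh(f), "base")
  # a hex cell (VTK type 12) is unsupported
  f2 <- withr::local_tempfile(fileext = ".vtu")
  write_vtu(m, f2)
  txt <- readLines(f2)
  typeline <- grep('Name="types"', txt) + 1
  txt[typeline] <- sub("^10", "12", txt[typeline])
  writeLines(txt, f2)
  expect_error(read_wall_mesh(f2), "cell type")
  expect_error(read_wall_mesh("no/such/file.vtu"), "not found")
})

test_that("a minimal Gmsh 4.1 file with physical surface names is read", {
  # single unit tet, one tagged triangle per surface
  msh <- c(
    "$MeshFormat", "4.1 0 8", "$EndMeshFormat",
    "$PhysicalNames", "3",
    '2 1 "endocardium"', '2 2 "epicardium"', '2 3 "base"',
    "$EndPhysicalNames",
    "$Entities", "0 0 3 1",
    "1 0 0 0 1 1 1 1 1", "2 0 0 0 1 1 1 1 2", "3 0 0 0 1 1 1 1 3",
    "1 0 0 0 1 1 1 0 3 1 2 3",
    "$EndEntities",
    "$Nodes", "1 4 1 4",
    "3 1 0 4", "1", "2", "3", "4",
    "0 0 0", "1 0 0", "0 1 0", "0 0 1",
    "$EndNodes",
    "$Elements", "4 4 1 4",
    "2 1 2 1", "1 1 2 3",
    "2 2 2 1", "2 1 2 4",
    "2 3 2 1", "3 1 3 4",
    "3 1 4 1", "4 1 2 3 4",
    "$EndElements"
  )
  f <- withr::local_tempfile(fileext = ".msh")
  writeLines(msh, f)
  m <- read_wall_mesh(f)
  expect_equal(nrow(m$tets), 1)
  expect_equal(m$total_volume, 1 / 6, tolerance = 1e-12)
  expect_setequal(m$facet_tags, c("endocardium", "epicardium", "base"))
})
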