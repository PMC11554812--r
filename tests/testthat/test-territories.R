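test_that("outlet projection picks nearest nodes with deterministic tie-breaks", {
  m <- test_rod()
  # outlet exactly at a node
  ot <- outlet_table(1, x = 3, y = 0, z = 0, radius = 1)
  s <- project_outlets(m, ot)
  expect_equal(unname(m$nodes[s, ]), c(3, 0, 0))
  # equidistant between x = 3 and x = 4: lowest node index wins
  ot2 <- outlet_table(1, x = 3.5, y = 0, z = 0, radius = 1)
  s2 <- project_outlets(m, ot2)
  d2 <- (m$nodes[, 1] - 3.5)^2 + m$nodes[, 2]^2 + m$nodes[, 3]^2
  expect_equal(s2, which(d2 == min(d2))[1])
  # colliding outlets: second falls back to a distinct node with a warning
  ot3 <- outlet_table(1:2, x = c(3, 3), y = 0, z = 0, radius = 1)
  expect_warning(s3 <- project_outlets(m, ot3), "next-nearest")
  expect_equal(length(unique(s3)), 2)
  expect_error(project_outlets(m, ot3[0, ]), "empty")
})

test_that("rod eikonal distances scale with the outlet radius", {
  m <- test_rod()
  axis <- which(m$nodes[, 2] == 0 & m$nodes[, 3] == 0)
  axis <- axis[order(m$nodes[axis, 1])]
  seed <- axis[1]
  d1 <- modified_eikonal(m, seed, r = 1)
  expect_equal(d1[axis], m$nodes[axis, 1], tolerance = 1e-12)
  d2 <- modified_eikonal(m, seed, r = 2)
  expect_equal(d2[axis], m$nodes[axis, 1] / 2, tolerance = 1e-12)
  expect_equal(d2, d1 / 2, tolerance = 1e-12)
  expect_error(modified_eikonal(m, seed, r = 0), "radius")
})

test_that("graph distances equal the brute-force all-pairs oracle on small meshes", {
  m <- generate_idealized_wall("slab", c(4, 2, 2), h = 2)   # 18 nodes
  ed <- myoperf:::mesh_edges(m)
  D <- floyd_warshall(nrow(m$nodes), ed$from, ed$to, ed$length)
  for (seed in seq_len(nrow(m$nodes))) {
    expect_equal(modified_eikonal(m, seed, r = 1), D[seed, ], tolerance = 1e-12)
  }
  # and for a non-unit radius
  expect_equal(modified_eikonal(m, 5, r = 2.5), D[5, ] / 2.5, tolerance = 1e-12)
})

test_that("territories partition the domain and conserve volume", {
  m <- test_slab()
  ot <- test_outlets()
  tm <- assign_territories(m, ot)
  expect_equal(sort(unique(tm$label)), 1:4)
  expect_equal(rowSums(tm$indicator), rep(1, nrow(m$nodes)))
  expect_equal(sum(tm$volumes$volume_mm3), m$total_volume, tolerance = 1e-10)
  expect_equal(colSums(tm$indicator * m$node_volumes),
               tm$volumes$volume_mm3, ignore_attr = TRUE)
  # single outlet claims everything
  tm1 <- assign_territories(m, ot[1, ])
  expect_equal(tm1$volumes$volume_mm3, m$total_volume)
})

test_that("two-outlet rod boundary follows the modified-distance equality", {
  m <- test_rod()
  # equal radii: symmetric split at x = 5
  ot <- outlet_table(1:2, x = c(0, 10), y = 0, z = 0, radius = c(1, 1))
  tm <- assign_territories(m, ot)
  xs <- m$nodes[, 1]
  expect_true(all(tm$label[xs < 5 - 1e-9] == 1))
  expect_true(all(tm$label[xs > 5 + 1e-9] == 2))
  # midpoint ties to the lower outlet id
  expect_true(all(tm$label[abs(xs - 5) < 1e-9] == 1))
  expect_equal(tm$volumes$volume_mm3[1] - tm$volumes$volume_mm3[2],
               sum(m$node_volumes[abs(xs - 5) < 1e-9]))
  # radii (1, 2): boundary at x = 10/3, so B's territory is larger
  ot2 <- outlet_table(1:2, x = c(0, 10), y = 0, z = 0, radius = c(1, 2))
  tm2 <- assign_territories(m, ot2)
  expect_equal(max(xs[tm2$label == 1]), 3)
  expect_equal(min(xs[tm2$label == 2]), 4)
  expect_gt(tm2$volumes$volume_mm3[2], tm2$volumes$volume_mm3[1])
})

test_that("enlarging an outlet radius never shrinks its territory", {
  set.seed(11)
  m <- test_slab()
  for (trial in 1:5) {
    ot <- outlet_table(
      1:3,
      x = stats::runif(3, 2, 18), y = stats::runif(3, 2, 18), z = 10,
      radius = stats::runif(3, 0.5, 1.5)
    )
    tm <- assign_territories(m, ot)
    ot_big <- ot
    ot_big$radius[1] <- ot$radius[1] * 2
    tm_big <- assign_territories(m, ot_big)
    expect_gte(tm_big$volumes$volume_mm3[1], tm$volumes$volume_mm3[1])
    # nodewise: territory 1 only grows
    expect_true(all(tm_big$label[tm$label == 1] == 1))
  }
})

test_that("euclidean legacy mode ignores radii", {
  m <- test_rod()
  ot <- outlet_table(1:2, x = c(0, 10), y = 0, z = 0, radius = c(1, 4))
  tm_e <- assign_territories_euclidean(m, ot)
  xs <- m$nodes[, 1]
  expect_true(all(tm_e$label[xs < 5 - 1e-9] == 1))
  expect_true(all(tm_e$label[xs > 5 + 1e-9] == 2))
  tm_r <- assign_territories(m, ot)
  expect_gt(sum(tm_r$label == 2), sum(tm_e$label == 2))
})
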