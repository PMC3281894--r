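test_that("grid graphs use the mean-resistance edge rule with sqrt(2) diagonals", {
  g12 <- build_grid_graph(surf(matrix(c(1, 3), 1, 2), cellsize = 10), 8)
  expect_equal(length(g12$from), 1)
  expect_equal(g12$resistance, 2)
  expect_equal(g12$cost, 20)

  u33 <- build_grid_graph(surf(matrix(1, 3, 3)), 8)
  expect_equal(length(u33$from), 20) # 12 orthogonal + 8 diagonal
  expect_equal(sort(unique(round(u33$resistance, 10))),
               c(1, round(sqrt(2), 10)))
  expect_equal(length(build_grid_graph(surf(matrix(1, 3, 3)), 4)$from), 12)

  hole <- matrix(1, 3, 3); hole[2, 2] <- NA
  gh <- build_grid_graph(surf(hole), 8)
  expect_equal(gh$n, 8)
  expect_equal(length(gh$from), 20 - 8) # no edges incident to the centre
  expect_error(build_grid_graph(surf(matrix(1, 2, 2)), 6), "4 or 8")
})

test_that("least-cost distances match closed forms and an exhaustive oracle", {
  # 1x3 uniform strip: two unit steps
  strip <- surf(matrix(1, 1, 3))
  s <- sites_at_cells(strip, c(1, 1), c(1, 3))
  expect_equal(least_cost_distances(strip, s)[1, 2], 2)

  # octile metric on a uniform grid: offset (3, 4) -> 3*sqrt(2) + 1
  u <- surf(matrix(1, 10, 10))
  s2 <- sites_at_cells(u, c(2, 5), c(2, 6))
  expect_equal(least_cost_distances(u, s2)[1, 2], 3 * sqrt(2) + 1)

  # random heterogeneous surfaces vs Floyd-Warshall
  set.seed(42)
  for (rep in 1:3) {
    m <- random_surface(6, 6, c(1, 5))
    sr <- surf(m, cellsize = 2)
    cells <- cbind(sample(6, 4, TRUE), sample(6, 4, TRUE))
    st <- sites_at_cells(sr, cells[, 1], cells[, 2])
    got <- least_cost_distances(sr, st)
    D <- fw_all_pairs(m, cellsize = 2)
    idx <- (cells[, 1] - 1) * 6 + cells[, 2]
    expect_equal(unclass(got), D[idx, idx], ignore_attr = TRUE,
                 tolerance = 1e-12)
  }

  # octile bound: LCP / Euclidean within [1, sqrt(2) - ... = 1.0824]
  set.seed(8)
  su <- surf(matrix(1, 40, 40))
  stu <- as_sites(data.frame(id = paste0("s", 1:8),
                             x = runif(8, 1, 39), y = runif(8, 1, 39)))
  lcp <- least_cost_distances(su, stu)
  geo <- geographic_distances(stu)
  # compare cell-centre to cell-centre geometry (sites snap to centres)
  rc <- cell_of_xy(su, stu$x, stu$y)
  snapped <- sites_at_cells(su, rc$row, rc$col, stu$id)
  geos <- geographic_distances(snapped)
  ratio <- lcp[upper.tri(lcp)] / geos[upper.tri(geos)]
  expect_true(all(ratio >= 1 - 1e-12))
  expect_true(all(ratio <= 2 * sqrt(2 - sqrt(2)) + 1e-12)) # 1.08239
})

test_that("disconnected site pairs get infinite distance", {
  m <- matrix(1, 3, 3); m[, 2] <- NA
  sp <- surf(m)
  s <- sites_at_cells(sp, c(2, 2), c(1, 3))
  expect_warning(d <- least_cost_distances(sp, s), "not connected")
  expect_identical(d[1, 2], Inf)
  expect_warning(r <- effective_resistances(sp, s), "not connected")
  expect_identical(r[1, 2], Inf)
})

test_that("effective resistances match series/parallel closed forms", {
  pair <- surf(matrix(1, 1, 2))
  s <- sites_at_cells(pair, c(1, 1), c(1, 2))
  expect_equal(effective_resistances(pair, s, 4)[1, 2], 1)

  quad <- surf(matrix(1, 1, 4))
  s4 <- sites_at_cells(quad, c(1, 1), c(1, 4))
  expect_equal(effective_resistances(quad, s4, 4)[1, 2], 3) # series law

  sq <- surf(matrix(1, 2, 2))
  sd <- sites_at_cells(sq, c(1, 2), c(1, 2))
  # two parallel two-resistor paths between diagonal corners
  expect_equal(effective_resistances(sq, sd, 4)[1, 2], 1)
})

test_that("effective resistances agree with the dense pseudo-inverse oracle", {
  set.seed(19)
  for (rep in 1:3) {
    m <- random_surface(8, 8, c(1, 2, 10))
    if (rep == 3) m[2, 2] <- NA
    sr <- surf(m)
    res <- dense_effective_resistance(m, neighbours = 8)
    cells <- rbind(c(1, 1), c(8, 8), c(4, 5), c(8, 1))
    st <- sites_at_cells(sr, cells[, 1], cells[, 2])
    got <- effective_resistances(sr, st, 8)
    for (i in 1:3) for (j in (i + 1):4)
      expect_equal(got[i, j],
                   res(cells[i, 1], cells[i, 2], cells[j, 1], cells[j, 2]),
                   tolerance = 1e-9)
  }
})

test_that("effective resistance is a metric and obeys Rayleigh monotonicity", {
  set.seed(77)
  m <- random_surface(7, 7, c(1, 4, 9))
  sr <- surf(m)
  cells <- cbind(sample(7, 5, TRUE), sample(7, 5, TRUE))
  st <- sites_at_cells(sr, cells[, 1], cells[, 2],
                       ids = paste0("s", 1:5))
  R <- effective_resistances(sr, st)
  expect_equal(unclass(R), t(unclass(R)), ignore_attr = TRUE)
  expect_true(all(diag(R) == 0))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(R[i, j], R[i, k] + R[k, j] + 1e-10)
  # lowering one cell's resistance can never increase any pairwise value
  m2 <- m
  hot <- which(m == max(m))[1]
  m2[hot] <- 1
  R2 <- effective_resistances(surf(m2), st)
  expect_true(all(R2 <= R + 1e-10))
})

test_that("circuit distance is bounded above by least-cost distance", {
  # with cellsize 1 the edge electrical resistance equals the traversal
  # cost, and current through all paths can only lower the distance
  set.seed(3)
  m <- random_surface(8, 8, c(1, 3))
  sr <- surf(m)
  cells <- cbind(sample(8, 5, TRUE), sample(8, 5, TRUE))
  st <- sites_at_cells(sr, cells[, 1], cells[, 2])
  lcp <- least_cost_distances(sr, st)
  ibr <- effective_resistances(sr, st)
  expect_true(all(ibr <= lcp + 1e-10))
})

test_that("edge-effect curves reproduce the boundary inflation pattern", {
  ee <- edge_effect_experiment(40, separations = c(5, 15),
                               offsets = c(1, 3, 6, 10, 16, 24))
  for (s in unique(ee$separation)) {
    cur <- ee[ee$separation == s, ]
    cur <- cur[order(cur$offset), ]
    # resistance non-increasing as the pair moves away from the edge
    expect_true(all(diff(cur$resistance) <= 1e-10))
  }
  # the larger separation carries a stronger, farther-reaching edge
  # effect: its excess over the deep-interior value stays higher
  s5 <- ee[ee$separation == 5, ]; s15 <- ee[ee$separation == 15, ]
  ex5 <- s5$resistance - min(s5$resistance)
  ex15 <- s15$resistance - min(s15$resistance)
  expect_true(all(ex15 >= ex5 - 1e-10))

  # dense-oracle agreement on a small disc
  r <- 12
  n <- 2 * r + 1
  dd <- sqrt(outer((1:n - (r + 1))^2, (1:n - (r + 1))^2, "+"))
  m <- ifelse(dd <= r, 1, NA)
  res <- dense_effective_resistance(m, neighbours = 8)
  ee2 <- edge_effect_experiment(r, separations = 4, offsets = c(1, 4))
  ctr <- r + 1
  for (k in seq_len(nrow(ee2))) {
    near <- ctr + r - ee2$offset[k]
    far <- near - ee2$separation[k]
    expect_equal(ee2$resistance[k], res(ctr, near, ctr, far),
                 tolerance = 1e-8)
  }
  expect_error(edge_effect_experiment(10, separations = 25, offsets = 0),
               "fit inside")
})

test_that("interior disc resistance grows with log-separation", {
  # far from the boundary the two-dimensional lattice Green's function
  # gives near-logarithmic growth, the basis for the logGEOG null
  ee <- edge_effect_experiment(45, separations = c(2, 4, 8, 16),
                               offsets = 37) # pairs centred in the disc
  r_lin <- cor(ee$resistance, ee$separation)
  r_log <- cor(ee$resistance, log(ee$separation))
  expect_gt(r_log, r_lin)
})

test_that("the model suite is complete and consistently ordered", {
  set.seed(6)
  sim <- simulate_landcover(0.4, "dispersed", extent = 750, cellsize = 25,
                            seed = 31)
  sites <- simulate_sites(sim$landcover, 4, seed = 32)
  reg <- region_from_grid(sim$landcover)
  surfs <- list(tree_surface(sim$tree, 5, reg),
                tree_surface(sim$tree, 10, reg),
                uniform_surface(reg))
  suite <- run_model_suite(surfs, sites, reg)
  expect_equal(length(suite), 9) # 3 x 2 + GEOG + logGEOG + CS_UNIFORM
  expect_setequal(names(suite),
                  c("TREE_1_5_LCP", "TREE_1_5_IBR", "TREE_1_10_LCP",
                    "TREE_1_10_IBR", "UNIFORM_LCP", "UNIFORM_IBR",
                    "GEOG", "logGEOG", "CS_UNIFORM"))
  for (m in suite) expect_identical(rownames(m), sites$id)
  empty <- run_model_suite(list(), sites, reg)
  expect_setequal(names(empty), c("GEOG", "logGEOG", "CS_UNIFORM"))
  # CS_UNIFORM is the circuit distance of the uniform surface
  expect_equal(unclass(empty$CS_UNIFORM), unclass(suite$UNIFORM_IBR),
               ignore_attr = TRUE)
})
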