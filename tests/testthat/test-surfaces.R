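make_region <- function(nr = 10, nc = 10, cellsize = 25) {
  region_from_grid(grid_create(matrix(1, nr, nc), cellsize = cellsize))
}

test_that("uniform surface fills the inside set with one value", {
  reg <- make_region(8, 9)
  u <- uniform_surface(reg)
  expect_equal(u$model, "UNIFORM")
  expect_true(all(u$values == 1))
  # counting oracle on a clipped region
  tmpl <- grid_create(matrix(1, 15, 15), cellsize = 10)
  s <- data.frame(id = "a", x = 75, y = 75)
  reg2 <- build_study_region(s, buffer = 40, template = tmpl)
  u2 <- uniform_surface(reg2, value = 1)
  expect_equal(sum(u2$values, na.rm = TRUE),
               sum(!is.na(reg2$mask$values)))
  expect_identical(is.na(u2$values), is.na(reg2$mask$values))
  expect_error(uniform_surface(reg, value = 0), "> 0")
})

test_that("tree-cover generalization keeps any cell holding a tree pixel centre", {
  z <- grid_create(matrix(0, 10, 10), cellsize = 10)
  expect_true(all(generalize_tree_cover(z, 25)$values == 0))

  one <- matrix(0, 10, 10)
  one[3, 7] <- 1 # pixel centre at x = 65, y = 75
  g1 <- generalize_tree_cover(grid_create(one, cellsize = 10), 25)
  expect_equal(sum(g1$values), 1)
  expect_equal(g1$values[g1$nrows - floor(75 / 25), floor(65 / 25) + 1], 1)

  # brute-force per-pixel assignment oracle, non-integer 10 m -> 25 m
  set.seed(7)
  m <- matrix(rbinom(900, 1, 0.2), 30, 30)
  fine <- grid_create(m, xll = 40, yll = -20, cellsize = 10)
  coarse <- generalize_tree_cover(fine, 25)
  oracle <- matrix(0, coarse$nrows, coarse$ncols)
  cc <- cell_centres(fine)
  for (k in seq_len(nrow(cc))) {
    if (m[cc$row[k], cc$col[k]] != 1) next
    col <- floor((cc$x[k] - fine$xll) / 25) + 1
    rowS <- floor((cc$y[k] - fine$yll) / 25)
    oracle[coarse$nrows - rowS, col] <- 1
  }
  expect_equal(coarse$values, oracle)
  # monotone: adding tree pixels never removes coarse tree cells
  m2 <- m; m2[sample(which(m == 0), 40)] <- 1
  coarse2 <- generalize_tree_cover(grid_create(m2, xll = 40, yll = -20,
                                               cellsize = 10), 25)
  expect_true(all(coarse2$values >= coarse$values))
  expect_error(generalize_tree_cover(grid_create(m * 3, cellsize = 10)),
               "binary")
})

test_that("scattered-tree rule follows centre-to-centre distance and is idempotent", {
  cls <- landcover_classes()
  lc <- matrix(cls[["improved"]], 7, 7)
  tr <- matrix(0, 7, 7)
  tr[4, 4] <- 1
  lc[4, 4] <- cls[["tree"]]
  lcg <- grid_create(lc, cellsize = 25)
  trg <- grid_create(tr, cellsize = 25)
  out <- classify_scattered_trees(lcg, trg, radius = 50)
  # centre distances from the tree cell: 25 (orth), 35.36 (diag), 50
  # (2 steps orth) are within 50 m; 55.9 and beyond are not
  d <- sqrt(outer((1:7 - 4)^2, (1:7 - 4)^2, "+")) * 25
  want <- ifelse(d == 0, cls[["tree"]],
                 ifelse(d <= 50, cls[["improved_scattered"]],
                        cls[["improved"]]))
  expect_equal(out$values, want)
  # the tree cell itself is never reassigned
  expect_equal(out$values[4, 4], cls[["tree"]])
  # no trees -> unchanged; idempotent
  expect_equal(classify_scattered_trees(lcg, grid_create(tr * 0,
                                                         cellsize = 25))$values,
               lc)
  expect_equal(classify_scattered_trees(out, trg, radius = 50)$values,
               out$values)
  expect_error(classify_scattered_trees(lcg, grid_create(tr, cellsize = 10)),
               "co-registered")
})

test_that("tree surfaces map resistances and dominate monotonically", {
  set.seed(21)
  tr <- grid_create(matrix(rbinom(100, 1, 0.4), 10, 10), cellsize = 25)
  reg <- make_region(10, 10)
  s5 <- tree_surface(tr, 5, reg)
  expect_equal(s5$model, "TREE_1_5")
  expect_true(all(s5$values[tr$values == 1] == 1))
  expect_true(all(s5$values[tr$values == 0] == 5))
  expect_equal(sum(s5$values == 5), sum(tr$values == 0))
  surfs <- lapply(c(2, 5, 10, 100), function(k) tree_surface(tr, k, reg))
  for (i in 1:3)
    expect_true(all(surfs[[i]]$values <= surfs[[i + 1]]$values))
  # all-tree landscape collapses to the uniform surface
  allt <- grid_create(matrix(1, 10, 10), cellsize = 25)
  expect_true(all(tree_surface(allt, 10, reg)$values == 1))
  expect_error(tree_surface(tr, 1, reg), "> 1")
  expect_warning(tree_surface(tr, 7, reg), "canonical")
})

test_that("SDM binarization maximizes Youden's J with lower-threshold ties", {
  g <- grid_create(matrix(seq(0, 1, length.out = 100), 10, 10),
                   cellsize = 10)
  hi <- which(g$values >= 0.9, arr.ind = TRUE)
  lo <- which(g$values <= 0.1, arr.ind = TRUE)
  pres <- sites_at_cells(g, hi[1:5, 1], hi[1:5, 2], paste0("p", 1:5))
  abs_ <- sites_at_cells(g, lo[1:5, 1], lo[1:5, 2], paste0("a", 1:5))
  b <- binarize_sdm(g, pres, abs_)
  expect_true(all(b$values %in% c(0, 1)))
  t_ <- attr(b, "threshold")
  pv1 <- g$values[cbind(hi[1:5, 1], hi[1:5, 2])]
  av1 <- g$values[cbind(lo[1:5, 1], lo[1:5, 2])]
  # perfectly separable: sensitivity = specificity = 1 at the threshold
  expect_gt(t_, max(av1)); expect_lte(t_, min(pv1))
  expect_equal(mean(pv1 >= t_) + mean(av1 < t_), 2)
  expect_equal(b$values, ifelse(g$values >= t_, 1, 0))

  # overlapping scores vs an exhaustive threshold-scan oracle
  set.seed(13)
  sc <- grid_create(matrix(runif(400), 20, 20), cellsize = 5)
  pcells <- cbind(sample(20, 10, TRUE), sample(20, 10, TRUE))
  acells <- cbind(sample(20, 10, TRUE), sample(20, 10, TRUE))
  pres2 <- sites_at_cells(sc, pcells[, 1], pcells[, 2], paste0("p", 1:10))
  abs2 <- sites_at_cells(sc, acells[, 1], acells[, 2], paste0("a", 1:10))
  b2 <- binarize_sdm(sc, pres2, abs2)
  pv <- sc$values[pcells]; av <- sc$values[acells]
  cand <- sort(unique(c(pv, av)))
  js <- sapply(cand, function(t) mean(pv >= t) + mean(av < t) - 1)
  expect_equal(attr(b2, "threshold"), min(cand[js == max(js)]))

  flat <- grid_create(matrix(0.5, 5, 5), cellsize = 10)
  p1 <- sites_at_cells(flat, 1, 1, "p")
  a1 <- sites_at_cells(flat, 5, 5, "a")
  expect_error(binarize_sdm(flat, p1, a1), "degenerate")
})

test_that("habitat surface equals a two-value relabelling", {
  set.seed(5)
  hab <- grid_create(matrix(rbinom(64, 1, 0.5), 8, 8), cellsize = 25)
  reg <- make_region(8, 8)
  h <- habitat_surface(hab, 2, reg)
  expect_equal(h$model, "HAB_1_2")
  expect_equal(h$values, ifelse(hab$values == 1, 1, 2))
  expect_true(all(habitat_surface(grid_create(matrix(1, 8, 8),
                                              cellsize = 25),
                                  10, reg)$values == 1))
})

test_that("land-cover surfaces look classes up in the resistance table", {
  cls <- landcover_classes()
  reg <- make_region(6, 6)
  tabs <- read_resistance_models()
  expect_true(all(c("BT_EO_100", "SFW_EO_5000", "TREE_1_5") %in%
                    names(tabs)))
  # the highest expert-opinion resistance equals the 10000 ceiling
  expect_equal(max(unlist(tabs[["SFW_EO_5000"]])), 10000)

  lc <- matrix(cls[["improved"]], 6, 6) # cleared, no scattered trees
  lc[1, 1] <- cls[["tree"]]
  lcg <- grid_create(lc, cellsize = 25)
  s <- landcover_surface(lcg, tabs[["BT_EO_100"]], reg)
  expect_equal(s$model, "BT_EO_100")
  expect_equal(s$values[1, 1], 1)
  expect_equal(s$values[3, 3], 2000)

  # dictionary-lookup oracle on a random landscape over all nine classes
  set.seed(9)
  rnd <- matrix(sample(cls, 36, replace = TRUE), 6, 6)
  tab9 <- setNames(as.numeric(sample(1:50, 9)), names(cls))
  s9 <- landcover_surface(grid_create(rnd, cellsize = 25), tab9, reg)
  oracle <- matrix(tab9[names(cls)[match(rnd, cls)]], 6, 6)
  expect_equal(s9$values, oracle)

  # a table mapping every class to 1 gives the uniform surface
  s1 <- landcover_surface(grid_create(rnd, cellsize = 25),
                          setNames(rep(1, 9), names(cls)), reg)
  expect_true(all(s1$values == 1))
  expect_error(landcover_surface(lcg, c(tree = 1), reg),
               "no value for land-cover class")
})
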