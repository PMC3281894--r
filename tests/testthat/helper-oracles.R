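# Independent oracles used across the suite. These deliberately share no
# code with the package internals: dense matrices, explicit loops, and
# closed forms.

# wrap a plain matrix of resistances as a surface
surf <- function(m, cellsize = 1, model = "S") {
  g <- grid_create(m, cellsize = cellsize)
  g$model <- model
  class(g) <- c("lg_surface", class(g))
  g
}

# sites at the centres of the given (row, col) cells of a grid
sites_at_cells <- function(grid, rows, cols, ids = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_along(rows))
  as_sites(data.frame(
    id = ids,
    x = grid$xll + (cols - 0.5) * grid$cellsize,
    y = grid$yll + (grid$nrows - rows + 0.5) * grid$cellsize))
}

# dense adjacency of edge traversal costs (or electrical resistances when
# cellsize = 1) built by explicit per-cell looping
dense_edge_matrix <- function(m, cellsize = 1, neighbours = 8,
                              electrical = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  idx <- function(r, c) (r - 1) * nc + c
  n <- nr * nc
  A <- matrix(Inf, n, n)
  offs <- list(c(0, 1), c(1, 0), c(0, -1), c(-1, 0))
  if (neighbours == 8)
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  for (r in 1:nr) for (c in 1:nc) {
    if (is.na(m[r, c])) next
    for (o in offs) {
      r2 <- r + o[1]; c2 <- c + o[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || is.na(m[r2, c2])) next
      w <- (m[r, c] + m[r2, c2]) / 2
      if (o[1] != 0 && o[2] != 0) w <- w * sqrt(2)
      if (!electrical) w <- w * cellsize
      A[idx(r, c), idx(r2, c2)] <- w
    }
  }
  A
}

# all-pairs shortest paths by exhaustive Floyd-Warshall relaxation;
# returned matrix is indexed by row-major cell index (r - 1) * ncol + c
fw_all_pairs <- function(m, cellsize = 1, neighbours = 8) {
  D <- dense_edge_matrix(m, cellsize, neighbours)
  n <- nrow(D)
  diag(D) <- 0
  for (k in 1:n) {
    through <- outer(D[, k], D[k, ], "+")
    D <- pmin(D, through)
  }
  D
}

# two-point effective resistances via the dense Laplacian pseudo-inverse;
# returns a lookup function res(r1, c1, r2, c2)
dense_effective_resistance <- function(m, neighbours = 8) {
  A <- dense_edge_matrix(m, neighbours = neighbours, electrical = TRUE)
  C <- ifelse(is.finite(A), 1 / A, 0)
  rowmajor_valid <- which(!is.na(t(m))) # cell (r,c) -> (r-1)*nc + c
  C <- C[rowmajor_valid, rowmajor_valid, drop = FALSE]
  L <- diag(rowSums(C)) - C
  Lp <- MASS::ginv(L)
  nc <- ncol(m)
  function(r1, c1, r2, c2) {
    i <- match((r1 - 1) * nc + c1, rowmajor_valid)
    j <- match((r2 - 1) * nc + c2, rowmajor_valid)
    Lp[i, i] + Lp[j, j] - 2 * Lp[i, j]
  }
}

# point-in-triangle by sign of cross products
in_triangle <- function(px, py, tri) {
  sgn <- function(ax, ay, bx, by, cx, cy)
    (ax - cx) * (by - cy) - (bx - cx) * (ay - cy)
  d1 <- sgn(px, py, tri[1, 1], tri[1, 2], tri[2, 1], tri[2, 2])
  d2 <- sgn(px, py, tri[2, 1], tri[2, 2], tri[3, 1], tri[3, 2])
  d3 <- sgn(px, py, tri[3, 1], tri[3, 2], tri[1, 1], tri[1, 2])
  neg <- (d1 < 0) | (d2 < 0) | (d3 < 0)
  pos <- (d1 > 0) | (d2 > 0) | (d3 > 0)
  !(neg & pos)
}

# random resistance surface with a guaranteed-connected valid mask
random_surface <- function(nr, nc, values = c(1, 5), p_nodata = 0) {
  m <- matrix(sample(values, nr * nc, replace = TRUE), nr, nc)
  if (p_nodata > 0) {
    drop <- sample(nr * nc, round(p_nodata * nr * nc))
    m[drop] <- NA
  }
  m
}
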