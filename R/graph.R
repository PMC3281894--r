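#' Build a weighted grid graph from a resistance surface
#'
#' Valid (non-missing) cells become nodes; 4- or 8-neighbouring valid
#' cells are joined by undirected edges. Per-cell resistances are
#' combined into edge values by the arithmetic mean of the two cells, the
#' standard raster-circuit convention: an orthogonal edge between cells
#' with resistances `r_a`, `r_b` has electrical resistance
#' `(r_a + r_b) / 2` and least-cost traversal cost
#' `(r_a + r_b) / 2 * cellsize`; diagonal edges scale both by `sqrt(2)`.
#'
#' @param surface a resistance surface (or any `lg_grid` of positive
#'   values).
#' @param neighbours 4 or 8 (default 8, the convention used for
#'   circuit-theory connectivity on rasters).
#' @return an object of class `lg_graph`: node/edge arrays plus the node
#'   index matrix (`node[row, col]`, `NA` for no-data cells).
#' @export
build_grid_graph <- function(surface, neighbours = 8) {
  stopifnot(inherits(surface, "lg_grid"))
  if (!neighbours %in% c(4, 8)) stop("`neighbours` must be 4 or 8")
  r <- surface$values
  if (any(r[!is.na(r)] <= 0)) stop("cell resistances must be > 0")
  nr <- nrow(r); nc <- ncol(r)
  valid <- !is.na(r)
  n <- sum(valid)
  node <- matrix(NA_integer_, nr, nc)
  node[valid] <- seq_len(n)

  offs <- list(c(0L, 1L), c(1L, 0L))
  if (neighbours == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  from <- to <- integer(0); res <- numeric(0)
  for (off in offs) {
    dr <- off[1]; dc <- off[2]
    rlo <- max(1L, 1L - dr); rhi <- min(nr, nr - dr)
    clo <- max(1L, 1L - dc); chi <- min(nc, nc - dc)
    if (rlo > rhi || clo > chi) next
    r1 <- rlo:rhi
    c1 <- clo:chi
    a <- valid[r1, c1, drop = FALSE] & valid[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(a)) next
    scale <- if (dr != 0 && dc != 0) sqrt(2) else 1
    from <- c(from, node[r1, c1, drop = FALSE][a])
    to <- c(to, node[r1 + dr, c1 + dc, drop = FALSE][a])
    res <- c(res,
             (r[r1, c1, drop = FALSE][a] +
                r[r1 + dr, c1 + dc, drop = FALSE][a]) / 2 * scale)
  }
  structure(
    list(n = n, from = from, to = to,
         resistance = res, cost = res * surface$cellsize,
         node = node, cellsize = surface$cellsize,
         nrows = nr, ncols = nc),
    class = "lg_graph")
}

#' @export
print.lg_graph <- function(x, ...) {
  cat(sprintf("<lg_graph> %d nodes, %d edges (cellsize %g m)\n",
              x$n, length(x$from), x$cellsize))
  invisible(x)
}

as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(graph$n, directed = FALSE)
  igraph::add_edges(g, as.vector(rbind(graph$from, graph$to)))
}

# map sites to graph node ids; error if a site misses the grid or lands
# on a no-data cell
site_nodes <- function(graph, surface, sites) {
  sites <- as_sites(sites)
  rc <- cell_of_xy(surface, sites$x, sites$y)
  if (anyNA(rc$row))
    stop("site(s) outside the surface extent: ",
         paste(sites$id[is.na(rc$row)], collapse = ", "))
  nd <- graph$node[cbind(rc$row, rc$col)]
  if (anyNA(nd))
    stop("site(s) placed on no-data cells: ",
         paste(sites$id[is.na(nd)], collapse = ", "))
  nd
}

new_distmat <- function(m, ids, model, method) {
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(ids, ids)
  structure(m, model = model, method = method,
            class = c("lg_distmat", class(m)))
}

#' @export
print.lg_distmat <- function(x, ...) {
  cat(sprintf("<lg_distmat> %s / %s, %d sites\n",
              attr(x, "model"), attr(x, "method"), nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}
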