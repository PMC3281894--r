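#' Pairwise least-cost path distances between sites
#'
#' The least-cost distance between two sites is the minimum, over all
#' paths in the grid graph, of the summed edge traversal costs
#' (resistance per unit distance times distance). Sites are snapped to
#' the cell containing their coordinates. Site pairs in different graph
#' components get distance `Inf`.
#'
#' @param surface a resistance surface.
#' @param sites site data.frame (see [as_sites()]).
#' @param neighbours 4 or 8 (default 8).
#' @return a symmetric site-by-site distance matrix (`lg_distmat`,
#'   method `LCP`).
#' @export
least_cost_distances <- function(surface, sites, neighbours = 8) {
  sites <- as_sites(sites)
  graph <- build_grid_graph(surface, neighbours)
  nd <- site_nodes(graph, surface, sites)
  g <- as_igraph(graph)
  un <- unique(nd)
  d <- igraph::distances(g, v = un, to = un, weights = graph$cost,
                         algorithm = "dijkstra")
  m <- d[match(nd, un), match(nd, un), drop = FALSE]
  if (any(is.infinite(m)))
    warning("some site pairs are not connected; distances are Inf")
  model <- if (!is.null(surface$model)) surface$model else "SURFACE"
  new_distmat(m, sites$id, model, "LCP")
}

# two-point effective resistances among `nodes` of the Laplacian of
# `graph`; one sparse Cholesky factorization per connected component,
# one triangular solve per distinct node
effective_resistance_nodes <- function(graph, nodes) {
  un <- sort(unique(nodes))
  k <- length(un)
  R <- matrix(Inf, k, k)
  diag(R) <- 0
  if (k > 1L) {
    cond <- 1 / graph$resistance
    A <- Matrix::sparseMatrix(i = graph$from, j = graph$to, x = cond,
                              dims = c(graph$n, graph$n))
    A <- A + Matrix::t(A)
    comp <- igraph::components(as_igraph(graph))$membership
    for (cm in unique(comp[un])) {
      members <- which(comp == cm)
      tgt <- un[comp[un] == cm]
      if (length(tgt) < 2L) next
      gnd <- tgt[1L]
      keep <- setdiff(members, gnd)
      Lr <- -A[keep, keep, drop = FALSE]
      Matrix::diag(Lr) <- Matrix::rowSums(A[keep, , drop = FALSE])
      ch <- Matrix::Cholesky(Matrix::forceSymmetric(Lr), LDL = FALSE)
      cols <- match(tgt[-1L], keep)
      B <- Matrix::sparseMatrix(i = cols, j = seq_along(cols), x = 1,
                                dims = c(length(keep), length(cols)))
      V <- as.matrix(Matrix::solve(ch, B, system = "A"))
      W <- V[cols, , drop = FALSE] # W[i, j] = potential at tgt[i+1] col j
      d <- diag(W)
      ii <- match(tgt, un)
      R[ii[1L], ii[-1L]] <- R[ii[-1L], ii[1L]] <- d
      if (length(d) > 1L) {
        sub <- outer(d, d, "+") - W - t(W)
        R[ii[-1L], ii[-1L]] <- sub
      }
    }
  }
  R[match(nodes, un), match(nodes, un), drop = FALSE]
}

#' Pairwise circuit-theory effective resistances between sites
#'
#' Isolation-by-resistance effective distance: the raster is treated as
#' an electrical network in which every edge of the grid graph is a
#' resistor, and the effective distance between two sites is the
#' two-point effective resistance, obtained by solving the graph
#' Laplacian linear system with unit current injected at one site and
#' extracted at the other. Unlike a least-cost path this integrates all
#' paths through the landscape. Computed by sparse Cholesky
#' factorization of the grounded Laplacian, one factorization per
#' connected component reused across all sites.
#'
#' @inheritParams least_cost_distances
#' @return a symmetric site-by-site matrix (`lg_distmat`, method `IBR`);
#'   `Inf` for pairs in different components.
#' @export
effective_resistances <- function(surface, sites, neighbours = 8) {
  sites <- as_sites(sites)
  graph <- build_grid_graph(surface, neighbours)
  nd <- site_nodes(graph, surface, sites)
  m <- effective_resistance_nodes(graph, nd)
  if (any(is.infinite(m)))
    warning("some site pairs are not connected; resistances are Inf")
  model <- if (!is.null(surface$model)) surface$model else "SURFACE"
  new_distmat(m, sites$id, model, "IBR")
}

#' Edge-effect experiment on a uniform circular grid
#'
#' Reproduces the boundary-inflation diagnostic for circuit-theory
#' distances: on a disc of uniform resistance 1 (cell size 1), point
#' pairs separated by a fixed number of cells are placed along a radius,
#' and their effective resistance is computed as the nearer point sits at
#' increasing offsets from the grid edge. Because cells outside the grid
#' are effectively infinite resistance, pairwise resistance is inflated
#' near the boundary, and the inflation extends farther inward for
#' larger separations — the rationale for buffering study regions and for
#' using a uniform-surface circuit distance (rather than straight-line
#' distance) as the null model for circuit-theory analyses.
#'
#' @param radius disc radius in cells.
#' @param separations integer vector of pair separations (cells).
#' @param offsets integer vector of offsets of the nearer point from the
#'   grid edge (cells).
#' @param neighbours 4 or 8 (default 8).
#' @return data.frame with columns `separation`, `offset`, `resistance`.
#' @export
edge_effect_experiment <- function(radius, separations, offsets,
                                   neighbours = 8) {
  stopifnot(radius >= 2, all(separations >= 1), all(offsets >= 0))
  n <- 2L * as.integer(radius) + 1L
  ctr <- as.integer(radius) + 1L
  dr <- matrix(seq_len(n) - ctr, n, n)
  dc <- t(dr)
  v <- ifelse(sqrt(dr^2 + dc^2) <= radius, 1, NA_real_)
  disc <- grid_create(v, cellsize = 1)
  disc$model <- "UNIFORM_DISC"
  class(disc) <- c("lg_surface", class(disc))

  cases <- expand.grid(separation = separations, offset = offsets)
  cases$near <- radius - cases$offset       # signed position on the axis
  cases$far <- cases$near - cases$separation
  if (any(cases$near > radius) || any(cases$far < -radius))
    stop("pair geometry does not fit inside the disc")
  pos <- sort(unique(c(cases$near, cases$far)))
  graph <- build_grid_graph(disc, neighbours)
  nodes <- graph$node[cbind(ctr, ctr + pos)]
  if (anyNA(nodes)) stop("pair geometry does not fit inside the disc")
  R <- effective_resistance_nodes(graph, nodes)
  cases$resistance <- R[cbind(match(cases$near, pos),
                              match(cases$far, pos))]
  cases[, c("separation", "offset", "resistance")]
}

#' Compute the full suite of effective-distance matrices
#'
#' For every supplied resistance surface, both the least-cost (`LCP`)
#' and circuit-theory (`IBR`) pairwise matrices are computed, plus three
#' null-model matrices: straight-line geographic distance (`GEOG`), its
#' log transform (`logGEOG`), and the circuit distance on a uniform
#' surface (`CS_UNIFORM`), which carries the same boundary inflation as
#' the heterogeneous circuit models.
#'
#' @param surfaces list of resistance surfaces (may be empty).
#' @param sites site data.frame.
#' @param region study region used for the uniform null surface.
#' @param neighbours 4 or 8 (default 8).
#' @return named list of `lg_distmat` objects: `<MODEL>_LCP` and
#'   `<MODEL>_IBR` per surface, then `GEOG`, `logGEOG`, `CS_UNIFORM`.
#' @export
run_model_suite <- function(surfaces, sites, region, neighbours = 8) {
  sites <- as_sites(sites)
  out <- list()
  for (s in surfaces) {
    out[[paste0(s$model, "_LCP")]] <-
      least_cost_distances(s, sites, neighbours)
    out[[paste0(s$model, "_IBR")]] <-
      effective_resistances(s, sites, neighbours)
  }
  out$GEOG <- geographic_distances(sites)
  out$logGEOG <- geographic_distances(sites, log_transform = TRUE)
  out$CS_UNIFORM <- effective_resistances(uniform_surface(region), sites,
                                          neighbours)
  attr(out$CS_UNIFORM, "model") <- "CS_UNIFORM"
  out
}

#' Write a pairwise distance matrix as delimited text
#'
#' @param m an `lg_distmat`.
#' @param path output path.
#' @param long if `TRUE`, write long form (`site_i`, `site_j`, `value`,
#'   `model`, `method`) over unordered pairs; otherwise a labelled square
#'   matrix.
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(m, path, long = FALSE) {
  stopifnot(inherits(m, "lg_distmat"))
  if (long) {
    idx <- which(upper.tri(m), arr.ind = TRUE)
    df <- data.frame(site_i = rownames(m)[idx[, 1]],
                     site_j = colnames(m)[idx[, 2]],
                     value = m[idx],
                     model = attr(m, "model"), method = attr(m, "method"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    utils::write.table(as.data.frame(unclass(m)), path, sep = "\t",
                       quote = FALSE, row.names = TRUE, col.names = NA)
  }
  invisible(path)
}
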