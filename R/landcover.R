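#' Land-cover class codes
#'
#' The nine land-cover classes used by the expert-opinion resistance
#' models: native tree-cover, plantation/horticulture, urban, and three
#' agricultural classes (unimproved pasture and native grassland,
#' improved pasture, arable crop) each with and without scattered trees.
#'
#' @return named integer vector mapping class name to cell code.
#' @export
landcover_classes <- function() {
  c(tree = 1L, plantation = 2L, urban = 3L,
    unimproved = 4L, improved = 5L, arable = 6L,
    unimproved_scattered = 7L, improved_scattered = 8L,
    arable_scattered = 9L)
}

# agricultural class -> its scattered-tree variant
scattered_variant <- c(unimproved = "unimproved_scattered",
                       improved = "improved_scattered",
                       arable = "arable_scattered")

# nine elicitation classes -> the six merged resistance categories of the
# final expert-opinion tables (the three cleared agricultural classes
# share one resistance, as do improved-pasture and crop with scattered
# trees)
landcover_merged_category <- function(class_name) {
  map <- c(tree = "tree", plantation = "horticulture", urban = "urban",
           unimproved = "cleared", improved = "cleared", arable = "cleared",
           unimproved_scattered = "unimproved_scattered",
           improved_scattered = "crop_improved_scattered",
           arable_scattered = "crop_improved_scattered")
  unname(map[class_name])
}

#' Generalize a fine binary tree-cover raster to a coarser cell size
#'
#' A coarse cell is classed as tree-cover when at least one fine
#' tree-pixel *centre* falls within it, so isolated large trees resolved
#' at the fine scale survive generalization. The coarse grid is aligned
#' to the fine grid's lower-left corner and covers its full extent.
#'
#' @param fine binary [grid_create()] object (values 0/1, `NA` allowed).
#' @param coarse_cellsize target cell size in metres, `>=` the fine cell
#'   size. Default 25.
#' @return binary grid at `coarse_cellsize`.
#' @export
generalize_tree_cover <- function(fine, coarse_cellsize = 25) {
  stopifnot(inherits(fine, "lg_grid"))
  v <- fine$values
  if (!all(v[!is.na(v)] %in% c(0, 1)))
    stop("`fine` must be a binary (0/1) tree-cover grid")
  if (coarse_cellsize < fine$cellsize)
    stop("`coarse_cellsize` must be >= the fine cell size")
  width <- fine$ncols * fine$cellsize
  height <- fine$nrows * fine$cellsize
  ncols <- ceiling(width / coarse_cellsize - 1e-9)
  nrows <- ceiling(height / coarse_cellsize - 1e-9)
  out <- matrix(0, nrows, ncols)
  cc <- cell_centres(fine)
  treed <- which(v[cbind(cc$row, cc$col)] == 1)
  if (length(treed)) {
    ccol <- floor((cc$x[treed] - fine$xll) / coarse_cellsize) + 1
    crowS <- floor((cc$y[treed] - fine$yll) / coarse_cellsize)
    crow <- nrows - crowS
    out[cbind(crow, ccol)] <- 1
  }
  grid_create(out, xll = fine$xll, yll = fine$yll,
              cellsize = coarse_cellsize, nodata = fine$nodata)
}

#' Reclassify agricultural land near trees as scattered-tree variants
#'
#' Scattered paddock trees facilitate the movement of woodland birds
#' through cleared farmland, so agricultural cells close to trees get
#' their own land-cover classes. A cell of class unimproved, improved or
#' arable is reassigned to its scattered-tree variant when its centre
#' lies within `radius` of any tree-cell centre and the cell itself is
#' not tree-cover. All other classes are unchanged. The operation is
#' idempotent.
#'
#' @param landcover land-cover grid coded as in [landcover_classes()].
#' @param tree binary tree-cover grid co-registered with `landcover`.
#' @param radius neighbourhood radius in metres. Default 50.
#' @return reclassified land-cover grid.
#' @export
classify_scattered_trees <- function(landcover, tree, radius = 50) {
  stopifnot(inherits(landcover, "lg_grid"), inherits(tree, "lg_grid"))
  if (landcover$nrows != tree$nrows || landcover$ncols != tree$ncols ||
      landcover$cellsize != tree$cellsize ||
      landcover$xll != tree$xll || landcover$yll != tree$yll)
    stop("`landcover` and `tree` grids are not co-registered")
  if (radius < 0) stop("`radius` must be >= 0")
  cs <- landcover$cellsize
  maxoff <- floor(radius / cs)
  istree <- !is.na(tree$values) & tree$values == 1
  near <- matrix(FALSE, landcover$nrows, landcover$ncols)
  nr <- landcover$nrows; nc <- landcover$ncols
  for (dr in -maxoff:maxoff) for (dc in -maxoff:maxoff) {
    if (sqrt(dr^2 + dc^2) * cs > radius) next
    # cell (r,c) is near a tree if cell (r+dr, c+dc) is tree
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs2 <- max(1, 1 - dc):min(nc, nc - dc)
    near[rs, cs2] <- near[rs, cs2] | istree[rs + dr, cs2 + dc]
  }
  cls <- landcover_classes()
  v <- landcover$values
  for (ag in names(scattered_variant)) {
    hit <- !is.na(v) & v == cls[[ag]] & near & !istree
    v[hit] <- cls[[scattered_variant[[ag]]]]
  }
  grid_create(v, xll = landcover$xll, yll = landcover$yll,
              cellsize = cs, nodata = landcover$nodata)
}
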