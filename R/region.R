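# distance from each point in P (n x 2) to segment a-b, vectorised over P
dist_point_segment <- function(P, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((P[, 1] - a[1])^2 + (P[, 2] - a[2])^2))
  t <- ((P[, 1] - a[1]) * ab[1] + (P[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  qx <- a[1] + t * ab[1]
  qy <- a[2] + t * ab[2]
  sqrt((P[, 1] - qx)^2 + (P[, 2] - qy)^2)
}

#' Build a buffered study region around sampling sites
#'
#' The computational study region is the minimum convex polygon enclosing
#' the sites, dilated by a buffer. Buffering counters the inflation of
#' circuit-theory resistance near an artificial grid boundary, so the
#' buffer should be generous relative to the between-site distances (the
#' default is 25 km). A cell belongs to the region when its *centre* lies
#' within the buffered hull; cells containing a site are always included.
#' Cells outside the region are treated as no-data and excluded from all
#' downstream computation.
#'
#' @param sites site data.frame (see [as_sites()]).
#' @param buffer buffer distance in metres, `>= 0`. Default 25000.
#' @param template a [grid_create()] object supplying extent, cell size
#'   and georeferencing for the region mask.
#' @return an object of class `lg_region`: list with `mask` (a grid whose
#'   inside cells are 1 and outside cells `NA`) and `buffer`.
#' @export
build_study_region <- function(sites, buffer = 25000, template) {
  sites <- as_sites(sites)
  stopifnot(inherits(template, "lg_grid"))
  if (nrow(sites) < 1L) stop("need at least one site")
  if (buffer < 0) stop("`buffer` must be >= 0")
  pts <- unique(cbind(sites$x, sites$y))
  if (nrow(pts) == 1L && nrow(sites) > 1L && buffer == 0)
    stop("degenerate study region: all sites coincident and buffer is 0")

  cc <- cell_centres(template)
  P <- cbind(cc$x, cc$y)
  inside <- rep(FALSE, nrow(P))

  if (nrow(pts) >= 3L) {
    h <- grDevices::chull(pts[, 1], pts[, 2])
    hull <- pts[h, , drop = FALSE]
  } else {
    hull <- pts
  }
  if (nrow(hull) >= 3L) {
    bnd <- rbind(hull, hull[1L, ])
    inside <- mgcv::in.out(bnd, P)
    segs <- nrow(hull)
  } else {
    segs <- max(nrow(hull) - 1L, 1L)
  }
  # dilate: within `buffer` of the hull boundary (also covers degenerate
  # point / segment hulls)
  if (buffer > 0 || !any(inside)) {
    near <- rep(FALSE, nrow(P))
    for (k in seq_len(segs)) {
      a <- hull[k, ]
      b <- hull[if (k == nrow(hull)) 1L else k + 1L, ]
      near <- near | dist_point_segment(P, a, b) <= buffer
    }
    inside <- inside | near
  }

  mask <- matrix(NA_real_, template$nrows, template$ncols)
  mask[cbind(cc$row, cc$col)[inside, , drop = FALSE]] <- 1

  # every site's cell is inside by contract
  sc <- cell_of_xy(template, sites$x, sites$y)
  if (anyNA(sc$row))
    stop("site(s) fall outside the template grid extent: ",
         paste(sites$id[is.na(sc$row)], collapse = ", "))
  mask[cbind(sc$row, sc$col)] <- 1

  structure(
    list(mask = grid_create(mask, xll = template$xll, yll = template$yll,
                            cellsize = template$cellsize,
                            nodata = template$nodata),
         buffer = buffer),
    class = "lg_region")
}

#' @export
print.lg_region <- function(x, ...) {
  cat(sprintf("<lg_region> %d inside cells, buffer %g m\n",
              sum(!is.na(x$mask$values)), x$buffer))
  invisible(x)
}

# apply a region's no-data mask to a values matrix
clip_to_region <- function(values, region) {
  stopifnot(inherits(region, "lg_region"))
  values[is.na(region$mask$values)] <- NA_real_
  values
}

#' Study region covering every valid cell of a grid
#'
#' Convenience constructor for analyses on a full raster (no hull
#' clipping): every non-missing cell of `template` is inside.
#'
#' @param template a [grid_create()] object.
#' @return an `lg_region` with buffer 0.
#' @export
region_from_grid <- function(template) {
  stopifnot(inherits(template, "lg_grid"))
  m <- template$values
  m[!is.na(m)] <- 1
  structure(
    list(mask = grid_create(m, xll = template$xll, yll = template$yll,
                            cellsize = template$cellsize,
                            nodata = template$nodata),
         buffer = 0),
    class = "lg_region")
}
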