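#' Construct a raster grid
#'
#' A `lg_grid` is the raster substrate used throughout the package: a
#' rectangular matrix of cell values in projected planar metres, with the
#' ESRI ASCII grid convention that row 1 of `values` is the *northernmost*
#' row. Cells with no data are stored as `NA` internally; the `nodata`
#' sentinel is only used when reading and writing files.
#'
#' @param values numeric matrix (`nrows` x `ncols`); `NA` marks no-data
#'   cells. Row 1 is the northernmost row.
#' @param xll easting of the lower-left corner of the grid (metres).
#' @param yll northing of the lower-left corner of the grid (metres).
#' @param cellsize cell edge length (metres), `> 0`.
#' @param nodata sentinel value used for no-data cells on file output.
#' @return an object of class `lg_grid`.
#' @export
grid_create <- function(values, xll = 0, yll = 0, cellsize = 1,
                        nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("`cellsize` must be a single positive number")
  if (any(!is.finite(values[!is.na(values)])))
    stop("all non-missing grid values must be finite")
  structure(
    list(ncols = ncol(values), nrows = nrow(values),
         xll = as.numeric(xll), yll = as.numeric(yll),
         cellsize = as.numeric(cellsize), nodata = as.numeric(nodata),
         values = values),
    class = "lg_grid")
}

#' @export
print.lg_grid <- function(x, ...) {
  nv <- sum(!is.na(x$values))
  cat(sprintf("<lg_grid> %d x %d cells @ %g m, origin (%g, %g), %d valid\n",
              x$nrows, x$ncols, x$cellsize, x$xll, x$yll, nv))
  invisible(x)
}

#' Cell-centre coordinates of every cell
#'
#' @param grid a [grid_create()] object.
#' @return data.frame with columns `row`, `col`, `x`, `y`, one line per
#'   cell in row-major order (row 1 = north).
#' @export
cell_centres <- function(grid) {
  rc <- expand.grid(col = seq_len(grid$ncols), row = seq_len(grid$nrows))
  data.frame(
    row = rc$row, col = rc$col,
    x = grid$xll + (rc$col - 0.5) * grid$cellsize,
    y = grid$yll + (grid$nrows - rc$row + 0.5) * grid$cellsize)
}

#' Locate the cell containing a point
#'
#' Points exactly on the outer north/east boundary are assigned to the
#' adjacent cell inside the grid, so any point within the closed extent
#' maps to a cell.
#'
#' @param grid a [grid_create()] object.
#' @param x,y point coordinates (metres), vectorised.
#' @return data.frame with columns `row`, `col`; `NA` for points outside
#'   the grid extent.
#' @export
cell_of_xy <- function(grid, x, y) {
  col <- floor((x - grid$xll) / grid$cellsize) + 1
  rowfromS <- floor((y - grid$yll) / grid$cellsize) # rows above yll
  col[x == grid$xll + grid$ncols * grid$cellsize] <- grid$ncols
  rowfromS[y == grid$yll + grid$nrows * grid$cellsize] <- grid$nrows - 1
  row <- grid$nrows - rowfromS
  bad <- col < 1 | col > grid$ncols | row < 1 | row > grid$nrows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Read an ESRI ASCII grid
#'
#' Reads the Circuitscape-compatible ASCII grid dialect: a header of
#' `ncols`, `nrows`, `xllcorner` (or `xllcenter`), `yllcorner` (or
#' `yllcenter`), `cellsize` and optional `NODATA_value`, followed by cell
#' values in rows from north to south. Cells equal to the no-data sentinel
#' become `NA` and are excluded from all downstream computation.
#'
#' @param path path to a `.asc` file.
#' @return a [grid_create()] object.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  keys <- c("ncols", "nrows", "xllcorner", "xllcenter",
            "yllcorner", "yllcenter", "cellsize", "nodata_value")
  while (i <= length(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(tok) == 0L) { i <- i + 1L; next }
    key <- tolower(tok[[1]])
    if (!(key %in% keys)) break
    val <- suppressWarnings(as.numeric(tok[[2]]))
    if (length(tok) != 2L || is.na(val))
      stop("malformed ASCII grid header line: '", lines[[i]], "'")
    hdr[[key]] <- val
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[k]]))
      stop("ASCII grid header is missing required keyword '", k, "'")
  if (is.null(hdr$xllcorner) && is.null(hdr$xllcenter))
    stop("ASCII grid header is missing 'xllcorner'/'xllcenter'")
  if (is.null(hdr$yllcorner) && is.null(hdr$yllcenter))
    stop("ASCII grid header is missing 'yllcorner'/'yllcenter'")
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  if (ncols < 1L || nrows < 1L) stop("ASCII grid dimensions must be >= 1")

  vals <- scan(text = paste(lines[seq.int(i, length(lines))], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != ncols * nrows)
    stop(sprintf(
      "ASCII grid body has %d values but header declares %d x %d = %d",
      length(vals), nrows, ncols, nrows * ncols))
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA
  grid_create(m, xll = xll, yll = yll, cellsize = cs, nodata = nodata)
}

# integral values are written without a decimal point so that integer-coded
# grids (land-cover classes, binary masks) are byte-stable fixtures
format_grid_values <- function(v, nodata = -9999) {
  fmt1 <- function(x) {
    intlike <- x == round(x) & abs(x) < 1e15
    s <- character(length(x))
    s[intlike] <- sprintf("%.0f", x[intlike])
    s[!intlike] <- formatC(x[!intlike], digits = 15, format = "g")
    s
  }
  out <- character(length(v))
  isna <- is.na(v)
  if (any(isna)) out[isna] <- fmt1(nodata)
  out[!isna] <- fmt1(v[!isna])
  out
}

#' Write an ESRI ASCII grid
#'
#' Emits the standard six-line header (always the `xllcorner` dialect)
#' followed by cell rows north to south; `NA` cells are written as the
#' grid's no-data sentinel.
#'
#' @param grid a [grid_create()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "lg_grid"))
  hdr <- c(
    paste("ncols", format_grid_values(grid$ncols, grid$nodata)),
    paste("nrows", format_grid_values(grid$nrows, grid$nodata)),
    paste("xllcorner", format_grid_values(grid$xll, grid$nodata)),
    paste("yllcorner", format_grid_values(grid$yll, grid$nodata)),
    paste("cellsize", format_grid_values(grid$cellsize, grid$nodata)),
    paste("NODATA_value", format_grid_values(grid$nodata, grid$nodata)))
  body <- apply(grid$values, 1L, function(r)
    paste(format_grid_values(r, grid$nodata), collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read a site table
#'
#' Sites are sampling locations in projected metres, given as delimited
#' text with columns `id`, `x`, `y` and optionally `landscape`.
#'
#' @param path path to a delimited text file (tab or comma separated).
#' @param sep field separator; guessed from the first line when `NULL`.
#' @return data.frame with columns `id` (character), `x`, `y` (numeric)
#'   and `landscape` (character).
#' @export
read_sites <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl(",", first)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  as_sites(df)
}

#' Validate a site table
#'
#' @param df data.frame with columns `id`, `x`, `y` and optionally
#'   `landscape`.
#' @return the validated data.frame.
#' @export
as_sites <- function(df) {
  need <- c("id", "x", "y")
  if (!all(need %in% names(df)))
    stop("site table must have columns id, x, y")
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) stop("site ids must be unique")
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("site coordinates must be finite")
  if (is.null(df$landscape)) df$landscape <- NA_character_
  df[, c("id", "x", "y", "landscape")]
}

#' Write a site table
#' @param sites a site data.frame (see [as_sites()]).
#' @param path output path; tab-separated.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(as_sites(sites), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
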