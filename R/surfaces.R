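new_surface <- function(values, template, model, region = NULL) {
  if (!is.null(region)) values <- clip_to_region(values, region)
  g <- grid_create(values, xll = template$xll, yll = template$yll,
                   cellsize = template$cellsize, nodata = template$nodata)
  v <- g$values[!is.na(g$values)]
  if (length(v) && (any(v < 1) || any(v > 10000)))
    stop("resistance values must lie in [1, 10000]")
  g$model <- model
  class(g) <- c("lg_surface", class(g))
  g
}

#' @export
print.lg_surface <- function(x, ...) {
  cat(sprintf("<lg_surface> model %s: %d x %d cells @ %g m, %d valid\n",
              x$model, x$nrows, x$ncols, x$cellsize,
              sum(!is.na(x$values))))
  invisible(x)
}

#' Uniform (isolation-by-distance null) resistance surface
#'
#' All inside cells carry the same resistance, the raster analogue of
#' isolation by distance. With the default value of 1 this is the UNIFORM
#' null model against which heterogeneous-landscape models are compared.
#'
#' @param region a [build_study_region()] object.
#' @param value per-cell resistance, `> 0`. Default 1.
#' @return a resistance surface (`lg_surface`), model code `UNIFORM`.
#' @export
uniform_surface <- function(region, value = 1) {
  stopifnot(inherits(region, "lg_region"))
  if (value <= 0) stop("`value` must be > 0")
  m <- region$mask$values
  m[!is.na(m)] <- value
  new_surface(m, region$mask, "UNIFORM")
}

#' Tree-cover resistance surface
#'
#' Tree-covered cells get resistance 1 and all other inside cells a
#' single higher resistance. The canonical off-tree resistances are 2, 5,
#' 10 and 100 (model codes `TREE_1_2` .. `TREE_1_100`); other values are
#' allowed for sensitivity analyses but flagged with a warning.
#'
#' @param tree binary tree-cover grid.
#' @param off_resistance resistance of non-tree cells, `> 1`.
#' @param region a [build_study_region()] object.
#' @return resistance surface with model code `TREE_1_<off>`.
#' @export
tree_surface <- function(tree, off_resistance, region) {
  stopifnot(inherits(tree, "lg_grid"), inherits(region, "lg_region"))
  v <- tree$values
  if (!all(v[!is.na(v)] %in% c(0, 1)))
    stop("`tree` must be a binary (0/1) grid")
  if (off_resistance <= 1) stop("`off_resistance` must be > 1")
  if (!off_resistance %in% c(2, 5, 10, 100))
    warning("off_resistance ", off_resistance,
            " is outside the canonical set {2, 5, 10, 100}")
  out <- ifelse(v == 1, 1, off_resistance)
  # inside cells missing from the tree grid count as non-treed
  out[is.na(out) & !is.na(region$mask$values)] <- off_resistance
  new_surface(out, region$mask,
              paste0("TREE_1_", format_grid_values(off_resistance, -9999)),
              region)
}

#' Binarize a species distribution model surface
#'
#' Converts a continuous habitat-suitability surface (predicted
#' probability of occurrence) into a binary habitat map using the
#' threshold that maximizes diagnosticity, operationalized as Youden's J
#' (sensitivity + specificity - 1) over the observed suitability values
#' at presence and absence points. Ties are broken toward the lower
#' threshold (the more inclusive habitat map). Cells with suitability
#' `>=` the threshold are habitat (1).
#'
#' @param sdm grid of probabilities in `[0, 1]`.
#' @param presences,absences site data.frames of evaluation points with
#'   valid `sdm` values.
#' @return binary grid with attribute `threshold`.
#' @export
binarize_sdm <- function(sdm, presences, absences) {
  stopifnot(inherits(sdm, "lg_grid"))
  presences <- as_sites(presences); absences <- as_sites(absences)
  score_at <- function(s) {
    rc <- cell_of_xy(sdm, s$x, s$y)
    if (anyNA(rc$row)) stop("evaluation point outside the SDM grid")
    v <- sdm$values[cbind(rc$row, rc$col)]
    if (anyNA(v)) stop("evaluation point on a no-data SDM cell")
    v
  }
  p <- score_at(presences)
  a <- score_at(absences)
  cand <- sort(unique(c(p, a)))
  if (length(cand) < 2L)
    stop("degenerate threshold: all evaluation scores are identical")
  j <- vapply(cand, function(t)
    mean(p >= t) + mean(a < t) - 1, numeric(1))
  tstar <- cand[which(j == max(j))[1L]] # ties -> lower threshold
  out <- ifelse(sdm$values >= tstar, 1, 0)
  g <- grid_create(out, xll = sdm$xll, yll = sdm$yll,
                   cellsize = sdm$cellsize, nodata = sdm$nodata)
  attr(g, "threshold") <- tstar
  g
}

#' Habitat-suitability resistance surface
#'
#' Habitat cells (from a binarized species distribution model) get
#' resistance 1; non-habitat inside cells get a single higher resistance,
#' canonically 2 (`HAB_1_2`) or 10 (`HAB_1_10`).
#'
#' @param habitat binary habitat grid (e.g. from [binarize_sdm()]).
#' @param off_resistance resistance of non-habitat cells, `> 1`.
#' @param region a [build_study_region()] object.
#' @return resistance surface with model code `HAB_1_<off>`.
#' @export
habitat_surface <- function(habitat, off_resistance, region) {
  stopifnot(inherits(habitat, "lg_grid"), inherits(region, "lg_region"))
  v <- habitat$values
  if (!all(v[!is.na(v)] %in% c(0, 1)))
    stop("`habitat` must be a binary (0/1) grid")
  if (off_resistance <= 1) stop("`off_resistance` must be > 1")
  if (!off_resistance %in% c(2, 10))
    warning("off_resistance ", off_resistance,
            " is outside the canonical set {2, 10}")
  out <- ifelse(v == 1, 1, off_resistance)
  out[is.na(out) & !is.na(region$mask$values)] <- off_resistance
  new_surface(out, region$mask,
              paste0("HAB_1_", format_grid_values(off_resistance, -9999)),
              region)
}

#' Land-cover resistance surface from a per-class resistance table
#'
#' Assigns each cell the resistance of its land-cover class. The table
#' may be keyed either by the nine elicitation class names (see
#' [landcover_classes()]) or by the six merged resistance categories
#' (`tree`, `horticulture`, `urban`, `cleared`, `unimproved_scattered`,
#' `crop_improved_scattered`); exact class names take precedence.
#'
#' @param landcover land-cover grid coded as in [landcover_classes()].
#' @param table named numeric vector of resistances, or a
#'   `lg_resistance_table` (see [read_resistance_models()]).
#' @param region a [build_study_region()] object.
#' @param model model code for the resulting surface; defaults to the
#'   table's model code if present.
#' @return resistance surface.
#' @export
landcover_surface <- function(landcover, table, region, model = NULL) {
  stopifnot(inherits(landcover, "lg_grid"), inherits(region, "lg_region"))
  if (inherits(table, "lg_resistance_table")) {
    if (is.null(model)) model <- attr(table, "model")
    table <- unclass(table)
  }
  if (is.null(model)) model <- "LANDCOVER"
  if (is.null(names(table)) || anyNA(names(table)))
    stop("`table` must be a named vector of class resistances")
  cls <- landcover_classes()
  v <- landcover$values
  present <- sort(unique(v[!is.na(v) & !is.na(region$mask$values)]))
  bad <- setdiff(present, cls)
  if (length(bad))
    stop("unknown land-cover codes in grid: ", paste(bad, collapse = ", "))
  out <- matrix(NA_real_, landcover$nrows, landcover$ncols)
  for (code in present) {
    nm <- names(cls)[match(code, cls)]
    key <- if (nm %in% names(table)) nm else landcover_merged_category(nm)
    if (!key %in% names(table))
      stop("resistance table has no value for land-cover class '", nm, "'")
    out[!is.na(v) & v == code] <- table[[key]]
  }
  new_surface(out, region$mask, model, region)
}

#' Read per-class resistance tables
#'
#' Reads a long-form delimited file with columns `model`, `class`,
#' `resistance` and returns one named resistance vector per model code.
#' With no `path`, the table of canonical model resistances shipped with
#' the package (uniform null, tree-cover, habitat and per-species
#' expert-opinion models) is read.
#'
#' @param path path to a tab-separated table; default uses the packaged
#'   table.
#' @return named list of `lg_resistance_table` objects (named numeric
#'   vectors with a `model` attribute), keyed by model code.
#' @export
read_resistance_models <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "resistance_models.tsv",
                        package = "landres", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("model", "class", "resistance") %in% names(df)))
    stop("resistance table must have columns model, class, resistance")
  if (any(!is.finite(df$resistance)) || any(df$resistance < 1))
    stop("all resistances must be finite and >= 1")
  out <- lapply(split(df, df$model), function(d) {
    tab <- stats::setNames(d$resistance, d$class)
    structure(tab, model = d$model[[1]], class = "lg_resistance_table")
  })
  out[unique(df$model)]
}
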