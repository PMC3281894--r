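# evaluate `code` under a temporary RNG state seeded with `seed`;
# NULL uses (and advances) the current stream
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# stationary Gaussian random field: white noise smoothed by circular FFT
# convolution with a Gaussian kernel of standard deviation `sigma` cells
smooth_field <- function(nrows, ncols, sigma) {
  z <- matrix(stats::rnorm(nrows * ncols), nrows, ncols)
  if (sigma <= 0) return(z)
  dwrap <- function(n) {
    d <- 0:(n - 1)
    pmin(d, n - d)
  }
  k <- outer(exp(-dwrap(nrows)^2 / (2 * sigma^2)),
             exp(-dwrap(ncols)^2 / (2 * sigma^2)))
  k <- k / sum(k)
  Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) /
    (nrows * ncols)
}

#' Simulate a land-cover raster with controlled tree cover
#'
#' Generates a synthetic landscape with the structure the analysis
#' assumes: a binary tree-cover grid obtained by thresholding a smoothed
#' Gaussian random field at the quantile giving the requested cover
#' fraction, with the smoothing length controlling spatial aggregation
#' (long for `aggregated`, short for `dispersed`; `continuous` is an
#' aggregated landscape with cover `>= 0.7`). Non-tree cells are
#' assigned to plantation, urban and the three agricultural classes by a
#' second smoothed field. Defaults emulate 10 x 10 km landscapes at 25 m
#' resolution.
#'
#' @param cover_fraction target tree-cover fraction in `[0, 1]`.
#' @param configuration `"aggregated"`, `"dispersed"` or `"continuous"`.
#' @param extent landscape edge length in metres (default 10000).
#' @param cellsize cell size in metres (default 25); `extent / cellsize`
#'   must be an integer.
#' @param seed optional RNG seed for reproducibility.
#' @return list with `landcover` (grid coded as in
#'   [landcover_classes()], without scattered-tree variants) and `tree`
#'   (binary grid).
#' @export
simulate_landcover <- function(cover_fraction,
                               configuration = c("aggregated",
                                                 "dispersed",
                                                 "continuous"),
                               extent = 10000, cellsize = 25,
                               seed = NULL) {
  configuration <- match.arg(configuration)
  if (cover_fraction < 0 || cover_fraction > 1)
    stop("`cover_fraction` must lie in [0, 1]")
  n <- extent / cellsize
  if (abs(n - round(n)) > 1e-9)
    stop("`extent` must be an integer multiple of `cellsize`")
  n <- as.integer(round(n))
  if (configuration == "continuous" && cover_fraction < 0.7)
    stop("`continuous` landscapes require cover_fraction >= 0.7")
  sigma <- switch(configuration, aggregated = 16, continuous = 16,
                  dispersed = 2)
  local_seed(seed, {
    f <- smooth_field(n, n, sigma)
    tree <- matrix(0, n, n)
    if (cover_fraction >= 1) {
      tree[] <- 1
    } else if (cover_fraction > 0) {
      thr <- stats::quantile(f, 1 - cover_fraction, names = FALSE)
      tree[f >= thr] <- 1
    }
    achieved <- mean(tree)
    if (abs(achieved - cover_fraction) > 0.02)
      stop(sprintf(
        "achieved cover %.3f misses target %.3f by more than 0.02",
        achieved, cover_fraction))
    cls <- landcover_classes()
    lc <- matrix(cls[["tree"]], n, n)
    nontree <- tree == 0
    if (any(nontree)) {
      g <- smooth_field(n, n, 8)
      u <- rank(g[nontree], ties.method = "first") / sum(nontree)
      # shares of the non-tree matrix: urban 2%, plantation 3%, then the
      # three agricultural classes
      brk <- cumsum(c(urban = 0.02, plantation = 0.03, unimproved = 0.35,
                      improved = 0.35, arable = 0.25))
      lab <- names(brk)[pmin(findInterval(u, c(0, brk), left.open = TRUE),
                             length(brk))]
      lc[nontree] <- cls[lab]
    }
    list(landcover = grid_create(lc, cellsize = cellsize),
         tree = grid_create(tree, cellsize = cellsize))
  })
}

#' Simulate sampling sites on a landscape
#'
#' Draws site locations at cell centres, optionally restricted to
#' tree-covered cells (sampling sites sit in remnant vegetation), with a
#' minimum pairwise spacing enforced by rejection.
#'
#' @param landcover land-cover grid (codes as in
#'   [landcover_classes()]).
#' @param n_sites number of sites (the study design uses 3-6 per
#'   landscape).
#' @param min_spacing minimum pairwise distance in metres (default 0).
#' @param require_tree restrict sites to tree-cover cells.
#' @param landscape label stored in the site table.
#' @param seed optional RNG seed.
#' @param max_tries rejection limit (default 2000).
#' @return site data.frame (see [as_sites()]).
#' @export
simulate_sites <- function(landcover, n_sites, min_spacing = 0,
                           require_tree = TRUE, landscape = "L1",
                           seed = NULL, max_tries = 2000) {
  stopifnot(inherits(landcover, "lg_grid"), n_sites >= 1)
  cls <- landcover_classes()
  v <- landcover$values
  elig <- which(!is.na(v) & (!require_tree | v == cls[["tree"]]))
  if (length(elig) < n_sites)
    stop("not enough eligible cells for ", n_sites, " sites")
  cc <- cell_centres(landcover)
  idx <- cbind(cc$row, cc$col)
  lin <- (idx[, 2] - 1L) * landcover$nrows + idx[, 1] # column-major index
  pos <- match(elig, lin)
  local_seed(seed, {
    chosen <- integer(0)
    tries <- 0L
    while (length(chosen) < n_sites) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place ", n_sites, " sites with min_spacing ",
             min_spacing, " m after ", max_tries, " tries")
      cand <- sample(pos, 1L)
      if (cand %in% chosen) next
      if (length(chosen)) {
        d <- sqrt((cc$x[chosen] - cc$x[cand])^2 +
                    (cc$y[chosen] - cc$y[cand])^2)
        if (any(d < min_spacing)) next
      }
      chosen <- c(chosen, cand)
    }
    as_sites(data.frame(
      id = paste0(landscape, "_S", seq_len(n_sites)),
      x = cc$x[chosen], y = cc$y[chosen], landscape = landscape))
  })
}

#' Simulate a habitat-suitability (SDM) surface
#'
#' Produces a probability-of-occurrence surface as a fidelity-weighted
#' mixture of the tree-cover indicator and a smooth random field,
#' rescaled to `[0, 1]`. At fidelity 1 the surface reproduces the tree
#' indicator; at fidelity 0 it is unrelated smooth noise.
#'
#' @param tree binary tree-cover grid.
#' @param fidelity mixing weight in `[0, 1]`.
#' @param seed optional RNG seed.
#' @return grid of probabilities in `[0, 1]`.
#' @export
simulate_sdm <- function(tree, fidelity, seed = NULL) {
  stopifnot(inherits(tree, "lg_grid"))
  if (fidelity < 0 || fidelity > 1) stop("`fidelity` must lie in [0, 1]")
  local_seed(seed, {
    g <- smooth_field(tree$nrows, tree$ncols, 6)
    g01 <- (g - min(g)) / max(max(g) - min(g), .Machine$double.eps)
    p <- fidelity * tree$values + (1 - fidelity) * g01
    p[is.na(tree$values)] <- NA
    grid_create(pmin(pmax(p, 0), 1), xll = tree$xll, yll = tree$yll,
                cellsize = tree$cellsize, nodata = tree$nodata)
  })
}

#' Simulate an expert elicitation panel with known variance structure
#'
#' Generates a complete expert x species x land-cover x distance panel
#' of traversal probabilities: each estimate is the true mean for its
#' combination plus zero-mean Gaussian expert, land-cover and species
#' effects and residual noise, with component variances realizing the
#' requested shares of `total_sd^2`, clipped to the elicitation bounds
#' `[0.0001, 1]`. Distance enters through the true means, which are
#' non-increasing in distance.
#'
#' @param n_experts number of experts (default 5, as in a typical
#'   elicitation panel).
#' @param species character vector of species codes.
#' @param landcovers character vector of land-cover class names
#'   (default the nine classes of [landcover_classes()]).
#' @param distances_m elicitation distances in metres (default the seven
#'   distances 100-10000).
#' @param true_mean function of distance (metres) giving the true mean
#'   probability, or a single number; must be non-increasing in
#'   distance. Default `exp(-d / 2000)` floored at 0.02.
#' @param shares named numeric vector of variance shares for `expert`,
#'   `landcover`, `species` (each in `[0, 1]`, sum `<= 1`); the residual
#'   takes the remainder.
#' @param total_sd total standard deviation of the generated effects
#'   (default 0.15).
#' @param seed optional RNG seed.
#' @return expert panel data.frame (see [as_expert_panel()]).
#' @export
simulate_expert_panel <- function(n_experts = 5,
                                  species = c("SPA", "SPB", "SPC"),
                                  landcovers = names(landcover_classes()),
                                  distances_m = c(100, 200, 500, 1000,
                                                  2000, 5000, 10000),
                                  true_mean = NULL,
                                  shares = c(expert = 0.1,
                                             landcover = 0.15,
                                             species = 0.08),
                                  total_sd = 0.15, seed = NULL) {
  for (nm in c("expert", "landcover", "species"))
    if (is.na(shares[nm])) shares[nm] <- 0
  shares <- shares[c("expert", "landcover", "species")]
  if (any(shares < 0) || sum(shares) > 1)
    stop("variance shares must be >= 0 and sum to <= 1")
  if (is.null(true_mean)) {
    true_mean <- function(d) pmax(0.02, exp(-d / 2000))
  } else if (is.numeric(true_mean)) {
    mu0 <- true_mean
    true_mean <- function(d) rep(mu0, length(d))
  }
  mu <- true_mean(distances_m)
  if (is.unsorted(rev(mu), strictly = FALSE))
    stop("`true_mean` must be non-increasing in distance")
  local_seed(seed, {
    experts <- paste0("E", seq_len(n_experts))
    grid <- expand.grid(expert = experts, species = species,
                        landcover = landcovers, distance_m = distances_m,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    eff <- function(levels, share)
      stats::setNames(stats::rnorm(length(levels),
                                   sd = total_sd * sqrt(share)), levels)
    e_exp <- eff(experts, shares[["expert"]])
    e_lc <- eff(landcovers, shares[["landcover"]])
    e_sp <- eff(species, shares[["species"]])
    resid_sd <- total_sd * sqrt(1 - sum(shares))
    p <- true_mean(grid$distance_m) +
      e_exp[grid$expert] + e_lc[grid$landcover] + e_sp[grid$species] +
      stats::rnorm(nrow(grid), sd = resid_sd)
    grid$probability <- pmin(pmax(p, 0.0001), 1)
    as_expert_panel(grid)
  })
}
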