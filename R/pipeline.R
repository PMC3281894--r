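canonical_model_pattern <-
  "^(UNIFORM|TREE_1_(2|5|10|100)|HAB_1_(2|10)|[A-Za-z]+_EO_[0-9]+)$"

validate_run_config <- function(config) {
  if (is.null(config$seed) || !is.numeric(config$seed))
    stop("config must supply a numeric `seed`")
  config$landscape <- utils::modifyList(
    list(cover_fraction = 0.3, configuration = "aggregated",
         extent = 10000, cellsize = 25), config$landscape %||% list())
  config$n_sites <- config$n_sites %||% 4
  config$min_spacing <- config$min_spacing %||% 0
  config$buffer <- config$buffer %||% 1000
  config$models <- config$models %||% c("UNIFORM", "TREE_1_5")
  config$methods <- config$methods %||% c("LCP", "IBR")
  config$bootstrap <- utils::modifyList(list(iterations = 1000),
                                        config$bootstrap %||% list())
  config$eo <- utils::modifyList(
    list(n_experts = 5, merge_tolerance = NULL), config$eo %||% list())
  bad <- config$models[!grepl(canonical_model_pattern, config$models)]
  if (length(bad))
    stop("unrecognized model code(s): ", paste(bad, collapse = ", "))
  if (!all(config$methods %in% c("LCP", "IBR")))
    stop("`methods` must be a subset of {LCP, IBR}")
  config
}

#' Run the full landscape-resistance analysis pipeline
#'
#' Orchestrates one reproducible end-to-end run on a simulated
#' landscape: generate land cover and sampling sites, build the
#' requested resistance surfaces (uniform null, tree-cover,
#' habitat-suitability, expert-opinion land cover), compute pairwise
#' effective distances by the requested methods plus the three null
#' matrices, bootstrap every model matrix against the nulls, and write
#' all artifacts to an output directory. All randomness derives
#' deterministically from the single `seed` in the configuration, so a
#' rerun with the same configuration produces byte-identical outputs.
#'
#' @param config named list: `seed` (required); `landscape` (list with
#'   `cover_fraction`, `configuration`, `extent`, `cellsize`);
#'   `n_sites`; `min_spacing`; `buffer` (region buffer, metres);
#'   `models` (codes among `UNIFORM`, `TREE_1_{2,5,10,100}`,
#'   `HAB_1_{2,10}`, `<SPECIES>_EO_<distance>`); `methods` (subset of
#'   `LCP`, `IBR`); `bootstrap` (list with `iterations`); `eo` (list
#'   with `n_experts`, `merge_tolerance`).
#' @param outdir output directory; created if missing.
#' @return invisibly, a run report: list with the resolved `config`,
#'   the site table, the named matrix list, the bootstrap results and
#'   the paths of all written artifacts.
#' @export
run_pipeline <- function(config, outdir) {
  config <- validate_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  artifacts <- character(0)
  put <- function(name) {
    p <- file.path(outdir, name)
    artifacts <<- c(artifacts, p)
    p
  }

  ls <- config$landscape
  sim <- simulate_landcover(ls$cover_fraction, ls$configuration,
                            ls$extent, ls$cellsize, seed = seed + 1L)
  sites <- simulate_sites(sim$landcover, config$n_sites,
                          min_spacing = config$min_spacing,
                          seed = seed + 2L)
  region <- build_study_region(sites, buffer = config$buffer,
                               template = sim$landcover)
  write_ascii_grid(sim$tree, put("tree.asc"))
  write_sites(sites, put("sites.tsv"))

  eo_codes <- grep("_EO_", config$models, value = TRUE)
  panel <- NULL
  lc_scattered <- NULL
  if (length(eo_codes)) {
    sp <- sub("_EO_.*$", "", eo_codes)
    dist <- unique(as.numeric(sub("^.*_EO_", "", eo_codes)))
    panel <- simulate_expert_panel(n_experts = config$eo$n_experts,
                                   species = unique(sp),
                                   distances_m = sort(unique(c(
                                     dist, c(100, 5000)))),
                                   seed = seed + 3L)
    lc_scattered <- classify_scattered_trees(sim$landcover, sim$tree)
  }

  surfaces <- list()
  for (code in config$models) {
    surfaces[[code]] <- if (code == "UNIFORM") {
      uniform_surface(region)
    } else if (startsWith(code, "TREE_1_")) {
      tree_surface(sim$tree, as.numeric(sub("TREE_1_", "", code)), region)
    } else if (startsWith(code, "HAB_1_")) {
      sdm <- simulate_sdm(sim$tree, fidelity = 0.8, seed = seed + 4L)
      absences <- simulate_sites(sim$landcover, config$n_sites,
                                 require_tree = FALSE,
                                 landscape = "ABS", seed = seed + 5L)
      habitat <- binarize_sdm(sdm, sites, absences)
      habitat_surface(habitat, as.numeric(sub("HAB_1_", "", code)),
                      region)
    } else { # <SPECIES>_EO_<distance>
      sp <- sub("_EO_.*$", "", code)
      dd <- as.numeric(sub("^.*_EO_", "", code))
      tab <- build_eo_tables(panel, dd,
                             merge_tolerance = config$eo$merge_tolerance,
                             species = sp)[[sp]]
      landcover_surface(lc_scattered, tab, region, model = code)
    }
    write_ascii_grid(surfaces[[code]], put(paste0(code, ".asc")))
  }

  suite <- run_model_suite(surfaces, sites, region)
  drop <- character(0)
  if (!"LCP" %in% config$methods) drop <- c(drop, "_LCP$")
  if (!"IBR" %in% config$methods) drop <- c(drop, "_IBR$")
  for (pat in drop) suite <- suite[!grepl(pat, names(suite))]
  for (nm in names(suite))
    write_dist_matrix(suite[[nm]], put(paste0("dist_", nm, ".tsv")))

  nulls <- suite[c("GEOG", "logGEOG", "CS_UNIFORM")]
  modmats <- suite[setdiff(names(suite), names(nulls))]
  boots <- list()
  set.seed(seed + 6L)
  for (nm in names(modmats)) {
    fit <- null_model_fit(modmats[[nm]], nulls,
                          n_iterations = config$bootstrap$iterations)
    for (nn in names(fit)) {
      fit[[nn]]$model_a <- nm
      fit[[nn]]$model_b <- nn
      boots[[paste(nm, nn, sep = "~")]] <- fit[[nn]]
    }
  }
  if (length(boots))
    write_bootstrap_table(boots, put("bootstrap_r2.tsv"))

  report <- list(config = config, sites = sites, matrices = suite,
                 bootstrap = boots, artifacts = artifacts)
  lines <- c(
    sprintf("landres pipeline run (seed %d)", seed),
    sprintf("landscape: %s, cover %.2f, %g m extent @ %g m cells",
            ls$configuration, ls$cover_fraction, ls$extent, ls$cellsize),
    sprintf("sites: %d, buffer %g m", nrow(sites), config$buffer),
    sprintf("models: %s", paste(config$models, collapse = ", ")),
    sprintf("methods: %s", paste(config$methods, collapse = ", ")),
    sprintf("bootstrap: %d iterations", config$bootstrap$iterations),
    "artifacts:", paste(" ", basename(artifacts)))
  writeLines(lines, file.path(outdir, "run_report.txt"))
  invisible(report)
}
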