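#' Validate an expert panel table
#'
#' An expert panel is a long-form table of elicited traversal
#' probabilities: for each expert, species, land-cover class and
#' distance, the estimated probability that an individual bird would,
#' during its lifetime, traverse that distance of that land-cover.
#' Estimates are bounded to `[0.0001, 1]` (the elicitation instrument's
#' floor and ceiling). Missing estimates (`NA`) are allowed and dropped
#' from aggregation.
#'
#' @param df data.frame with columns `expert`, `species`, `landcover`,
#'   `distance_m`, `probability`.
#' @return the validated data.frame.
#' @export
as_expert_panel <- function(df) {
  need <- c("expert", "species", "landcover", "distance_m", "probability")
  if (!all(need %in% names(df)))
    stop("expert panel must have columns ", paste(need, collapse = ", "))
  p <- df$probability
  ok <- is.na(p) | (p >= 0.0001 & p <= 1)
  if (!all(ok))
    stop("probabilities must lie in [0.0001, 1]")
  df[, need]
}

#' Read an expert panel from delimited text
#' @param path path to a tab- or comma-separated long-form panel file.
#' @return validated panel data.frame (see [as_expert_panel()]).
#' @export
read_expert_panel <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else "\t"
  as_expert_panel(utils::read.table(path, header = TRUE, sep = sep,
                                    stringsAsFactors = FALSE))
}

#' Mean landscape conductivity per combination
#'
#' The mean over experts of the elicited traversal probability, for each
#' species x land-cover x distance combination, interpreted as the mean
#' probability of dispersal, i.e. the landscape conductivity of that
#' class for that species at that distance.
#'
#' @param panel an expert panel (see [as_expert_panel()]).
#' @return data.frame with columns `species`, `landcover`, `distance_m`,
#'   `conductivity`, `n_experts`.
#' @export
mean_conductivity <- function(panel) {
  panel <- as_expert_panel(panel)
  key <- interaction(panel$species, panel$landcover, panel$distance_m,
                     drop = TRUE)
  agg <- do.call(rbind, lapply(split(panel, key), function(d) {
    ok <- !is.na(d$probability)
    if (!any(ok))
      stop(sprintf(
        "no estimates for combination species=%s landcover=%s distance=%s",
        d$species[1], d$landcover[1], d$distance_m[1]))
    data.frame(species = d$species[1], landcover = d$landcover[1],
               distance_m = d$distance_m[1],
               conductivity = mean(d$probability[ok]),
               n_experts = sum(ok))
  }))
  rownames(agg) <- NULL
  agg[order(agg$species, agg$landcover, agg$distance_m), ]
}

#' Convert conductivity to land-cover resistance
#'
#' Resistance is the reciprocal of the mean dispersal probability
#' (conductivity). With the elicitation bounds of `[0.0001, 1]` the
#' resulting resistance lies in `[1, 10000]`; the 10000 ceiling arises
#' when every expert gives the minimum permissible probability.
#'
#' @param conductivity probability in `(0, 1]`, vectorised.
#' @return resistance values `1 / conductivity`.
#' @export
resistance_from_conductivity <- function(conductivity) {
  if (any(!is.finite(conductivity)) || any(conductivity <= 0) ||
      any(conductivity > 1))
    stop("`conductivity` must lie in (0, 1]")
  1 / conductivity
}

#' Merge land-cover classes with equal resistance
#'
#' Classes whose aggregated resistances are equal (within a relative
#' tolerance, default exact) are merged into a single resistance class;
#' in the elicitation this reduced the nine land-cover classes to six
#' resistance classes. The groups partition the input classes exactly.
#'
#' @param table named numeric vector of per-class resistances.
#' @param tolerance relative tolerance for equality (default 0, exact).
#' @return list with `groups` (list of character vectors of class names)
#'   and `reduced` (named vector, one entry per group, named by the
#'   concatenated member names).
#' @export
merge_equal_classes <- function(table, tolerance = 0) {
  stopifnot(is.numeric(table), !is.null(names(table)))
  ord <- order(table)
  v <- table[ord]
  grp <- integer(length(v))
  g <- 1L
  grp[1L] <- 1L
  for (i in seq_along(v)[-1L]) {
    ref <- v[which(grp == g)[1L]]
    if (abs(v[i] - ref) <= tolerance * abs(ref)) grp[i] <- g
    else { g <- g + 1L; grp[i] <- g }
  }
  groups <- split(names(v), grp)
  names(groups) <- NULL
  reduced <- vapply(groups, function(nm) unname(table[nm[1L]]), numeric(1))
  names(reduced) <- vapply(groups, paste, character(1), collapse = "+")
  list(groups = groups, reduced = reduced)
}

#' Variance decomposition of expert estimates
#'
#' Decomposes the variance of the elicited traversal probabilities into
#' crossed random-effect components for expert, land-cover and species
#' (plus distance when all distances are pooled), fitted by a linear
#' mixed-effects model with random intercepts; components are reported
#' as percentages of the total variance including the residual. With
#' `by_distance = TRUE` a separate decomposition is returned for each
#' elicitation distance (the distance component drops out within a
#' distance).
#'
#' @param panel an expert panel (see [as_expert_panel()]).
#' @param by_distance also return per-distance decompositions.
#' @return object of class `lg_varcomp`: list with `overall` (named
#'   percentage vector over `distance`, `expert`, `landcover`,
#'   `species`, `residual`), `degenerate` flag, and `per_distance`
#'   (component x distance matrix) when requested.
#' @export
variance_components <- function(panel, by_distance = FALSE) {
  panel <- as_expert_panel(panel)
  panel <- panel[!is.na(panel$probability), ]
  comps <- c("distance", "expert", "landcover", "species", "residual")

  decomp <- function(d, with_distance) {
    terms <- c(if (with_distance) "(1 | distance_m)",
               "(1 | expert)", "(1 | landcover)", "(1 | species)")
    used <- c(if (with_distance) "distance_m", "expert", "landcover",
              "species")
    for (f in used)
      if (length(unique(d[[f]])) < 2L)
        stop("need >= 2 levels of '", f, "' for variance decomposition")
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(stats::as.formula(
        paste("probability ~ 1 +", paste(terms, collapse = " + "))),
        data = d, REML = TRUE,
        control = lme4::lmerControl(check.conv.singular = "ignore"))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    v <- stats::setNames(vc$vcov, vc$grp)
    out <- c(distance = unname(v["distance_m"]),
             expert = unname(v["expert"]),
             landcover = unname(v["landcover"]),
             species = unname(v["species"]),
             residual = unname(v["Residual"]))
    out[is.na(out)] <- 0
    100 * out / sum(out)
  }

  degenerate <- stats::var(panel$probability) == 0
  if (degenerate) {
    overall <- stats::setNames(rep(0, 5), comps)
  } else {
    multi_d <- length(unique(panel$distance_m)) > 1L
    overall <- decomp(panel, with_distance = multi_d)
  }
  res <- list(overall = overall, degenerate = degenerate)
  if (by_distance) {
    ds <- sort(unique(panel$distance_m))
    per <- sapply(ds, function(dd) {
      sub <- panel[panel$distance_m == dd, ]
      if (stats::var(sub$probability) == 0)
        stats::setNames(rep(0, 5), comps)
      else decomp(sub, with_distance = FALSE)
    })
    colnames(per) <- as.character(ds)
    res$per_distance <- per[setdiff(comps, "distance"), , drop = FALSE]
  }
  class(res) <- "lg_varcomp"
  res
}

#' @export
print.lg_varcomp <- function(x, ...) {
  cat("<lg_varcomp> % of variance",
      if (x$degenerate) "(degenerate: zero total variance)", "\n")
  print(round(x$overall, 1))
  if (!is.null(x$per_distance)) {
    cat("per distance (m):\n")
    print(round(x$per_distance, 1))
  }
  invisible(x)
}

#' Build per-species expert-opinion resistance tables
#'
#' For one elicitation distance, aggregates the panel to mean
#' conductivity per species and land-cover, converts to resistance by
#' reciprocal, optionally merges classes with equal resistance, and
#' labels each table `<SPECIES>_EO_<distance>`.
#'
#' @param panel an expert panel (see [as_expert_panel()]).
#' @param distance one of the panel's elicitation distances (metres).
#' @param merge_tolerance relative tolerance passed to
#'   [merge_equal_classes()]; `NULL` (default) skips merging.
#' @param species optional character vector of species to include; a
#'   species absent from the panel is a coverage error.
#' @return named list of `lg_resistance_table` objects, one per
#'   species.
#' @export
build_eo_tables <- function(panel, distance, merge_tolerance = NULL,
                            species = NULL) {
  panel <- as_expert_panel(panel)
  if (!distance %in% panel$distance_m)
    stop("distance ", distance, " m is not in the panel's distance set")
  if (!is.null(species)) {
    miss <- setdiff(species, unique(panel$species))
    if (length(miss))
      stop("species absent from the expert panel: ",
           paste(miss, collapse = ", "))
  } else species <- sort(unique(panel$species))
  cond <- mean_conductivity(panel[panel$distance_m == distance, ])
  out <- lapply(species, function(sp) {
    d <- cond[cond$species == sp, ]
    tab <- stats::setNames(resistance_from_conductivity(d$conductivity),
                           d$landcover)
    if (!is.null(merge_tolerance)) {
      mg <- merge_equal_classes(tab, merge_tolerance)
      # keep one entry per class but snapped to its group representative
      for (grp in mg$groups) tab[grp] <- tab[grp[1L]]
    }
    structure(tab, model = paste0(sp, "_EO_", distance),
              class = "lg_resistance_table")
  })
  stats::setNames(out, species)
}
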