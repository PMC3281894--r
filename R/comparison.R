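#' Pairwise geographic distance matrix
#'
#' Straight-line Euclidean distances between sites in metres; optionally
#' natural-log transformed (the log-linear expectation of isolation by
#' distance in two dimensions).
#'
#' @param sites site data.frame (see [as_sites()]).
#' @param log_transform if `TRUE`, return the elementwise natural log of
#'   the distances (diagonal stays 0); requires all pairwise distances
#'   `> 0`.
#' @return `lg_distmat` with method `GEOG` or `logGEOG`.
#' @export
geographic_distances <- function(sites, log_transform = FALSE) {
  sites <- as_sites(sites)
  if (nrow(sites) < 2L) stop("need at least two sites")
  m <- as.matrix(stats::dist(cbind(sites$x, sites$y)))
  if (log_transform) {
    off <- m[upper.tri(m)]
    if (any(off == 0))
      stop("duplicate coordinates: log-distance undefined for distance 0")
    m[upper.tri(m) | lower.tri(m)] <- log(m[upper.tri(m) | lower.tri(m)])
  }
  method <- if (log_transform) "logGEOG" else "GEOG"
  new_distmat(m, sites$id, method, method)
}

#' Sample disjoint (independent) site pairs
#'
#' A pairwise distance matrix on `n` sites holds `choose(n, 2)`
#' comparisons but only `floor(n / 2)` of them can be mutually
#' independent: no site may be used twice. This draws one such maximal
#' set uniformly at random over perfect matchings, by randomly permuting
#' the sites and pairing consecutive entries (with odd `n`, the leftover
#' site differs between draws).
#'
#' @param n_sites number of sites, `>= 2`.
#' @return integer matrix with `floor(n_sites / 2)` rows and columns
#'   `i`, `j`; every site index appears at most once.
#' @export
sample_independent_pairs <- function(n_sites) {
  if (n_sites < 2L) stop("`n_sites` must be >= 2")
  p <- sample.int(n_sites)
  k <- n_sites %/% 2L
  cbind(i = p[seq_len(k) * 2L - 1L], j = p[seq_len(k) * 2L])
}

#' Bootstrap correlation between two distance matrices over
#' independent pairs
#'
#' Entries of a pairwise distance matrix are non-independent, so the
#' squared correlation between two distance models is estimated by
#' repeatedly drawing a maximal set of disjoint site pairs (see
#' [sample_independent_pairs()]), extracting the corresponding entries of
#' both matrices, and computing the squared Pearson correlation. The mean
#' and the empirical 2.5/97.5 percentiles across iterations are
#' reported, conditioning the estimate on the true number of independent
#' data points rather than the inflated count of all pairs. Iterations in
#' which either selection has zero variance (or non-finite entries) are
#' discarded and counted.
#'
#' @param A,B symmetric distance matrices sharing the same site
#'   ordering.
#' @param n_iterations number of bootstrap iterations (default 1000).
#' @return object of class `lg_bootstrap`: list with `model_a`,
#'   `model_b`, `n_iterations`, `pairs_per_iteration`, `mean_r2`,
#'   `lo95`, `hi95`, `n_discarded` and the per-iteration `r2` vector.
#' @export
bootstrap_r2 <- function(A, B, n_iterations = 1000) {
  if (!is.matrix(A) || !is.matrix(B) || !all(dim(A) == dim(B)))
    stop("`A` and `B` must be matrices of identical dimension")
  n <- nrow(A)
  if (n < 4L) stop("need at least 4 sites (2 disjoint pairs)")
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B)))
    stop("`A` and `B` do not share the same site ordering")
  r2 <- rep(NA_real_, n_iterations)
  for (it in seq_len(n_iterations)) {
    prs <- sample_independent_pairs(n)
    a <- A[prs]; b <- B[prs]
    if (!all(is.finite(a)) || !all(is.finite(b))) next
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    r2[it] <- stats::cor(a, b)^2
  }
  keep <- r2[!is.na(r2)]
  if (!length(keep))
    stop("degenerate bootstrap: every iteration was discarded")
  q <- unname(stats::quantile(keep, c(0.025, 0.975), type = 7))
  structure(
    list(model_a = attr(A, "model"), model_b = attr(B, "model"),
         n_iterations = n_iterations,
         pairs_per_iteration = n %/% 2L,
         mean_r2 = mean(keep), lo95 = q[1], hi95 = q[2],
         n_discarded = n_iterations - length(keep), r2 = keep),
    class = "lg_bootstrap")
}

#' @export
print.lg_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<lg_bootstrap> %s vs %s: mean R2 = %.3f [%.3f, %.3f] (%d x %d pairs%s)\n",
    x$model_a %||% "A", x$model_b %||% "B", x$mean_r2, x$lo95, x$hi95,
    x$n_iterations, x$pairs_per_iteration,
    if (x$n_discarded) paste0(", ", x$n_discarded, " discarded") else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank candidate null models for a distance model
#'
#' Bootstraps the squared correlation of a distance model against each
#' candidate null matrix (typically `GEOG`, `logGEOG` and `CS_UNIFORM`)
#' and ranks the nulls by mean R-squared; the top entry is the
#' recommended conditioning null for that model.
#'
#' @param model an `lg_distmat`.
#' @param nulls named list of null `lg_distmat` objects sharing the
#'   model's site ordering.
#' @param n_iterations bootstrap iterations per null (default 1000).
#' @return list of `lg_bootstrap` results sorted by decreasing
#'   `mean_r2`, named by null model.
#' @export
null_model_fit <- function(model, nulls, n_iterations = 1000) {
  stopifnot(length(nulls) >= 1L)
  res <- lapply(nulls, function(nm) bootstrap_r2(model, nm, n_iterations))
  res[order(vapply(res, `[[`, numeric(1), "mean_r2"), decreasing = TRUE)]
}

#' Score an a-priori model ranking against observed correlations
#'
#' Hypotheses about which landscape models should best predict genetic
#' structure are encoded as ranked model lists (rank 1 = best expected
#' fit, ties allowed). Given observed mean R-squared values per model,
#' the agreement is the Spearman rank correlation (midrank ties) between
#' the predicted ranks and the ranks of the observed values in
#' descending order. Models with missing predicted rank (`NA`, not
#' applicable for that species) are dropped.
#'
#' @param predicted named numeric vector of predicted ranks.
#' @param observed named numeric vector of observed mean R-squared
#'   values covering every ranked model.
#' @return Spearman rank-agreement score in `[-1, 1]`.
#' @export
evaluate_ranking <- function(predicted, observed) {
  predicted <- predicted[!is.na(predicted)]
  miss <- setdiff(names(predicted), names(observed))
  if (length(miss))
    stop("observed values missing for model(s): ",
         paste(miss, collapse = ", "))
  obs <- observed[names(predicted)]
  stats::cor(rank(predicted, ties.method = "average"),
             rank(-obs, ties.method = "average"), method = "spearman")
}

#' Read the packaged a-priori hypothesis rankings
#'
#' Per-species predicted ranks of candidate effective-distance models
#' (1 = best expected fit, ties allowed, `NA` where a model is not
#' applicable to a species) together with the expected strength of
#' isolation by distance.
#'
#' @param path optional path to a tab-separated ranking table with
#'   columns `model` then one column per species code; a final row
#'   `IBD_STRENGTH` holds the strength labels. Default uses the packaged
#'   table.
#' @return list with `ranks` (data.frame model x species) and
#'   `ibd_strength` (named character vector).
#' @export
read_hypothesis_rankings <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hypothesis_rankings.tsv",
                        package = "landres", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  strength <- df[df$model == "IBD_STRENGTH", -1L, drop = FALSE]
  ranks <- df[df$model != "IBD_STRENGTH", , drop = FALSE]
  rownames(ranks) <- ranks$model
  ranks$model <- NULL
  for (cl in names(ranks)) ranks[[cl]] <- as.numeric(ranks[[cl]])
  list(ranks = ranks,
       ibd_strength = stats::setNames(as.character(unlist(strength)),
                                      names(strength)))
}

#' Write bootstrap comparison results as delimited text
#'
#' @param results list of `lg_bootstrap` objects.
#' @param path output path (tab separated).
#' @return `path`, invisibly.
#' @export
write_bootstrap_table <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(x)
    data.frame(model_a = x$model_a %||% NA_character_,
               model_b = x$model_b %||% NA_character_,
               mean_r2 = x$mean_r2, lo95 = x$lo95, hi95 = x$hi95,
               iterations = x$n_iterations,
               pairs = x$pairs_per_iteration,
               discarded = x$n_discarded)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
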