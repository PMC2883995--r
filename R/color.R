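#' Sample points uniformly on the color sphere
#'
#' Each point on the unit sphere is tagged with a unique color by mapping
#' its Cartesian coordinates affinely from `[-1, 1]` to RGB channels in
#' `[0, 1]`. Colors are labels only; they never enter any computation.
#'
#' @param n number of points.
#' @param seed optional integer seed.
#' @return List with `points` (`n x 3`, unit rows) and `colors`
#'   (`n x 3` in `[0, 1]`).
#' @export
sample_color_sphere <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(n * 3), n, 3)
  pts <- z / sqrt(rowSums(z^2))
  list(points = pts, colors = (pts + 1) / 2)
}

#' Sample a stochastic onym graph from sphere points
#'
#' Pairs subtending at most `threshold_angle` are synonym candidates;
#' pairs within the same angle of the antipode are antonym candidates
#' (for thresholds below 90 degrees no pair can qualify for both). Each
#' candidate pair is admitted independently with a single acceptance
#' probability calibrated from the analytically expected candidate count
#' so that the expected mean degree equals `mean_degree`.
#'
#' @param points `n x 3` matrix of unit vectors.
#' @param threshold_angle degrees, in (0, 90).
#' @param mean_degree target average number of onyms per point.
#' @param seed optional integer seed.
#' @return A [signed_graph] over tokens `c0001`, `c0002`, ...
#' @export
generate_onym_graph <- function(points, threshold_angle = 20,
                                mean_degree = 3.5, seed = NULL) {
  stopifnot(nrow(points) >= 2, threshold_angle > 0, threshold_angle < 90,
            mean_degree > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(points)
  cth <- cos(threshold_angle * pi / 180)
  C <- tcrossprod(points)
  ut <- upper.tri(C)
  syn <- which(ut & C >= cth, arr.ind = TRUE)
  ant <- which(ut & C <= -cth, arr.ind = TRUE)
  if (nrow(syn) + nrow(ant) == 0L)
    stop("no candidate pairs under the threshold; ",
         "increase threshold_angle or the number of points")
  # for uniform sphere pairs P(angle <= t or >= 180 - t) = 1 - cos(t)
  expected_candidates <- choose(n, 2) * (1 - cth)
  p_accept <- min(1, (mean_degree * n / 2) / expected_candidates)
  keep_s <- stats::runif(nrow(syn)) < p_accept
  keep_a <- stats::runif(nrow(ant)) < p_accept
  words <- sprintf("c%0*d", max(4L, nchar(n)), seq_len(n))
  edges <- data.frame(
    from = c(syn[keep_s, 1], ant[keep_a, 1]),
    to = c(syn[keep_s, 2], ant[keep_a, 2]),
    sign = c(rep(1, sum(keep_s)), rep(-1, sum(keep_a))))
  if (nrow(edges) == 0L)
    stop("stochastic selection produced an empty graph; ",
         "increase mean_degree, threshold_angle or the number of points")
  signed_graph(words, edges)
}

#' Generate a color-sphere world
#'
#' Bundles a uniform sphere sample and the stochastic onym graph drawn
#' from it: the ground-truth world the reconstruction pipeline is scored
#' against. Defaults match the reference simulation conditions (1000
#' points, threshold 20 degrees, mean degree 3.5, embedding dimension
#' 10).
#'
#' @param n_points number of sphere points.
#' @param embed_dim embedding dimension used at reconstruction.
#' @param threshold_angle degrees, in (0, 90).
#' @param mean_degree target average onym count per point.
#' @param seed integer seed (drives both the sample and the graph).
#' @return An object of class `color_world` with `points`, `colors`,
#'   `graph` and the generating parameters.
#' @export
color_world <- function(n_points = 1000, embed_dim = 10,
                        threshold_angle = 20, mean_degree = 3.5,
                        seed = NULL) {
  stopifnot(n_points >= 4)
  sph <- sample_color_sphere(n_points, seed = seed)
  g <- generate_onym_graph(sph$points, threshold_angle, mean_degree)
  structure(list(points = sph$points, colors = sph$colors, graph = g,
                 params = list(n_points = n_points, embed_dim = embed_dim,
                               threshold_angle = threshold_angle,
                               mean_degree = mean_degree, seed = seed)),
            class = "color_world")
}

#' @export
print.color_world <- function(x, ...) {
  st <- graph_stats(x$graph)
  cat(sprintf(
    paste0("Color world: %d sphere points, threshold %g deg, onym graph ",
           "with mean degree %.2f\n"),
    nrow(x$points), x$params$threshold_angle,
    st$mean_synonyms_per_word + st$mean_antonyms_per_word))
  invisible(x)
}

#' Reconstruct the color map from its onym graph
#'
#' Runs the full pipeline on the sampled graph: core extraction,
#' embedding in `embed_dim` dimensions, energy minimization, rotation to
#' principal components, significance assessment and normalization.
#' The reconstructed cloud is normalized to mean squared vector length
#' `target_dims = 3`, the pipeline's reporting convention for the
#' sphere; no ground-truth information enters the reconstruction.
#'
#' @param world a [color_world].
#' @param params,control energy and optimizer settings.
#' @param n_null null replicates for the dimension-significance test.
#' @param seed integer seed for the embedding (defaults to the world's
#'   seed plus one).
#' @param target_dims normalization target (mean squared vector length).
#' @return A `semantic_map` over the retained core tokens.
#' @export
reconstruct_color_map <- function(world, params = energy_params(),
                                  control = optimizer_control(),
                                  n_null = 19, seed = NULL,
                                  target_dims = 3) {
  stopifnot(inherits(world, "color_world"))
  if (is.null(seed))
    seed <- if (!is.null(world$params$seed)) world$params$seed + 1L else NULL
  semantic_map(world$graph, dims = world$params$embed_dim,
               params = params, control = control, core = TRUE,
               anchors = NULL, n_null = n_null, seed = seed,
               target_dims = target_dims)
}

#' Score a reconstruction against the ground truth
#'
#' Overall correlation between the original sphere coordinates of the
#' retained points and the first three reconstructed PCs. The measure is
#' invariant under rotations of either side, so the arbitrary
#' orientation of the reconstruction does not need aligning.
#'
#' @param world a [color_world].
#' @param m the reconstructed `semantic_map` (at least 4 retained words).
#' @return List with `oc` and `n_retained`.
#' @export
evaluate_reconstruction <- function(world, m) {
  stopifnot(inherits(world, "color_world"), inherits(m, "semantic_map"))
  idx <- match(m$words, world$graph$words)
  if (anyNA(idx)) stop("map words not drawn from this world")
  if (length(idx) < 4) stop("fewer than 4 retained words")
  k <- min(3L, ncol(m$pcs))
  list(oc = overall_correlation(world$points[idx, , drop = FALSE],
                                m$pcs[, seq_len(k), drop = FALSE]),
       n_retained = length(idx))
}

#' Robustness sweep of the color-map reconstruction
#'
#' Re-runs world generation, reconstruction and evaluation over a
#' parameter grid, with replicates. Failed cells (e.g. an empty core at
#' extreme settings) are recorded and the sweep continues.
#'
#' @param grid data frame with any of the columns `n_points`,
#'   `embed_dim`, `threshold_angle`, `mean_degree`; missing columns use
#'   the defaults of [color_world].
#' @param replicates replicate worlds per cell.
#' @param seed integer base seed.
#' @param n_null null replicates passed to [reconstruct_color_map]
#'   (0 skips the significance test and normalizes to 3 dimensions).
#' @param control optimizer settings.
#' @return Data frame: grid columns plus `mean_oc`, `sd_oc`,
#'   `n_failed`.
#' @export
reconstruction_sweep <- function(grid, replicates = 3, seed = 1,
                                 n_null = 0,
                                 control = optimizer_control()) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  defaults <- list(n_points = 1000, embed_dim = 10, threshold_angle = 20,
                   mean_degree = 3.5)
  out <- grid
  out$mean_oc <- NA_real_; out$sd_oc <- NA_real_; out$n_failed <- 0L
  for (i in seq_len(nrow(grid))) {
    pars <- defaults
    for (nm in intersect(names(defaults), names(grid)))
      pars[[nm]] <- grid[[nm]][i]
    ocs <- rep(NA_real_, replicates)
    for (r in seq_len(replicates)) {
      cell_seed <- seed + 1013L * i + r
      ocs[r] <- tryCatch({
        w <- color_world(pars$n_points, pars$embed_dim,
                         pars$threshold_angle, pars$mean_degree,
                         seed = cell_seed)
        m <- reconstruct_color_map(w, control = control, n_null = n_null,
                                   seed = cell_seed + 1L)
        evaluate_reconstruction(w, m)$oc
      }, error = function(e) NA_real_)
    }
    out$mean_oc[i] <- mean(ocs, na.rm = TRUE)
    out$sd_oc[i] <- stats::sd(ocs[!is.na(ocs)])
    out$n_failed[i] <- sum(is.na(ocs))
  }
  out
}

#' Export a color world as plain text
#'
#' Writes a TSV (`token`, `x`, `y`, `z`, `r`, `g`, `b`) and the graph
#' edge list next to it.
#'
#' @param world a [color_world].
#' @param path path of the point table; the edge list is written to
#'   `paste0(path, ".edges.tsv")`.
#' @return `path`, invisibly.
#' @export
write_color_world <- function(world, path) {
  tab <- data.frame(token = world$graph$words,
                    x = world$points[, 1], y = world$points[, 2],
                    z = world$points[, 3],
                    r = world$colors[, 1], g = world$colors[, 2],
                    b = world$colors[, 3])
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_edgelist(world$graph, paste0(path, ".edges.tsv"))
  invisible(path)
}
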