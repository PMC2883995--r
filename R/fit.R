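#' Fit a semantic map
#'
#' The central fitting function. Starting from a lexicon or signed graph,
#' it (optionally) extracts the core, allocates the words at random in a
#' `dims`-dimensional unit ball, minimizes the signed-graph energy,
#' rotates the converged configuration to principal components, assesses
#' how many dimensions are statistically significant against a
#' sign-shuffled null, standardizes axis signs against anchor words, and
#' rescales the cloud so its mean squared vector length equals the number
#' of significant dimensions.
#'
#' @param x an [onym_lexicon] or [signed_graph].
#' @param dims embedding dimension (default 26; results are insensitive
#'   between roughly 10 and 100).
#' @param params an [energy_params] object.
#' @param control an [optimizer_control] object.
#' @param core apply [extract_core] before fitting (default `TRUE`).
#' @param anchors an [anchor_set] for axis orientation, or `NULL` to skip
#'   sign standardization (e.g. for synthetic tokens).
#' @param n_null null replicates for [significant_dimensions]; `0` skips
#'   the significance assessment.
#' @param target_dims normalization target (mean squared vector length);
#'   defaults to the significant-dimension count.
#' @param seed integer seed governing initialization, annealing noise and
#'   the null ensemble.
#' @param ... unused.
#' @return An object of class `semantic_map`; see [rotate_to_pcs] for its
#'   fields. `fit` holds the optimizer report (`converged`, `steps`,
#'   `final_energy`, `monitor`).
#' @examples
#' lex <- onym_lexicon(
#'   c("good", "fine", "bad", "poor"),
#'   synonyms = list("fine", "good", "poor", "bad"),
#'   antonyms = list("bad", "poor", "good", "fine"))
#' m <- semantic_map(build_signed_graph(lex), dims = 3, n_null = 5,
#'                   anchors = NULL, seed = 1)
#' round(word_angle(m, "good", "bad"))
#' @export
semantic_map <- function(x, ...) UseMethod("semantic_map")

#' @rdname semantic_map
#' @export
semantic_map.onym_lexicon <- function(x, ...) {
  semantic_map(build_signed_graph(x), ...)
}

#' @rdname semantic_map
#' @export
semantic_map.signed_graph <- function(x, dims = 26,
                                      params = energy_params(),
                                      control = optimizer_control(),
                                      core = TRUE,
                                      anchors = default_anchors(),
                                      n_null = 19, target_dims = NULL,
                                      seed = NULL, ...) {
  cl <- match.call()
  g <- if (core) extract_core(x) else x
  if (n_words(g) < 2)
    stop("graph has fewer than 2 words after core extraction")
  if (is.null(seed)) seed <- as.integer(stats::runif(1, 0, 2^20))
  x0 <- init_config(n_words(g), dims, seed = seed)
  ctl <- control
  ctl$seed <- seed + 1L
  fit <- minimize_energy(x0, g, params, ctl)
  m <- rotate_to_pcs(fit$config, words = g$words, graph = g, fit = fit)
  if (n_null > 0) {
    m$n_significant <- significant_dimensions(
      m, g, n_null = n_null, seed = seed + 2L, params = params,
      control = control)
  }
  m <- standardize_signs(m, anchors)
  m <- normalize_map(m, target_dims)
  m$call <- cl
  m
}

#' @export
print.semantic_map <- function(x, ...) {
  cat(sprintf("Semantic map: %d words in %d dimensions\n",
              length(x$words), ncol(x$pcs)))
  if (!is.na(x$n_significant))
    cat(sprintf("  significant dimensions: %d\n", x$n_significant))
  cat(sprintf("  leading PC sd: %s\n",
              paste(sprintf("%.3f", utils::head(x$pc_sd, 4)),
                    collapse = ", ")))
  if (!is.null(x$fit))
    cat(sprintf("  optimizer: %s in %d steps (monitor: %s), energy %.4f\n",
                if (isTRUE(x$fit$converged)) "converged" else "stopped",
                x$fit$steps, x$fit$monitor, x$fit$final_energy))
  invisible(x)
}

#' @export
summary.semantic_map <- function(object, k = min(6L, ncol(object$pcs)),
                                 ...) {
  structure(list(map = object, pcs = pc_summary(object, k),
                 lengths = vector_length_stats(object)),
            class = "summary.semantic_map")
}

#' @export
print.summary.semantic_map <- function(x, ...) {
  print(x$map)
  cat("\nPer-PC summary:\n")
  print(x$pcs, row.names = FALSE, digits = 3)
  cat(sprintf("\nVector length: median %.3f, mean %.3f, sd %.3f\n",
              x$lengths$median, x$lengths$mean, x$lengths$sd))
  invisible(x)
}

#' @export
coef.semantic_map <- function(object, ...) {
  structure(object$pcs,
            dimnames = list(object$words,
                            paste0("PC", seq_len(ncol(object$pcs)))))
}

#' Predict onym relations from a fitted map
#'
#' For each word pair, reports the cosine and angle of the embedded
#' vectors and the dot-product relation call: `synonym` for a positive
#' dot product, `antonym` for a negative one, `abstain` at exactly zero.
#' By default the listed onym pairs of the stored graph are scored, so
#' the prediction table doubles as a training-edge accuracy report.
#'
#' @param object a `semantic_map`.
#' @param newdata optional data frame with columns `word1`, `word2`.
#' @param ... unused.
#' @return Data frame with `word1`, `word2`, `cosine`, `angle`,
#'   `relation` and, for listed pairs, the listed `sign`.
#' @export
predict.semantic_map <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$graph)) stop("no stored graph; supply `newdata`")
    e <- graph_edges(object$graph)
    newdata <- data.frame(word1 = object$graph$words[e$from],
                          word2 = object$graph$words[e$to],
                          sign = e$sign)
  }
  cs <- mapply(function(a, b) word_cosine(object, a, b),
               newdata$word1, newdata$word2)
  newdata$cosine <- as.numeric(cs)
  newdata$angle <- acos(pmin(1, pmax(-1, newdata$cosine))) * 180 / pi
  newdata$relation <- ifelse(newdata$cosine > 0, "synonym",
                             ifelse(newdata$cosine < 0, "antonym",
                                    "abstain"))
  newdata
}

#' @export
fitted.semantic_map <- function(object, ...) {
  p <- predict(object)
  stats::setNames(p$cosine, paste(p$word1, p$word2, sep = "~"))
}

#' @export
residuals.semantic_map <- function(object, ...) {
  p <- predict(object)
  stats::setNames(p$sign - p$cosine, paste(p$word1, p$word2, sep = "~"))
}

#' Plot a semantic map
#'
#' `type = "map"` draws the maximum-spread projection (PC2 against PC1);
#' `type = "scree"` draws per-PC standard deviations.
#'
#' @param x a `semantic_map`.
#' @param type `"map"` or `"scree"`.
#' @param labels words to annotate (`type = "map"`).
#' @param ... passed to the underlying plotting function.
#' @export
plot.semantic_map <- function(x, type = c("map", "scree"),
                              labels = NULL, ...) {
  type <- match.arg(type)
  if (type == "map") {
    graphics::plot(x$pcs[, 1], x$pcs[, 2], pch = 16, cex = 0.4,
                   col = "steelblue", xlab = "PC1", ylab = "PC2", ...)
    if (!is.null(labels)) {
      i <- match(labels, x$words)
      i <- i[!is.na(i)]
      graphics::text(x$pcs[i, 1], x$pcs[i, 2], x$words[i], pos = 3,
                     cex = 0.8)
    }
  } else {
    graphics::barplot(x$pc_sd, names.arg = seq_along(x$pc_sd),
                      xlab = "PC", ylab = "standard deviation", ...)
  }
  invisible(x)
}
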