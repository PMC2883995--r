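new_semantic_map <- function(words, pcs, flips = NULL, graph = NULL,
                             fit = NULL, n_significant = NA_integer_,
                             normalized_to = NA_real_, call = NULL,
                             raw_pc_sd = NULL) {
  v <- apply(pcs, 2, stats::var)
  structure(list(
    words = words,
    pcs = unname(pcs),
    pc_sd = sqrt(v),
    raw_pc_sd = if (is.null(raw_pc_sd)) sqrt(v) else raw_pc_sd,
    pc_kurtosis = apply(pcs, 2, pearson_kurtosis),
    cum_variance = if (sum(v) > 0) cumsum(v) / sum(v) else rep(NA_real_, length(v)),
    flips = if (is.null(flips)) rep(FALSE, ncol(pcs)) else flips,
    n_significant = n_significant,
    normalized_to = normalized_to,
    graph = graph,
    fit = fit,
    call = call),
    class = "semantic_map")
}

pearson_kurtosis <- function(z) {
  m2 <- mean((z - mean(z))^2)
  if (m2 == 0) return(NA_real_)
  mean((z - mean(z))^4) / m2^2
}

#' Rotate a configuration to its principal components
#'
#' Centers the coordinate cloud at its mean and rotates it (via SVD) so
#' that columns are principal axes in descending variance order. The
#' rotation preserves all pairwise angles of the centered cloud.
#'
#' @param x `N x d` configuration matrix (at least two rows).
#' @param words token vector naming the rows.
#' @param graph optional [signed_graph] to carry along for analytics.
#' @param fit optional optimizer report to store.
#' @return A `semantic_map` object with elements `words`, `pcs`, `pc_sd`,
#'   `pc_kurtosis`, `cum_variance`, `flips`.
#' @export
rotate_to_pcs <- function(x, words = NULL, graph = NULL, fit = NULL) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  if (is.null(words))
    words <- if (!is.null(graph)) graph$words else
      sprintf("w%0*d", nchar(nrow(x)), seq_len(nrow(x)))
  if (length(words) != nrow(x)) stop("`words` must name every row")
  xc <- sweep(x, 2, colMeans(x))
  if (max(abs(xc)) == 0) stop("degenerate input: all points identical")
  sv <- svd(xc)
  new_semantic_map(words, xc %*% sv$v, graph = graph, fit = fit)
}

#' Anchor words fixing axis orientations
#'
#' PC signs out of the optimizer are arbitrary (the energy is symmetric
#' about the origin), so each axis is oriented by a small list of pole
#' words. The shipped defaults orient the four leading axes toward
#' "good", "exciting", "open" and "elaborate"; they are plain lists and
#' can be replaced wholesale.
#'
#' @return A list of class `anchor_set`: one element per axis, each with
#'   character vectors `positive` and `negative` (disjoint).
#' @export
default_anchors <- function() {
  anchor_set(list(
    list(positive = c("good", "well", "clear", "improve", "praise",
                      "accept", "happy", "support"),
         negative = c("bad", "poor", "decline", "stop", "fail", "reject",
                      "sad", "badly", "criticize")),
    list(positive = c("exciting", "hard", "stiff", "heavy", "serious",
                      "extreme", "loud", "tough", "fierce"),
         negative = c("calm", "calming", "relaxed", "mild", "easy",
                      "gentle", "modest", "quiet", "soft")),
    list(positive = c("open", "free", "release", "go", "fire", "freedom",
                      "independent", "new"),
         negative = c("close", "closed", "final", "detain", "restraint",
                      "confine", "swallow", "restrain")),
    list(positive = c("elaborate", "later", "advanced", "soggy", "slowly",
                      "wordy", "far ahead"),
         negative = c("basic", "earlier", "concise", "plain", "quickly",
                      "crisp", "austere"))))
}

#' @rdname default_anchors
#' @param axes list of per-axis `list(positive=, negative=)` entries.
#' @export
anchor_set <- function(axes) {
  for (a in axes) {
    if (length(intersect(a$positive, a$negative)))
      stop("anchor poles must be disjoint per axis")
  }
  structure(axes, class = "anchor_set")
}

#' Standardize axis signs against anchor words
#'
#' Axis `k` is negated iff the mean coordinate of its positive-pole
#' anchors minus that of its negative-pole anchors is negative. Axes with
#' no anchor word present in the map are left unflipped with a warning.
#'
#' @param m a `semantic_map`.
#' @param anchors an [anchor_set]; `NULL` leaves the map untouched.
#' @return The map with `flips` recording which axes were negated.
#' @export
standardize_signs <- function(m, anchors = default_anchors()) {
  stopifnot(inherits(m, "semantic_map"))
  if (is.null(anchors)) return(m)
  flips <- m$flips
  for (k in seq_len(min(length(anchors), ncol(m$pcs)))) {
    pos <- match(anchors[[k]]$positive, m$words)
    neg <- match(anchors[[k]]$negative, m$words)
    pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
    if (length(pos) + length(neg) == 0L) {
      warning("no anchor words present for axis ", k, "; left unflipped")
      next
    }
    mp <- if (length(pos)) mean(m$pcs[pos, k]) else 0
    mn <- if (length(neg)) mean(m$pcs[neg, k]) else 0
    if (mp - mn < 0) {
      m$pcs[, k] <- -m$pcs[, k]
      flips[k] <- !flips[k]
    }
  }
  m$flips <- flips
  m
}

#' Rescale a map to a target mean squared vector length
#'
#' Applies one global scale factor so that the mean squared word-vector
#' length equals `target_dims`. With the target equal to the number of
#' significant dimensions, each significant PC ends up with standard
#' deviation near 1 when the significant PCs share the variance evenly.
#' Uniform scaling preserves every angle; applying the operation twice
#' with the same target is the identity.
#'
#' @param m a `semantic_map` with nonzero total variance.
#' @param target_dims target mean squared vector length (defaults to the
#'   map's significant-dimension count when known, else the number of PCs
#'   covering 99.9 percent of variance).
#' @return The rescaled map, with `normalized_to` recording the target.
#' @export
normalize_map <- function(m, target_dims = NULL) {
  stopifnot(inherits(m, "semantic_map"))
  msl <- mean(rowSums(m$pcs^2))
  if (msl == 0) stop("zero variance: cannot normalize")
  if (is.null(target_dims)) {
    target_dims <- if (!is.na(m$n_significant) && m$n_significant > 0)
      m$n_significant
    else
      which(m$cum_variance >= 0.999)[1]
  }
  stopifnot(target_dims > 0)
  s <- sqrt(target_dims / msl)
  new_semantic_map(m$words, m$pcs * s, flips = m$flips,
                   graph = m$graph, fit = m$fit,
                   n_significant = m$n_significant,
                   normalized_to = target_dims, call = m$call,
                   raw_pc_sd = m$raw_pc_sd)
}

#' Per-PC summary table
#'
#' @param m a `semantic_map`.
#' @param k number of leading PCs to report.
#' @param excess report excess kurtosis (normal = 0) instead of the
#'   Pearson convention (normal = 3).
#' @return Data frame with columns `pc`, `sd`, `kurtosis`, `cum_var`.
#' @export
pc_summary <- function(m, k = ncol(m$pcs), excess = FALSE) {
  stopifnot(inherits(m, "semantic_map"), k <= ncol(m$pcs))
  data.frame(pc = seq_len(k),
             sd = m$pc_sd[seq_len(k)],
             kurtosis = m$pc_kurtosis[seq_len(k)] - if (excess) 3 else 0,
             cum_var = m$cum_variance[seq_len(k)])
}

#' Number of statistically significant map dimensions
#'
#' Compares the map's PC variance fractions against a null ensemble of
#' maps fitted to sign-shuffled copies of the same graph (identical
#' topology, permuted +/-1 edge labels), which keeps the degree structure
#' but destroys the semantic signal. The count is the largest `k` such
#' that each of the first `k` PC variances exceeds the 95th percentile of
#' the corresponding (index-matched) null PC variances. Variances are
#' compared on the fitted energy scale, which the energy function itself
#' sets, so maps rescaled by [normalize_map] are handled through their
#' stored fitted-scale record; maps loaded from disk without that record
#' use their current scale. On relation graphs sampled from metric
#' neighborhoods the unsigned topology alone sustains a structured
#' embedding, so this null is conservative for trailing signal
#' dimensions (see the methods vignette).
#'
#' @param m a `semantic_map` fitted to `g`.
#' @param g the [signed_graph] the map was built from (defaults to the
#'   graph stored in the map).
#' @param n_null number of sign-shuffled null maps (at least 1).
#' @param seed integer seed for the null ensemble.
#' @param params,control energy and optimizer settings used for the null
#'   fits; defaults match [semantic_map()] defaults.
#' @return Integer count of significant dimensions.
#' @export
significant_dimensions <- function(m, g = m$graph, n_null = 19,
                                   seed = NULL,
                                   params = energy_params(),
                                   control = optimizer_control()) {
  stopifnot(inherits(m, "semantic_map"))
  if (is.null(g)) stop("a signed graph is needed to build the null")
  if (n_null < 1) stop("n_null must be at least 1")
  if (is.null(seed)) seed <- 0L
  d <- ncol(m$pcs)
  v <- if (!is.null(m$raw_pc_sd)) m$raw_pc_sd^2 else m$pc_sd^2
  null_var <- matrix(NA_real_, n_null, d)
  for (b in seq_len(n_null)) {
    gb <- shuffle_signs(g, seed = seed + b)
    x0 <- init_config(n_words(gb), d, seed = seed + 7919L + b)
    ctl <- control
    ctl$seed <- seed + 104729L + b
    fit <- minimize_energy(x0, gb, params, ctl)
    xc <- sweep(fit$config, 2, colMeans(fit$config))
    null_var[b, ] <- svd(xc)$d^2 / (nrow(xc) - 1)
  }
  thr <- apply(null_var, 2, stats::quantile, probs = 0.95, names = FALSE)
  below <- which(v <= thr)
  if (length(below) == 0L) d else below[1] - 1L
}
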