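word_index <- function(m, w) {
  i <- match(w, m$words)
  if (is.na(i)) stop("word not in map: ", w)
  i
}

word_cosine <- function(m, w1, w2) {
  v1 <- m$pcs[word_index(m, w1), ]
  v2 <- m$pcs[word_index(m, w2), ]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    stop("undefined angle: zero-length vector for '",
         if (n1 == 0) w1 else w2, "'")
  sum(v1 * v2) / (n1 * n2)
}

#' Angle between two word vectors
#'
#' @param m a `semantic_map`.
#' @param w1,w2 words present in the map with nonzero vectors.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
word_angle <- function(m, w1, w2) {
  acos(pmin(1, pmax(-1, word_cosine(m, w1, w2)))) * 180 / pi
}

#' Dot-product onym classification
#'
#' Calls a pair a synonym if the dot product of the embedded vectors is
#' positive, an antonym if negative, and abstains at exactly zero.
#'
#' @inheritParams word_angle
#' @return One of `"synonym"`, `"antonym"`, `"abstain"`.
#' @export
classify_onym <- function(m, w1, w2) {
  v1 <- m$pcs[word_index(m, w1), ]
  v2 <- m$pcs[word_index(m, w2), ]
  d <- sum(v1 * v2)
  if (d > 0) "synonym" else if (d < 0) "antonym" else "abstain"
}

all_pair_angles <- function(m, i, j) {
  vi <- m$pcs[i, , drop = FALSE]
  vj <- m$pcs[j, , drop = FALSE]
  ni <- sqrt(rowSums(vi^2)); nj <- sqrt(rowSums(vj^2))
  cs <- rowSums(vi * vj) / (ni * nj)
  acos(pmin(1, pmax(-1, cs))) * 180 / pi
}

#' Angle distributions of word-pair classes
#'
#' Histograms (over `[0, 180]` degrees) of the pair classes that
#' characterize a map: (1) listed synonym pairs, (2) listed antonym
#' pairs, (3) onym-of-onym pairs not themselves listed onyms, (4) a
#' random sample of unrelated pairs.
#'
#' @param m a `semantic_map` built on `g`.
#' @param g the [signed_graph] of listed relations.
#' @param bins number of histogram bins.
#' @param unrelated_sample number of random unrelated pairs to draw.
#' @param seed integer seed for the unrelated sample.
#' @return A list of class `onym_histograms`: per class, the angles, the
#'   `hist` object, the median and the mean.
#' @export
onym_angle_histograms <- function(m, g = m$graph, bins = 36,
                                  unrelated_sample = 10000,
                                  seed = NULL) {
  stopifnot(inherits(m, "semantic_map"), inherits(g, "signed_graph"))
  if (!is.null(seed)) set.seed(seed)
  idx <- match(g$words, m$words)
  if (anyNA(idx)) stop("map/graph word mismatch")
  e <- graph_edges(g)
  ei <- idx[e$from]; ej <- idx[e$to]
  classes <- list()
  classes$synonyms <- all_pair_angles(m, ei[e$sign > 0], ej[e$sign > 0])
  classes$antonyms <- all_pair_angles(m, ei[e$sign < 0], ej[e$sign < 0])

  # two-step neighbors that are not themselves listed onyms
  A <- abs(g$W) > 0
  A2 <- (A %*% A) > 0
  oo <- Matrix::triu(A2 & !A, 1)
  Matrix::diag(oo) <- FALSE
  sm <- Matrix::summary(methods::as(methods::as(oo, "generalMatrix"),
                                    "TsparseMatrix"))
  sm <- sm[sm$x != 0, , drop = FALSE]
  classes$onyms_of_onyms <- all_pair_angles(m, idx[sm$i], idx[sm$j])

  n <- length(g$words)
  i <- sample.int(n, unrelated_sample, replace = TRUE)
  j <- sample.int(n - 1L, unrelated_sample, replace = TRUE)
  j <- j + (j >= i)
  related <- abs(g$W)[cbind(i, j)] > 0 | as.matrix(A2[cbind(i, j)]) > 0
  classes$unrelated <- all_pair_angles(m, idx[i[!related]],
                                       idx[j[!related]])

  breaks <- seq(0, 180, length.out = bins + 1)
  structure(lapply(classes, function(a) {
    list(angles = a,
         hist = if (length(a)) graphics::hist(a, breaks = breaks,
                                              plot = FALSE) else NULL,
         median = stats::median(a), mean = mean(a))
  }), class = "onym_histograms")
}

#' @export
print.onym_histograms <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("%-16s n=%6d  median %6.1f deg  mean %6.1f deg\n", nm,
                length(x[[nm]]$angles), x[[nm]]$median, x[[nm]]$mean))
  invisible(x)
}

#' Words most representative of a principal component
#'
#' Scores every word as its coordinate on axis `k` divided by the square
#' root of its vector length -- the geometric mean of the projection on
#' the axis and the alignment with it -- and returns the highest and
#' lowest scoring words.
#'
#' @param m a `semantic_map`.
#' @param k PC index.
#' @param n number of words per direction.
#' @return List with data frames `top` (descending) and `bottom`
#'   (ascending), columns `word`, `score`.
#' @export
rank_words <- function(m, k, n = 10) {
  stopifnot(inherits(m, "semantic_map"), k >= 1, k <= ncol(m$pcs))
  len <- sqrt(rowSums(m$pcs^2))
  ok <- len > 0
  score <- m$pcs[ok, k] / sqrt(len[ok])
  words <- m$words[ok]
  o <- order(score, decreasing = TRUE)
  list(top = data.frame(word = words[o[seq_len(min(n, length(o)))]],
                        score = score[o[seq_len(min(n, length(o)))]]),
       bottom = data.frame(
         word = rev(words[o])[seq_len(min(n, length(o)))],
         score = rev(score[o])[seq_len(min(n, length(o)))]))
}

#' Antonym pairs most representative of a principal component
#'
#' Scores each listed antonym pair by the absolute coordinate difference
#' on axis `k` divided by the square root of the Euclidean distance of
#' the two vectors; the positive-pole word is listed first.
#'
#' @param m a `semantic_map`.
#' @param g a [signed_graph] with at least one antonym edge.
#' @param k PC index.
#' @param n number of pairs.
#' @return Data frame `word_pos`, `word_neg`, `score`, descending.
#' @export
rank_antonym_pairs <- function(m, g = m$graph, k, n = 10) {
  stopifnot(inherits(m, "semantic_map"))
  e <- graph_edges(g)
  e <- e[e$sign < 0, , drop = FALSE]
  if (nrow(e) == 0L) stop("graph has no antonym edges")
  i <- match(g$words[e$from], m$words)
  j <- match(g$words[e$to], m$words)
  d <- sqrt(rowSums((m$pcs[i, , drop = FALSE] -
                       m$pcs[j, , drop = FALSE])^2))
  keep <- d > 0
  if (!all(keep)) message(sum(!keep), " coincident antonym pair(s) skipped")
  i <- i[keep]; j <- j[keep]; d <- d[keep]
  diff <- m$pcs[i, k] - m$pcs[j, k]
  score <- abs(diff) / sqrt(d)
  pos <- ifelse(diff >= 0, m$words[i], m$words[j])
  neg <- ifelse(diff >= 0, m$words[j], m$words[i])
  o <- order(score, decreasing = TRUE)[seq_len(min(n, length(score)))]
  data.frame(word_pos = pos[o], word_neg = neg[o], score = score[o])
}

#' Two-step neighborhood of a word
#'
#' The onyms of onyms of `w`: every word reachable in exactly two hops
#' (synonyms of synonyms, synonyms of antonyms, antonyms of synonyms,
#' antonyms of antonyms), excluding `w` itself. Directly listed onyms are
#' excluded unless `include_listed` is `TRUE`.
#'
#' @param g a [signed_graph].
#' @param w a word in `g`.
#' @param include_listed keep words that are also direct onyms of `w`.
#' @return Character vector of words.
#' @export
onyms_of_onyms <- function(g, w, include_listed = FALSE) {
  i <- match(w, g$words)
  if (is.na(i)) stop("word not in graph: ", w)
  A <- abs(g$W) > 0
  one <- which(A[i, ])
  two <- which(Matrix::colSums(A[one, , drop = FALSE] != 0) > 0)
  two <- setdiff(two, i)
  if (!include_listed) two <- setdiff(two, one)
  g$words[two]
}

#' Dot-product prediction of listed relations among related words
#'
#' Within the onyms of onyms of `w` that are also listed onyms of `w`,
#' correlates the cosine of the angle with `w` against the listed binary
#' label (+1 synonym, -1 antonym). Significance is from the two-sided
#' t-distribution test for a Pearson correlation.
#'
#' @param m a `semantic_map`.
#' @param g the [signed_graph] of listed relations.
#' @param w a word present in both.
#' @return List with `R`, `p`, `N`.
#' @export
oo_prediction_correlation <- function(m, g = m$graph, w) {
  i <- match(w, g$words)
  if (is.na(i)) stop("word not in graph: ", w)
  pool <- onyms_of_onyms(g, w, include_listed = TRUE)
  labels <- g$W[i, match(pool, g$words)]
  keep <- labels != 0
  pool <- pool[keep]; labels <- as.numeric(labels[keep])
  if (length(pool) < 3 || length(unique(labels)) < 2)
    stop("insufficient labeled onym-of-onym pairs for '", w, "'")
  cs <- vapply(pool, function(u) word_cosine(m, w, u), numeric(1))
  r <- stats::cor(cs, labels)
  n <- length(pool)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(R = r, p = p, N = n)
}

#' Connotation octant of a word
#'
#' Assigns the (PC1, PC2) projection to one of eight 45-degree sectors
#' centered on the semi-axes and diagonals: good (+PC1), good/exciting,
#' exciting (+PC2), bad/exciting, bad, bad/calming, calming, good/calming.
#' Boundary angles (odd multiples of 22.5 degrees) go to the
#' counter-clockwise sector; a projection at the origin is `"neutral"`.
#'
#' @param m a `semantic_map`.
#' @param w a word in the map.
#' @return Sector label.
#' @export
connotation_octant <- function(m, w) {
  v <- m$pcs[word_index(m, w), 1:2]
  if (all(v == 0)) return("neutral")
  sectors <- c("good", "good/exciting", "exciting", "bad/exciting",
               "bad", "bad/calming", "calming", "good/calming")
  ang <- (atan2(v[2], v[1]) * 180 / pi) %% 360
  # the small offset sends exact 22.5-degree boundaries to the
  # counter-clockwise sector independently of floating-point noise
  sectors[(floor((ang + 22.5) / 45 + 1e-9) %% 8) + 1]
}

#' Distribution of word-vector lengths
#'
#' @param m a `semantic_map`.
#' @param probs percentile grid for the cumulative curve.
#' @return List with `median`, `mean`, `sd` and a `percentiles` data
#'   frame.
#' @export
vector_length_stats <- function(m, probs = seq(0, 1, 0.025)) {
  len <- sqrt(rowSums(m$pcs^2))
  list(median = stats::median(len), mean = mean(len),
       sd = stats::sd(len),
       percentiles = data.frame(prob = probs,
                                length = stats::quantile(len, probs,
                                                         names = FALSE)))
}

#' Read a word-frequency table
#'
#' Two-column TSV (`word`, `count`) with a header row.
#'
#' @param path file path.
#' @return Named numeric vector of nonnegative counts.
#' @export
read_frequency_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE,
                           colClasses = c("character", "numeric"))
  if (any(tab[[2]] < 0)) stop("negative frequency count in ", path)
  stats::setNames(tab[[2]], tab[[1]])
}

#' Frequency-weighted concept mean
#'
#' The frequency-weighted average position of all words in the map -- the
#' most representative meaning composed across a language. Standard
#' errors come from a word-level bootstrap (resampling words with
#' replacement); the difference from the unweighted mean is tested per
#' axis with a two-sided bootstrap z-test.
#'
#' @param m a `semantic_map`.
#' @param freq named numeric vector of counts (see
#'   [read_frequency_table]); at least one word must be shared with the
#'   map.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return List of class `concept_mean` with `vector`, `se`, `n_words`,
#'   `diff` (weighted minus unweighted mean), `diff_se`, `p_diff`.
#' @export
frequency_weighted_mean <- function(m, freq, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(m, "semantic_map"))
  common <- intersect(m$words, names(freq))
  if (length(common) == 0L) stop("no words shared between map and table")
  if (!is.null(seed)) set.seed(seed)
  i <- match(common, m$words)
  w <- as.numeric(freq[common])
  if (sum(w) <= 0) stop("all shared words have zero frequency")
  X <- m$pcs[i, , drop = FALSE]
  wm <- colSums(X * w) / sum(w)
  um <- colMeans(X)
  nb <- length(common)
  boot <- matrix(NA_real_, n_boot, ncol(X))
  boot_d <- matrix(NA_real_, n_boot, ncol(X))
  for (b in seq_len(n_boot)) {
    s <- sample.int(nb, nb, replace = TRUE)
    boot[b, ] <- colSums(X[s, , drop = FALSE] * w[s]) / sum(w[s])
    boot_d[b, ] <- boot[b, ] - colMeans(X[s, , drop = FALSE])
  }
  se <- apply(boot, 2, stats::sd)
  dse <- apply(boot_d, 2, stats::sd)
  z <- (wm - um) / pmax(dse, .Machine$double.eps)
  structure(list(vector = wm, se = se, n_words = nb,
                 diff = wm - um, diff_se = dse,
                 p_diff = 2 * stats::pnorm(-abs(z))),
            class = "concept_mean")
}

#' @export
print.concept_mean <- function(x, ...) {
  cat(sprintf("Concept mean over %d words:\n", x$n_words))
  k <- min(4L, length(x$vector))
  for (j in seq_len(k))
    cat(sprintf("  PC%d: %+.3f (se %.3f), diff from unweighted %+.3f (p = %.2g)\n",
                j, x$vector[j], x$se[j], x$diff[j], x$p_diff[j]))
  invisible(x)
}

#' Coordinate of a word relative to a reference word
#'
#' `pcs[w, k] - pcs[reference, k]`: the valence (or other component) of
#' `w` as seen from `reference`.
#'
#' @param m a `semantic_map`.
#' @param reference,w words in the map.
#' @param k PC index.
#' @return Signed real.
#' @export
relative_projection <- function(m, reference, w, k = 1) {
  m$pcs[word_index(m, w), k] - m$pcs[word_index(m, reference), k]
}
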