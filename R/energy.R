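#' Energy-function parameters
#'
#' The configuration energy of `N` word vectors `x_i` coupled by the
#' signed relation matrix `W` is
#' \deqn{H(x) = -c_p \sum_{i<j} W_{ij} \langle x_i, x_j\rangle
#'       + c_q \sum_i \lVert x_i \rVert^4,}
#' the simplest analytical form that pulls synonym vectors parallel,
#' pushes antonym vectors antiparallel, and keeps the cloud compact
#' through the lowest symmetric power term. The shape of the minimum is
#' invariant under rescaling both coefficients, so the defaults
#' (`pair_coeff = 1`, `quartic_coeff = 1/4`) fix only the overall scale.
#'
#' @param pair_coeff positive weight of the pairwise alignment term.
#' @param quartic_coeff positive weight of the quartic confinement term.
#' @return A list of class `energy_params`.
#' @export
energy_params <- function(pair_coeff = 1, quartic_coeff = 0.25) {
  stopifnot(pair_coeff > 0, quartic_coeff > 0)
  structure(list(pair_coeff = pair_coeff, quartic_coeff = quartic_coeff),
            class = "energy_params")
}

check_config <- function(x, g) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("configuration must be a numeric matrix")
  if (nrow(x) != n_words(g))
    stop("configuration has ", nrow(x), " rows but the graph has ",
         n_words(g), " words")
  invisible(TRUE)
}

#' Random initial configuration in the unit ball
#'
#' Draws each word vector uniformly from the d-dimensional unit ball
#' (direction from a spherical Gaussian, radius as `U^{1/d}`).
#'
#' @param n number of words (rows); must be positive.
#' @param dims embedding dimension.
#' @param seed optional integer seed for reproducibility.
#' @return An `n x dims` numeric matrix with all row norms at most 1.
#' @export
init_config <- function(n, dims = 26, seed = NULL) {
  if (n < 1) stop("empty input: n must be >= 1")
  stopifnot(dims >= 2)
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(n * dims), n, dims)
  z <- z / sqrt(rowSums(z^2))
  z * stats::runif(n)^(1 / dims)
}

#' Configuration energy
#'
#' Reference implementation of the configuration energy; the optimizer
#' uses an equivalent compiled path that is cross-checked against this
#' one in the test suite.
#'
#' @param x `N x d` coordinate matrix.
#' @param g the [signed_graph] the rows of `x` index.
#' @param params an [energy_params] object.
#' @return A finite scalar.
#' @export
map_energy <- function(x, g, params = energy_params()) {
  check_config(x, g)
  pair <- -0.5 * sum(x * as.matrix(g$W %*% x))
  params$pair_coeff * pair + params$quartic_coeff * sum(rowSums(x^2)^2)
}

#' Analytic energy gradient
#'
#' Row `i` is `-c_p * sum_j W_ij x_j + 4 c_q ||x_i||^2 x_i`.
#'
#' @inheritParams map_energy
#' @return An `N x d` matrix.
#' @export
map_energy_gradient <- function(x, g, params = energy_params()) {
  check_config(x, g)
  -params$pair_coeff * as.matrix(g$W %*% x) +
    4 * params$quartic_coeff * rowSums(x^2) * x
}

#' Mean pairwise angle of a configuration
#'
#' Mean over sampled distinct row pairs of the angle (in degrees) between
#' the two vectors. Pairs containing a zero-length vector are skipped
#' with a warning.
#'
#' @param x coordinate matrix with at least two rows.
#' @param sample_pairs number of random distinct pairs to sample.
#' @param seed optional integer seed.
#' @return Mean angle in degrees.
#' @export
mean_pairwise_angle <- function(x, sample_pairs = 10000, seed = NULL) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  i <- sample.int(n, sample_pairs, replace = TRUE)
  j <- sample.int(n - 1L, sample_pairs, replace = TRUE)
  j <- j + (j >= i)  # distinct partner
  ni <- sqrt(rowSums(x[i, , drop = FALSE]^2))
  nj <- sqrt(rowSums(x[j, , drop = FALSE]^2))
  ok <- ni > 0 & nj > 0
  if (!all(ok)) warning(sum(!ok), " pair(s) with a zero vector skipped")
  cs <- rowSums(x[i, , drop = FALSE] * x[j, , drop = FALSE])[ok] /
    (ni[ok] * nj[ok])
  mean(acos(pmin(1, pmax(-1, cs)))) * 180 / pi
}
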