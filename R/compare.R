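#' Align the common words of two maps
#'
#' Restricts two maps to their shared vocabulary and returns paired
#' coordinate matrices. An optional translation table (source token of
#' map B to target token in map A's language) is applied to map B first;
#' when several source words translate to the same target, their
#' coordinate rows are averaged before pairing.
#'
#' @param mA,mB `semantic_map` objects.
#' @param translation optional named character vector or two-column data
#'   frame (`source`, `target`) mapping B's tokens into A's vocabulary.
#' @return A list of class `paired_coordinates` with `words`, `A`
#'   (`n x dA`) and `B` (`n x dB`).
#' @export
align_common_words <- function(mA, mB, translation = NULL) {
  stopifnot(inherits(mA, "semantic_map"), inherits(mB, "semantic_map"))
  wordsB <- mB$words
  pcsB <- mB$pcs
  if (!is.null(translation)) {
    if (is.data.frame(translation))
      translation <- stats::setNames(as.character(translation[[2]]),
                                     as.character(translation[[1]]))
    tgt <- unname(translation[wordsB])
    keep <- !is.na(tgt) & nzchar(tgt)
    wordsB <- tgt[keep]
    pcsB <- pcsB[keep, , drop = FALSE]
    if (anyDuplicated(wordsB)) {
      # many-to-one translation: average the source rows
      pcsB <- rowsum(pcsB, wordsB) / as.vector(table(wordsB)[sort(unique(wordsB))])
      wordsB <- rownames(pcsB)
    }
  }
  common <- intersect(mA$words, wordsB)
  if (length(common) < 2L)
    stop("fewer than 2 words in common between the maps")
  structure(list(words = common,
                 A = mA$pcs[match(common, mA$words), , drop = FALSE],
                 B = pcsB[match(common, wordsB), , drop = FALSE]),
            class = "paired_coordinates")
}

#' Read a translation table
#'
#' Two-column TSV (`source`, `target`) with a header row; many-to-one
#' mappings are allowed.
#'
#' @param path file path.
#' @return Named character vector (source to target).
#' @export
read_translation_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (any(!nzchar(tab[[2]]))) stop("empty translation target in ", path)
  stats::setNames(tab[[2]], tab[[1]])
}

#' PC-to-PC correlation matrix of two aligned maps
#'
#' Entry `(i, j)` is the Pearson correlation between B's PC `i` and A's
#' PC `j` over the paired words, with a two-sided t-test p-value.
#' Constant columns yield `NA` entries.
#'
#' @param p a [align_common_words] result with more than 3 words.
#' @param kA,kB numbers of leading PCs of A and B to correlate.
#' @return List with matrices `R` (`kB x kA`) and `p`.
#' @export
pc_correlation_matrix <- function(p, kA = 4, kB = 4) {
  stopifnot(inherits(p, "paired_coordinates"))
  n <- length(p$words)
  if (n <= 3) stop("need more than 3 paired words")
  kA <- min(kA, ncol(p$A)); kB <- min(kB, ncol(p$B))
  R <- matrix(NA_real_, kB, kA,
              dimnames = list(paste0("B.PC", 1:kB), paste0("A.PC", 1:kA)))
  P <- R
  for (i in seq_len(kB)) for (j in seq_len(kA)) {
    b <- p$B[, i]; a <- p$A[, j]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    r <- stats::cor(a, b)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    R[i, j] <- r
    P[i, j] <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(R = R, p = P)
}

#' Canonical correlation analysis of two aligned maps
#'
#' Canonical correlations between the leading PCs of the two maps, with
#' the number of significant components assessed by Bartlett's
#' sequential chi-squared test. By construction the first coefficient is
#' at least the absolute correlation between the two first PCs.
#'
#' @param p a [align_common_words] result with `n > kA + kB`.
#' @param kA,kB numbers of leading PCs entering the analysis.
#' @param alpha significance level for the sequential test.
#' @return List with `coefficients` (descending), `n_significant`,
#'   `p_last` (p-value of the last significant component, `NA` if none)
#'   and `p_values` (all sequential p-values).
#' @export
map_cca <- function(p, kA = 4, kB = 4, alpha = 0.001) {
  stopifnot(inherits(p, "paired_coordinates"))
  kA <- min(kA, ncol(p$A)); kB <- min(kB, ncol(p$B))
  n <- length(p$words)
  if (n <= kA + kB) stop("need more paired words than kA + kB")
  A <- p$A[, seq_len(kA), drop = FALSE]
  B <- p$B[, seq_len(kB), drop = FALSE]
  qa <- qr(scale(A, scale = FALSE)); qb <- qr(scale(B, scale = FALSE))
  if (qa$rank < kA || qb$rank < kB)
    message("rank-deficient side reduced to effective rank")
  A <- A[, qa$pivot[seq_len(qa$rank)], drop = FALSE]
  B <- B[, qb$pivot[seq_len(qb$rank)], drop = FALSE]
  cc <- stats::cancor(A, B)
  rho <- cc$cor
  k <- length(rho)
  # Bartlett's sequential test: component m significant if the test of
  # "rho_m = ... = rho_k = 0" rejects
  pvals <- vapply(seq_len(k), function(m) {
    stat <- -(n - 1 - (ncol(A) + ncol(B) + 1) / 2) *
      sum(log(pmax(1 - rho[m:k]^2, .Machine$double.eps)))
    df <- (ncol(A) - m + 1) * (ncol(B) - m + 1)
    stats::pchisq(stat, df, lower.tail = FALSE)
  }, numeric(1))
  nsig <- if (any(pvals >= alpha)) which(pvals >= alpha)[1] - 1L else k
  list(coefficients = rho, n_significant = nsig,
       p_last = if (nsig >= 1) pvals[nsig] else NA_real_,
       p_values = pvals)
}

#' Overall correlation of two multidimensional variables
#'
#' A multidimensional generalization of the absolute Pearson coefficient
#' built from norms of covariance matrices:
#' \deqn{OC = \frac{\lVert \mathrm{Cov}(A, B)\rVert}
#'   {\sqrt{\lVert \mathrm{Cov}(A)\rVert \cdot \lVert \mathrm{Cov}(B)\rVert}}.}
#' With the default spectral (operator 2-) norm, OC reduces to |R| in one
#' dimension and always lies between the correlation of the two first
#' principal components and the first canonical correlation. The value
#' is invariant under separate orthogonal rotations of either side, so
#' rotating each cloud to its own principal components (the reporting
#' convention) does not change it.
#'
#' @param p a [align_common_words] result, or an `n x dA` matrix (then
#'   `B` must be given).
#' @param B optional `n x dB` matrix when `p` is a matrix.
#' @param norm matrix norm: `"spectral"` (default), `"frobenius"` or
#'   `"nuclear"`.
#' @return OC in `[0, 1]`.
#' @export
overall_correlation <- function(p, B = NULL,
                                norm = c("spectral", "frobenius",
                                         "nuclear")) {
  norm <- match.arg(norm)
  if (inherits(p, "paired_coordinates")) {
    A <- p$A; B <- p$B
  } else {
    A <- as.matrix(p)
    if (is.null(B)) stop("supply `B` when `p` is a matrix")
    B <- as.matrix(B)
  }
  if (nrow(A) <= 2) stop("need more than 2 paired rows")
  mnorm <- switch(norm,
                  spectral = function(M) svd(M, nu = 0, nv = 0)$d[1],
                  frobenius = function(M) sqrt(sum(M^2)),
                  nuclear = function(M) sum(svd(M, nu = 0, nv = 0)$d))
  va <- mnorm(stats::cov(A)); vb <- mnorm(stats::cov(B))
  if (va == 0 || vb == 0) stop("zero variance on one side")
  mnorm(stats::cov(A, B)) / sqrt(va * vb)
}

#' Full cross-map comparison report
#'
#' Bundles the common-word alignment, PC correlation matrix, CCA and
#' overall correlation of two maps.
#'
#' @inheritParams align_common_words
#' @param kA,kB numbers of leading PCs compared.
#' @return A list of class `map_comparison` with `n`, `pc_matrix`, `cca`,
#'   `oc`.
#' @export
compare_maps <- function(mA, mB, translation = NULL, kA = 4, kB = 4) {
  p <- align_common_words(mA, mB, translation)
  structure(list(n = length(p$words),
                 pc_matrix = pc_correlation_matrix(p, kA, kB),
                 cca = map_cca(p, kA, kB),
                 oc = overall_correlation(p)),
            class = "map_comparison")
}

#' @export
print.map_comparison <- function(x, ...) {
  cat(sprintf("Cross-map comparison over %d common words\n", x$n))
  cat("PC-to-PC correlations:\n")
  print(round(x$pc_matrix$R, 3))
  cat(sprintf("CCA coefficients: %s (%d significant)\n",
              paste(sprintf("%.3f", x$cca$coefficients), collapse = ", "),
              x$cca$n_significant))
  cat(sprintf("Overall correlation: %.3f\n", x$oc))
  invisible(x)
}
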