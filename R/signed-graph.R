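#' Signed onym graphs
#'
#' A signed graph holds an ordered word list and a sparse symmetric
#' relation matrix `W` with entries +1 (synonym pair), -1 (antonym pair)
#' and a zero diagonal. It is the combinatorial object the embedding
#' energy is defined on.
#'
#' @param words character vector of tokens (unique, non-empty).
#' @param edges data frame with columns `from`, `to` (indices or tokens)
#'   and `sign` (+1/-1). May be `NULL` for an edgeless graph.
#' @return An object of class `signed_graph` with elements `words` and
#'   `W` (a `dgCMatrix`).
#' @export
signed_graph <- function(words, edges = NULL) {
  words <- as.character(words)
  if (anyDuplicated(words)) stop("duplicate tokens in `words`")
  if (any(!nzchar(words))) stop("empty token in `words`")
  n <- length(words)
  if (is.null(edges) || nrow(edges) == 0L) {
    W <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, n))
  } else {
    from <- edges$from
    to <- edges$to
    if (is.character(from)) from <- match(from, words)
    if (is.character(to)) to <- match(to, words)
    if (anyNA(from) || anyNA(to)) stop("edge endpoint not in `words`")
    if (any(from == to)) stop("self-loop in edge list")
    s <- as.numeric(edges$sign)
    if (!all(s %in% c(-1, 1))) stop("edge signs must be +1 or -1")
    W <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from),
                              x = c(s, s), dims = c(n, n),
                              use.last.ij = TRUE)
  }
  new_signed_graph(words, W)
}

new_signed_graph <- function(words, W) {
  W <- methods::as(methods::as(W, "generalMatrix"), "CsparseMatrix")
  structure(list(words = words, W = W), class = "signed_graph")
}

#' Build the signed graph of a lexicon
#'
#' Every directed synonym/antonym listing becomes a symmetric +/-1 entry
#' (if A lists B, the B-A link is added too). A pair listed with
#' conflicting signs from any direction is dropped entirely; the number of
#' removed conflicting pairs is reported via a message. Conflict removal
#' is applied after full symmetrization, so the result is independent of
#' listing order.
#'
#' @param lex an [onym_lexicon].
#' @param quiet suppress the conflict-count message.
#' @return A [signed_graph] over all lexicon tokens (head words and listed
#'   onyms).
#' @export
build_signed_graph <- function(lex, quiet = FALSE) {
  stopifnot(inherits(lex, "onym_lexicon"))
  if (length(lex$word) == 0L) stop("empty lexicon")
  words <- unique(c(lex$word, unlist(lex$synonyms), unlist(lex$antonyms)))
  wi <- seq_along(lex$word)
  from <- rep(match(lex$word, words), lengths(lex$synonyms) + lengths(lex$antonyms))
  to <- match(unlist(lapply(wi, function(i)
    c(lex$synonyms[[i]], lex$antonyms[[i]]))), words)
  sgn <- unlist(lapply(wi, function(i)
    c(rep(1, length(lex$synonyms[[i]])), rep(-1, length(lex$antonyms[[i]])))))
  if (length(from) == 0L)
    return(new_signed_graph(words, Matrix::sparseMatrix(
      i = integer(), j = integer(), x = numeric(),
      dims = c(length(words), length(words)))))
  # undirected pair keys
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b)
  syn_keys <- unique(key[sgn > 0])
  ant_keys <- unique(key[sgn < 0])
  conflict <- intersect(syn_keys, ant_keys)
  if (!quiet && length(conflict))
    message(length(conflict), " conflicting onym pair(s) removed")
  keep_keys <- setdiff(union(syn_keys, ant_keys), conflict)
  first <- !duplicated(key)
  sel <- first & (key %in% keep_keys)
  edges <- data.frame(from = a[sel], to = b[sel], sign = sgn[sel])
  signed_graph(words, edges)
}

n_words <- function(g) length(g$words)

#' @export
print.signed_graph <- function(x, ...) {
  st <- graph_stats(x)
  cat(sprintf(
    "Signed graph: %d words, %d synonym edges, %d antonym edges\n",
    st$n_words,
    round(st$mean_synonyms_per_word * st$n_words / 2),
    round(st$mean_antonyms_per_word * st$n_words / 2)))
  invisible(x)
}

#' Extract edges of a signed graph
#'
#' @param g a [signed_graph].
#' @return Data frame with columns `from`, `to` (word indices,
#'   `from < to`) and `sign`.
#' @export
graph_edges <- function(g) {
  U <- Matrix::triu(g$W, 1)
  sm <- Matrix::summary(methods::as(U, "TsparseMatrix"))
  sm <- sm[sm$x != 0, , drop = FALSE]
  data.frame(from = sm$i, to = sm$j, sign = sm$x)[order(sm$i, sm$j), ,
                                                  drop = FALSE]
}

subset_graph <- function(g, idx) {
  new_signed_graph(g$words[idx], g$W[idx, idx, drop = FALSE])
}

components_of <- function(g) {
  ig <- igraph::graph_from_adjacency_matrix(abs(g$W) > 0,
                                            mode = "undirected")
  igraph::components(ig)
}

#' Largest connected component
#'
#' Returns the subgraph induced by the largest connected component of the
#' unsigned support of `W`. Size ties are broken in favor of the component
#' containing the lexicographically smallest word, for determinism.
#'
#' @param g a [signed_graph] with at least one word.
#' @return A [signed_graph].
#' @export
largest_component <- function(g) {
  stopifnot(inherits(g, "signed_graph"), n_words(g) >= 1L)
  comp <- components_of(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    # tie-break: component holding the lexicographically smallest word
    reps <- vapply(best, function(b) min(g$words[comp$membership == b]),
                   character(1))
    best <- best[order(reps)][1]
  }
  subset_graph(g, comp$membership == best)
}

#' Extract the core of a signed graph
#'
#' The core is the fixed point of repeatedly (i) dropping words with fewer
#' than two incident edges or with no antonym edge and (ii) re-taking the
#' largest connected component. Cascaded degree loss is handled by the
#' iteration; the result can be empty (returned as an empty graph).
#'
#' @param g a non-empty [signed_graph].
#' @param quiet suppress the message emitted when the core is empty.
#' @return A [signed_graph], possibly with zero words.
#' @export
extract_core <- function(g, quiet = FALSE) {
  stopifnot(inherits(g, "signed_graph"), n_words(g) >= 1L)
  repeat {
    if (n_words(g) == 0L) break
    deg <- Matrix::colSums(g$W != 0)
    nant <- Matrix::colSums(g$W < 0)
    bad <- deg < 2 | nant < 1
    if (any(bad)) {
      g <- subset_graph(g, !bad)
      next
    }
    comp <- components_of(g)
    if (comp$no <= 1L) break
    g <- largest_component(g)
  }
  if (n_words(g) == 0L && !quiet)
    message("core extraction removed every word")
  g
}

#' Basic statistics of a signed graph
#'
#' Mean synonym/antonym counts per word are computed as twice the edge
#' count of that sign divided by the number of words, and component sizes
#' are reported in descending order.
#'
#' @param g a [signed_graph].
#' @return A list of class `core_stats` with `n_words`,
#'   `mean_synonyms_per_word`, `mean_antonyms_per_word`, `component_sizes`.
#' @export
graph_stats <- function(g) {
  stopifnot(inherits(g, "signed_graph"))
  n <- n_words(g)
  if (n == 0L)
    return(structure(list(n_words = 0L, mean_synonyms_per_word = 0,
                          mean_antonyms_per_word = 0,
                          component_sizes = integer()),
                     class = "core_stats"))
  e <- graph_edges(g)
  comp <- components_of(g)
  structure(list(
    n_words = n,
    mean_synonyms_per_word = 2 * sum(e$sign > 0) / n,
    mean_antonyms_per_word = 2 * sum(e$sign < 0) / n,
    component_sizes = sort(as.integer(comp$csize), decreasing = TRUE)),
    class = "core_stats")
}

#' @export
print.core_stats <- function(x, ...) {
  cat(sprintf(
    paste0("%d words; %.2f synonyms and %.2f antonyms per word; ",
           "%d component(s), largest %d\n"),
    x$n_words, x$mean_synonyms_per_word, x$mean_antonyms_per_word,
    length(x$component_sizes),
    if (length(x$component_sizes)) x$component_sizes[1] else 0L))
  invisible(x)
}

# permute the +/-1 labels over the existing edge set (topology preserved);
# used as the null model for dimension significance
shuffle_signs <- function(g, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  e <- graph_edges(g)
  e$sign <- sample(e$sign)
  signed_graph(g$words, e)
}

#' Capture-recapture estimate of true onym-set size
#'
#' Treats two dictionaries as independent random samples of links from a
#' comprehensive set, so that `estimate = n1 * n2 / overlap` with per
#' dictionary coverage `n_i / estimate`. This is a coarse overestimate of
#' coverage whenever common links are more likely to be listed in both
#' sources.
#'
#' @param n1,n2 link counts in the two dictionaries.
#' @param overlap number of links listed in both; must be at least 1 and
#'   no larger than `min(n1, n2)`.
#' @return List with `estimate`, `coverage1`, `coverage2`.
#' @examples
#' capture_recapture(30922, 12188, 6576)
#' @export
capture_recapture <- function(n1, n2, overlap) {
  stopifnot(n1 >= 0, n2 >= 0)
  if (overlap < 1) stop("estimate undefined for overlap < 1")
  if (overlap > min(n1, n2)) stop("overlap exceeds min(n1, n2)")
  est <- n1 * n2 / overlap
  list(estimate = est, coverage1 = n1 / est, coverage2 = n2 / est)
}

#' Write / read a signed-graph edge list
#'
#' Plain TSV with columns `word_a`, `word_b`, `sign`, written sorted for
#' bit-stable diffs. Reading restores the graph (word order is first
#' appearance order in the sorted edge list unless `words` is given).
#'
#' @param g a [signed_graph].
#' @param path file path.
#' @param words optional token vector fixing word order on read.
#' @return `write_edgelist` returns `path` invisibly; `read_edgelist`
#'   returns a [signed_graph].
#' @export
write_edgelist <- function(g, path) {
  e <- graph_edges(g)
  out <- data.frame(word_a = g$words[e$from], word_b = g$words[e$to],
                    sign = as.integer(e$sign))
  out <- out[order(out$word_a, out$word_b), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path, words = NULL) {
  tab <- utils::read.delim(path, header = TRUE, colClasses =
                             c("character", "character", "integer"))
  if (is.null(words))
    words <- unique(c(rbind(tab$word_a, tab$word_b)))
  signed_graph(words, data.frame(from = tab$word_a, to = tab$word_b,
                                 sign = tab$sign))
}
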