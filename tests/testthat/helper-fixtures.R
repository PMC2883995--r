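# Fixture builders shared across test files. Everything is generated in
# code; no binary data.

# random lexicon with possibly overlapping/conflicting listings
random_lexicon <- function(n = 10, seed = 1, p_syn = 0.2, p_ant = 0.1) {
  set.seed(seed)
  words <- sprintf("w%02d", seq_len(n))
  syn <- lapply(seq_len(n), function(i)
    sample(words[-i], rbinom(1, n - 1, p_syn)))
  ant <- lapply(seq_len(n), function(i)
    sample(words[-i], rbinom(1, n - 1, p_ant)))
  onym_lexicon(words, syn, ant)
}

# independent brute-force oracle for build_signed_graph: enumerate every
# unordered pair, collect signs from all four directed listings, drop
# conflicts
brute_signed_edges <- function(lex) {
  words <- unique(c(lex$word, unlist(lex$synonyms), unlist(lex$antonyms)))
  out <- NULL
  for (ai in seq_along(words)) for (bi in seq_along(words)) {
    if (ai >= bi) next
    a <- words[ai]; b <- words[bi]
    signs <- c()
    for (w in list(c(a, b), c(b, a))) {
      i <- match(w[1], lex$word)
      if (is.na(i)) next
      if (w[2] %in% lex$synonyms[[i]]) signs <- c(signs, 1)
      if (w[2] %in% lex$antonyms[[i]]) signs <- c(signs, -1)
    }
    su <- unique(signs)
    if (length(su) == 1)
      out <- rbind(out, data.frame(a = a, b = b, sign = su))
  }
  out
}

# two synonym cliques of size k joined all-to-all by antonym edges: the
# archetypal graph with an exact antipodal minimum
two_clique_graph <- function(k = 4) {
  words <- c(sprintf("p%d", 1:k), sprintf("n%d", 1:k))
  edges <- NULL
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    edges <- rbind(edges,
                   data.frame(from = i, to = j, sign = 1),
                   data.frame(from = k + i, to = k + j, sign = 1))
  }
  for (i in 1:k) for (j in 1:k)
    edges <- rbind(edges, data.frame(from = i, to = k + j, sign = -1))
  signed_graph(words, edges)
}

# random signed graph (guaranteed simple): sample pairs, assign signs
random_signed_graph <- function(n = 12, n_edges = 20, seed = 1,
                                p_ant = 0.4) {
  set.seed(seed)
  pairs <- t(utils::combn(n, 2))
  sel <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  signed_graph(sprintf("v%02d", seq_len(n)),
               data.frame(from = pairs[sel, 1], to = pairs[sel, 2],
                          sign = ifelse(stats::runif(length(sel)) < p_ant,
                                        -1, 1)))
}

# wrap a raw coordinate matrix as a semantic map without refitting
as_map <- function(pcs, words = NULL) {
  if (is.null(words)) words <- sprintf("t%02d", seq_len(nrow(pcs)))
  semap:::new_semantic_map(words, pcs)
}

# small fitted map from a graph (annealed descent, fixed seed)
fit_small <- function(g, dims = 3, seed = 1, tol = 2e-6) {
  x0 <- init_config(semap:::n_words(g), dims, seed = seed)
  minimize_energy(x0, g, control = optimizer_control(
    tolerance = tol, seed = seed + 1L,
    noise_scale0 = 0.05, noise_decay = 0.98))
}

angle_between <- function(u, v) {
  acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}
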