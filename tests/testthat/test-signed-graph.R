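test_that("one-way listings become symmetric edges and conflicts drop", {
  lex <- onym_lexicon(c("A", "B", "C"),
                      synonyms = list("B", character(), character()),
                      antonyms = list(character(), character(), "A"))
  g <- build_signed_graph(lex, quiet = TRUE)
  iA <- match("A", g$words); iB <- match("B", g$words)
  iC <- match("C", g$words)
  expect_equal(g$W[iA, iB], 1)
  expect_equal(g$W[iB, iA], 1)
  expect_equal(g$W[iA, iC], -1)

  # A lists B as both synonym and antonym -> no edge
  lex2 <- onym_lexicon("A", synonyms = list("B"), antonyms = list("B"))
  expect_message(g2 <- build_signed_graph(lex2), "conflicting")
  expect_equal(sum(g2$W != 0), 0)
})

test_that("signed graph matches brute-force pair enumeration", {
  # 4-word lexicon with a conflicting listing
  lex <- onym_lexicon(c("a", "b", "c", "d"),
                      synonyms = list(c("b"), c("c"), character(), "c"),
                      antonyms = list(c("c"), "a", "b", character()))
  g <- build_signed_graph(lex, quiet = TRUE)
  exp <- brute_signed_edges(lex)
  e <- graph_edges(g)
  got <- data.frame(a = g$words[e$from], b = g$words[e$to], sign = e$sign)
  o1 <- got[order(got$a, got$b), ]; o2 <- exp[order(exp$a, exp$b), ]
  expect_equal(unname(as.matrix(o1)), unname(as.matrix(o2)))
})

test_that("random lexicons always yield symmetric conflict-free graphs", {
  for (s in 1:12) {
    g <- build_signed_graph(random_lexicon(8, seed = s), quiet = TRUE)
    W <- as.matrix(g$W)
    expect_identical(W, t(W))
    expect_true(all(diag(W) == 0))
    expect_true(all(W %in% c(-1, 0, 1)))
    exp <- brute_signed_edges(random_lexicon(8, seed = s))
    expect_equal(sum(W != 0) / 2, if (is.null(exp)) 0L else nrow(exp))
  }
})

test_that("largest_component keeps the biggest cluster, ties by word", {
  g <- signed_graph(c("a", "b", "c", "d", "e"),
                    data.frame(from = c(1, 2, 4), to = c(2, 3, 5),
                               sign = c(1, -1, 1)))
  lc <- largest_component(g)
  expect_setequal(lc$words, c("a", "b", "c"))

  # connected graph is untouched
  g2 <- two_clique_graph(3)
  expect_identical(largest_component(g2)$words, g2$words)

  # equal-size components: pick the one holding "ant"
  g3 <- signed_graph(c("cat", "dog", "ant", "bee"),
                     data.frame(from = c(1, 3), to = c(2, 4),
                                sign = c(1, -1)))
  expect_setequal(largest_component(g3)$words, c("ant", "bee"))
})

test_that("extract_core prunes to the stated fixed point", {
  # a word with two synonyms but no antonym is removed
  g <- signed_graph(c("a", "b", "c"),
                    data.frame(from = c(1, 1), to = c(2, 3),
                               sign = c(1, 1)))
  expect_message(core <- extract_core(g), "removed every word")
  expect_equal(semap:::n_words(core), 0)

  # alternating 4-cycle: every node has degree 2 and one antonym ->
  # retained unchanged
  cyc <- signed_graph(c("a", "b", "c", "d"),
                      data.frame(from = c(1, 2, 3, 4), to = c(2, 3, 4, 1),
                                 sign = c(1, -1, 1, -1)))
  expect_identical(extract_core(cyc)$words, cyc$words)
  expect_equal(as.matrix(extract_core(cyc)$W), as.matrix(cyc$W))
})

test_that("cascaded pruning matches an iterative brute-force oracle", {
  oracle_core <- function(g) {
    keep <- rep(TRUE, length(g$words))
    W <- as.matrix(g$W)
    repeat {
      Wk <- W[keep, keep, drop = FALSE]
      if (!any(keep)) break
      deg <- colSums(Wk != 0); ant <- colSums(Wk < 0)
      bad <- deg < 2 | ant < 1
      # largest component by BFS on the kept submatrix
      nk <- sum(keep)
      comp <- rep(NA_integer_, nk); cid <- 0
      for (s0 in seq_len(nk)) {
        if (!is.na(comp[s0])) next
        cid <- cid + 1; q <- s0; comp[s0] <- cid
        while (length(q)) {
          v <- q[1]; q <- q[-1]
          nb <- which(Wk[v, ] != 0 & is.na(comp))
          comp[nb] <- cid; q <- c(q, nb)
        }
      }
      sizes <- table(comp)
      main <- as.integer(names(sizes)[order(-sizes,
        vapply(names(sizes), function(cc)
          min(g$words[keep][comp == as.integer(cc)]), character(1)))])[1]
      drop <- bad | comp != main
      if (!any(drop)) break
      keep[which(keep)[drop]] <- FALSE
    }
    sort(g$words[keep])
  }
  # chain where removing an endpoint cascades
  chain <- signed_graph(
    c("a", "b", "c", "d", "e"),
    data.frame(from = c(1, 2, 3, 4, 1, 2), to = c(2, 3, 4, 5, 3, 4),
               sign = c(1, -1, 1, 1, -1, -1)))
  expect_identical(sort(extract_core(chain)$words), oracle_core(chain))

  for (s in 1:10) {
    g <- random_signed_graph(10, 14, seed = s)
    expect_identical(sort(extract_core(g, quiet = TRUE)$words),
                     oracle_core(g))
  }
})

test_that("extract_core output satisfies the core property and is idempotent", {
  for (s in 1:8) {
    g <- random_signed_graph(14, 26, seed = 100 + s)
    core <- extract_core(g, quiet = TRUE)
    if (semap:::n_words(core) == 0) next
    W <- as.matrix(core$W)
    expect_true(all(colSums(W != 0) >= 2))
    expect_true(all(colSums(W < 0) >= 1))
    comp <- semap:::components_of(core)
    expect_equal(comp$no, 1)
    core2 <- extract_core(core, quiet = TRUE)
    expect_identical(core2$words, core$words)
    expect_equal(as.matrix(core2$W), W)
  }
})

test_that("graph_stats means agree with edge enumeration", {
  g <- signed_graph(c("a", "b"), data.frame(from = 1, to = 2, sign = 1))
  expect_equal(graph_stats(g)$mean_synonyms_per_word, 1)

  empty <- signed_graph(character(0))
  st0 <- graph_stats(empty)
  expect_equal(st0$n_words, 0)
  expect_equal(st0$mean_synonyms_per_word, 0)

  for (s in 1:5) {
    g <- random_signed_graph(20, 40, seed = 200 + s)
    st <- graph_stats(g)
    e <- graph_edges(g)
    expect_equal(st$mean_synonyms_per_word, 2 * sum(e$sign > 0) / 20)
    expect_equal(st$mean_antonyms_per_word, 2 * sum(e$sign < 0) / 20)
    expect_equal(sum(st$component_sizes), 20)
  }
})

test_that("capture-recapture reproduces the dictionary-overlap estimate", {
  cr <- capture_recapture(30922, 12188, 6576)
  expect_equal(round(cr$estimate), 57311)
  expect_equal(round(100 * cr$coverage1), 54)
  expect_equal(round(100 * cr$coverage2), 21)

  id <- capture_recapture(7, 7, 7)
  expect_equal(id$estimate, 7)
  expect_equal(id$coverage1, 1)
  expect_equal(id$coverage2, 1)

  expect_error(capture_recapture(10, 10, 0), "overlap")
  expect_error(capture_recapture(10, 10, 11), "overlap")
})

test_that("edge lists round-trip through sorted TSV", {
  g <- random_signed_graph(9, 14, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edgelist(g, f)
  g2 <- read_edgelist(f, words = g$words)
  expect_equal(as.matrix(g2$W), as.matrix(g$W))
  # byte-stable: writing again is identical
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_edgelist(g2, f2)
  expect_identical(readLines(f), readLines(f2))
})
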