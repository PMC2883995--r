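test_that("angles and dot-product classification follow the geometry", {
  m <- as_map(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0.6, 0.6)),
              c("e1", "neg", "orth", "diag"))
  expect_equal(word_angle(m, "e1", "neg"), 180)
  expect_equal(word_angle(m, "e1", "orth"), 90)
  # direct arccos oracle on an arbitrary pair
  expect_equal(word_angle(m, "e1", "diag"),
               acos(sum(c(1, 0) * c(0.6, 0.6)) /
                      (1 * sqrt(0.72))) * 180 / pi)
  expect_identical(classify_onym(m, "e1", "diag"), "synonym")
  expect_identical(classify_onym(m, "e1", "neg"), "antonym")
  expect_identical(classify_onym(m, "e1", "orth"), "abstain")
  expect_error(word_angle(m, "e1", "missing"), "not in map")
  mz <- as_map(rbind(c(0, 0), c(1, 0)), c("zero", "one"))
  expect_error(word_angle(mz, "zero", "one"), "zero-length")
})

test_that("word ranking scores equal projection-alignment geometric means", {
  # coordinate 0.8 with unit vector length scores 0.8
  m <- as_map(rbind(c(0.8, 0.6), c(0.3, -0.1)), c("a", "b"))
  expect_equal(rank_words(m, 1, 2)$top$score[1], 0.8)

  set.seed(8)
  pcs <- matrix(rnorm(12), 6, 2)
  m6 <- as_map(pcs)
  rw <- rank_words(m6, 1, 6)
  # score^2 == projection * |alignment| for every word
  len <- sqrt(rowSums(pcs^2))
  for (i in 1:6) {
    sc <- pcs[i, 1] / sqrt(len[i])
    expect_equal(sc^2, abs(pcs[i, 1] * (pcs[i, 1] / len[i])))
  }
  # ordering matches an exhaustive sort
  sc_all <- pcs[, 1] / sqrt(len)
  expect_identical(rw$top$word, m6$words[order(sc_all, decreasing = TRUE)])
  expect_identical(rw$bottom$word, m6$words[order(sc_all)])
})

test_that("antonym-pair ranking uses the distance-normalized difference", {
  g <- signed_graph(c("p", "n", "x", "y"),
                    data.frame(from = c(1, 3), to = c(2, 4),
                               sign = c(-1, -1)))
  m <- as_map(rbind(c(1, 0), c(-1, 0), c(0.4, 0.3), c(0.4, -0.2)),
              g$words)
  rp <- rank_antonym_pairs(m, g, k = 1, n = 2)
  expect_equal(rp$score[1], 2 / sqrt(2))
  expect_identical(rp$word_pos[1], "p")
  # identical coordinates on the ranked axis score zero
  expect_equal(rp$score[2], 0)

  # brute-force sort oracle on a random toy
  set.seed(9)
  g2 <- two_clique_graph(3)
  pcs <- matrix(rnorm(12), 6, 2)
  m2 <- as_map(pcs, g2$words)
  e <- graph_edges(g2); e <- e[e$sign < 0, ]
  sc <- apply(e, 1, function(r) {
    d <- sqrt(sum((pcs[r[1], ] - pcs[r[2], ])^2))
    abs(pcs[r[1], 1] - pcs[r[2], 1]) / sqrt(d)
  })
  rp2 <- rank_antonym_pairs(m2, g2, k = 1, n = 3)
  expect_equal(rp2$score, unname(sort(sc, decreasing = TRUE))[1:3])
})

test_that("two-step neighborhoods match brute-force closure", {
  path <- signed_graph(c("A", "B", "C"),
                       data.frame(from = c(1, 2), to = c(2, 3),
                                  sign = c(1, -1)))
  expect_identical(onyms_of_onyms(path, "A"), "C")

  star <- signed_graph(c("hub", "s1", "s2", "s3"),
                       data.frame(from = c(1, 1, 1), to = c(2, 3, 4),
                                  sign = c(1, -1, 1)))
  # the hub's only two-step neighbor is itself, which is excluded, so
  # the set is empty whether or not listed onyms are retained
  expect_length(onyms_of_onyms(star, "hub"), 0)
  expect_length(onyms_of_onyms(star, "hub", include_listed = TRUE), 0)
  # a leaf reaches its siblings in two steps through the hub
  expect_setequal(onyms_of_onyms(star, "s1"), c("s2", "s3"))

  g <- random_signed_graph(6, 8, seed = 55)
  A <- as.matrix(abs(g$W) > 0)
  for (w in g$words) {
    i <- match(w, g$words)
    two <- which((A %*% A)[i, ] > 0)
    two <- setdiff(two, c(i, which(A[i, ])))
    expect_setequal(onyms_of_onyms(g, w), g$words[two])
  }
  expect_error(onyms_of_onyms(g, "nope"), "not in graph")
})

test_that("onym-of-onym correlations separate perfect and null labelings", {
  # perfect separation: cosines +1 for synonyms, -1 for antonyms
  g <- signed_graph(c("w", "s1", "s2", "a1", "a2"),
                    data.frame(from = c(1, 1, 1, 1, 2, 4),
                               to = c(2, 3, 4, 5, 3, 5),
                               sign = c(1, 1, -1, -1, 1, 1)))
  m <- as_map(rbind(c(1, 0), c(1, 0.01), c(0.9, 0.02),
                    c(-1, 0.01), c(-0.95, 0)), g$words)
  r <- oo_prediction_correlation(m, g, "w")
  expect_equal(r$R, 1, tolerance = 0.01)
  expect_lt(r$p, 0.01)

  # hand-computed Pearson oracle
  pool <- onyms_of_onyms(g, "w", include_listed = TRUE)
  lab <- as.numeric(g$W[1, match(pool, g$words)])
  keep <- lab != 0
  cs <- vapply(pool[keep], function(u) {
    v1 <- m$pcs[1, ]; v2 <- m$pcs[match(u, g$words), ]
    sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  }, numeric(1))
  expect_equal(r$R, stats::cor(cs, lab[keep]))
  expect_equal(r$N, sum(keep))

  # labels independent of geometry: R hovers near zero
  set.seed(66)
  rs <- replicate(20, {
    k <- 12
    g2 <- signed_graph(
      c("w", sprintf("o%d", 1:k)),
      data.frame(from = rep(1, k), to = 2:(k + 1),
                 sign = sample(c(-1, 1), k, replace = TRUE)))
    # make everyone an onym-of-onym through a shared neighbor
    g2 <- signed_graph(g2$words, rbind(graph_edges(g2),
      data.frame(from = 2, to = 3:(k + 1), sign = 1)))
    m2 <- as_map(matrix(rnorm((k + 1) * 3), k + 1, 3), g2$words)
    oo_prediction_correlation(m2, g2, "w")$R
  })
  expect_lt(abs(mean(rs)), 0.25)
  expect_error(oo_prediction_correlation(m, g, "s2"), "insufficient")
})

test_that("connotation octants follow the 45-degree sector rule", {
  ring <- t(sapply(seq(0, 337.5, by = 22.5), function(a)
    c(cos(a * pi / 180), sin(a * pi / 180))))
  m <- as_map(ring, sprintf("r%02d", 1:16))
  sectors <- c("good", "good/exciting", "exciting", "bad/exciting",
               "bad", "bad/calming", "calming", "good/calming")
  # independent sector arithmetic: nearest sector center, ties CCW
  expected <- sapply(seq(0, 337.5, by = 22.5), function(a)
    sectors[(floor((a + 22.5) / 45) %% 8) + 1])
  got <- sapply(m$words, function(w) connotation_octant(m, w))
  expect_identical(unname(got), unname(expected))
  expect_identical(connotation_octant(m, "r01"), "good")
  m2 <- as_map(rbind(c(-1, -1) / sqrt(2), c(0, 0)), c("bc", "origin"))
  expect_identical(connotation_octant(m2, "bc"), "bad/calming")
  expect_identical(connotation_octant(m2, "origin"), "neutral")
})

test_that("vector length statistics match moment oracles", {
  m <- as_map(rbind(c(1, 0), c(0, 1), c(-1, 0)))
  vl <- vector_length_stats(m)
  expect_equal(vl$median, 1)
  expect_equal(vl$mean, 1)
  expect_equal(vl$sd, 0)

  m2 <- as_map(rbind(c(1, 0), c(3, 0)))
  expect_equal(vector_length_stats(m2)$mean, 2)

  set.seed(12)
  pcs <- matrix(rnorm(60), 20, 3)
  len <- sqrt(rowSums(pcs^2))
  vl3 <- vector_length_stats(as_map(pcs))
  expect_equal(vl3$mean, mean(len))
  expect_equal(vl3$sd, sd(len))
  expect_equal(vl3$percentiles$length[vl3$percentiles$prob == 0.5],
               median(len))
})

test_that("frequency weighting reduces to the expected means", {
  pcs <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1), c(2, 2))
  m <- as_map(pcs, c("a", "b", "c", "d", "e"))
  u <- frequency_weighted_mean(m, c(a = 1, b = 1, c = 1, d = 1, e = 1),
                               n_boot = 50, seed = 1)
  expect_equal(u$vector, colMeans(pcs))

  one <- frequency_weighted_mean(m, c(e = 10), n_boot = 50, seed = 1)
  expect_equal(one$vector, pcs[5, ])
  expect_equal(one$se, c(0, 0))

  w <- c(a = 2, b = 1, c = 3, d = 0, e = 4)
  fw <- frequency_weighted_mean(m, w, n_boot = 50, seed = 1)
  expect_equal(fw$vector, colSums(pcs[1:5, ] * w) / sum(w))
  expect_error(frequency_weighted_mean(m, c(zz = 3)), "no words shared")
})

test_that("relative projections are plain coordinate differences", {
  m <- as_map(rbind(c(1.36, 0), c(1.70, 0), c(2.13, 0)),
              c("okay", "fine", "good"))
  expect_equal(relative_projection(m, "fine", "okay", 1), -0.34)
  expect_equal(relative_projection(m, "fine", "good", 1), 0.43)
  expect_equal(relative_projection(m, "fine", "fine", 1), 0)
})
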