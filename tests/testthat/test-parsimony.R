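test_that("ordered tree length matches hand examples", {
  tr <- newick("((a,b),(c,d));")
  cm <- char_matrix(matrix(c(0L, 3L, 3L, 3L), 4, 1,
                           dimnames = list(c("a", "b", "c", "d"), "x")),
                    "zero_ancestral", 4L)
  expect_equal(tree_length(tr, cm), 3)                      # ordered
  expect_equal(tree_length(tr, cm, ordered = FALSE), 1)     # unordered contrast

  # constant character costs nothing
  cm0 <- char_matrix(matrix(2L, 4, 1, dimnames = list(letters[1:4], "x")),
                     "zero_ancestral", 5L)
  expect_equal(tree_length(tr, cm0), 0)

  # two leaves: plain path distance
  tr2 <- newick("(a,b);")
  cm2 <- char_matrix(matrix(c(5L, 9L), 2, 1, dimnames = list(c("a", "b"), "x")),
                     "zero_ancestral", 24L)
  expect_equal(tree_length(tr2, cm2), 4)
})

test_that("engine length equals brute-force enumeration on all small trees", {
  S <- 4L
  for (n in 4:5) {
    topos <- phangorn::allTrees(n, rooted = FALSE, tip.label = letters[1:n])
    topos <- lapply(seq_along(topos), function(i) topos[[i]])  # expand labels
    withr::with_seed(n, {
      sts <- replicate(2, setNames(sample(0:(S - 1L), n, TRUE), letters[1:n]),
                       simplify = FALSE)
    })
    for (tr in topos) {
      for (st in sts) {
        cm <- char_matrix(matrix(st, ncol = 1,
                                 dimnames = list(names(st), "x")),
                          "zero_ancestral", S)
        expect_equal(tree_length(tr, cm),
                     brute_force_char_length(tr, st, S))
      }
    }
  }
})

test_that("engine length agrees with an independent Sankoff implementation", {
  S <- 5L
  cost <- outer(0:(S - 1), 0:(S - 1), function(i, j) abs(i - j))
  for (seed in 1:5) {
    cm <- random_cm(7, 10, S, seed)
    tr <- withr::with_seed(seed, ape::rtree(7, tip.label = rownames(cm$state),
                                            br = NULL))
    dat <- phangorn::phyDat(cm$state, type = "USER", levels = 0:(S - 1))
    expect_equal(tree_length(tr, cm),
                 phangorn::parsimony(tr, dat, method = "sankoff", cost = cost))
  }
})

test_that("mp_search finds the global optimum on exhaustively checkable data", {
  # one perfectly compatible binary character on 4 taxa
  cm <- char_matrix(matrix(c(0L, 0L, 1L, 1L), 4, 1,
                           dimnames = list(letters[1:4], "x")),
                    "zero_ancestral", 2L)
  res <- mp_search(cm, search_config(seed = 1))
  expect_equal(attr(res, "length"), 1)
  key <- urproteome:::.topo_key(res[[1]])
  expect_equal(key, urproteome:::.topo_key(newick("((a,b),(c,d));")))

  # 6-taxon random matrices vs enumeration of all 105 topologies
  topos <- phangorn::allTrees(6, rooted = FALSE, tip.label = letters[1:6])
  topos <- lapply(seq_along(topos), function(i) topos[[i]])  # expand labels
  for (seed in 1:4) {
    cm6 <- random_cm(6, 8, 6, seed, taxa = letters[1:6])
    opt <- min(vapply(topos, function(t) tree_length(t, cm6), 0))
    res6 <- mp_search(cm6, search_config(n_addition_replicates = 3, seed = seed))
    expect_equal(attr(res6, "length"), opt)
  }
})

test_that("searches are reproducible under a fixed seed", {
  cm <- random_cm(8, 12, 8, 2)
  a <- mp_search(cm, search_config(seed = 42))
  b <- mp_search(cm, search_config(seed = 42))
  expect_identical(lapply(a, ape::write.tree), lapply(b, ape::write.tree))
  expect_identical(attr(a, "length"), attr(b, "length"))
})

test_that("Lundberg rooting: examples and attachment-edge oracle", {
  # 3-leaf star, states 0/1/2, zero ancestor: edge attachment reaches 2
  tr3 <- newick("(a,b,c);")
  cm3 <- char_matrix(matrix(0:2, 3, 1, dimnames = list(c("a", "b", "c"), "x")),
                     "zero_ancestral", 3L)
  rt3 <- lundberg_root(tr3, cm3)
  expect_equal(rt3$unrooted_length, 2)
  oracle3 <- min(vapply(seq_len(nrow(tr3$edge)), function(i) {
    att <- urproteome:::.add_tip(tr3, i, "ANC")
    st <- c(setNames(0:2, c("a", "b", "c")), ANC = 0L)
    brute_force_char_length(att, st, 3L)
  }, 0))
  expect_equal(rt3$length, oracle3)

  # all-zero matrix roots for free
  cm0 <- char_matrix(matrix(0L, 4, 2, dimnames = list(letters[1:4],
                                                      c("x", "y"))),
                     "zero_ancestral", 24L)
  rt0 <- lundberg_root(newick("((a,b),(c,d));"), cm0)
  expect_equal(rt0$length, 0)
  expect_equal(rt0$unrooted_length, 0)

  # 5-taxon tree: chosen attachment equals argmin over all edges by re-scoring
  cm5 <- random_cm(5, 6, 6, 9, taxa = letters[1:5])
  tr5 <- newick("((a,b),(c,d),e);")
  rt5 <- lundberg_root(tr5, cm5)
  per_edge <- vapply(seq_len(nrow(tr5$edge)), function(i) {
    att <- urproteome:::.add_tip(tr5, i, "ANC")
    cma <- char_matrix(rbind(cm5$state, ANC = 0L), "zero_ancestral", 6L)
    tree_length(att, cma)
  }, 0)
  expect_equal(rt5$length, min(per_edge))
  expect_true(rt5$length >= rt5$unrooted_length)
})

test_that("consistency and retention indices follow their definitions", {
  tr <- newick("((a,b),(c,d));")
  # single character {0,0,3,3} grouping the 0s: m = 3, length = 3, g = 6
  cm <- char_matrix(matrix(c(0L, 0L, 3L, 3L), 4, 1,
                           dimnames = list(letters[1:4], "x")),
                    "zero_ancestral", 4L)
  res <- ci_ri(tr, cm)
  expect_equal(res$length, 3)
  expect_equal(res$ci, 1)
  expect_equal(res$ri, 1)

  # character fitting as badly as a bush: RI = 0
  cmw <- char_matrix(matrix(c(0L, 3L, 0L, 3L), 4, 1,
                            dimnames = list(letters[1:4], "x")),
                     "zero_ancestral", 4L)
  resw <- ci_ri(tr, cmw)
  expect_equal(resw$ri, 0)

  # perfectly compatible multi-character matrix: CI = 1
  cmp <- char_matrix(cbind(x = c(0L, 0L, 2L, 2L), y = c(0L, 0L, 0L, 3L)) |>
                       `rownames<-`(letters[1:4]),
                     "zero_ancestral", 4L)
  expect_equal(ci_ri(tr, cmp)$ci, 1)
})

test_that("g1 skewness: degenerate, reproducible, and signal-sensitive", {
  cmc <- char_matrix(matrix(3L, 5, 4, dimnames = list(sprintf("t%d", 1:5),
                                                      sprintf("c%d", 1:4))),
                     "zero_ancestral", 24L)
  expect_equal(g1_skewness(cmc, n_random = 50, seed = 1), 0)

  cm <- random_cm(7, 10, 8, 4)
  expect_identical(g1_skewness(cm, n_random = 200, seed = 3),
                   g1_skewness(cm, n_random = 200, seed = 3))

  # strongly structured data (clean two-clade signal) skew left
  st <- rbind(matrix(0L, 4, 10), matrix(7L, 4, 10))
  dimnames(st) <- list(sprintf("t%d", 1:8), sprintf("c%d", 1:10))
  cms <- char_matrix(st, "zero_ancestral", 8L)
  expect_lt(g1_skewness(cms, n_random = 300, seed = 5), 0)
})

test_that("bootstrap gives full support to a perfectly compatible clade", {
  st <- cbind(matrix(c(0L, 0L, 0L, 5L, 5L, 5L), 6, 8))
  dimnames(st) <- list(letters[1:6], sprintf("c%d", 1:8))
  cm <- char_matrix(st, "zero_ancestral", 6L)
  bs <- bootstrap_support(cm, reps = 20, cfg = search_config(seed = 2))
  expect_true(all(bs$support >= 0 & bs$support <= 100))
  expect_true(any(bs$support == 100))
  bs2 <- bootstrap_support(cm, reps = 20, cfg = search_config(seed = 2))
  expect_identical(bs$support, bs2$support)
})

test_that("majority-rule consensus keeps clades above the cutoff", {
  t1 <- newick("((a,b),(c,d),e);")
  t2 <- newick("((a,c),(b,d),e);")
  expect_identical(consensus_majority(list(t1)), t1)
  star <- consensus_majority(list(t1, t2))
  expect_lt(star$Nnode, t1$Nnode)          # conflict collapses to a polytomy
  cons <- consensus_majority(list(t1, t1, t2))
  expect_true(grepl("\\(a,b\\)|\\(b,a\\)", ape::write.tree(cons)))
})
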