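test_that("identical seeds reproduce the simulation bit for bit", {
  a <- simulate_census(n_per_superkingdom = 4, n_ancestral = 6, n_derived = 20,
                       hgt_rate = 0.05, seed = 77)
  b <- simulate_census(n_per_superkingdom = 4, n_ancestral = 6, n_derived = 20,
                       hgt_rate = 0.05, seed = 77)
  expect_identical(a$abundance$g, b$abundance$g)
  expect_identical(a$truth$birth_edge, b$truth$birth_edge)
  expect_identical(ape::write.tree(a$truth$tree), ape::write.tree(b$truth$tree))
})

test_that("derived FSFs stay confined to their birth subtree without HGT", {
  sim <- simulate_census(n_per_superkingdom = 5, n_ancestral = 5,
                         n_derived = 30, loss_prob = 0, hgt_rate = 0, seed = 19)
  phy <- sim$truth$tree
  nt <- length(phy$tip.label)
  for (fsf in sim$truth$derived) {
    edge <- sim$truth$birth_edge[[fsf]]
    clade <- ape::extract.clade(phy, phy$edge[edge, 2])$tip.label
    present <- colnames(sim$abundance$g)[sim$abundance$g[fsf, ] > 0L]
    expect_true(all(present %in% clade))
    expect_true(length(present) > 0)
  }
})

test_that("ancestral FSFs are more abundant than late-born ones", {
  # Wilcoxon rank test over replicates: duplication makes old FSFs plentiful
  withr::with_seed(23, {
    pvals <- vapply(1:10, function(i) {
      sim <- simulate_census(n_per_superkingdom = 4, n_ancestral = 10,
                             n_derived = 40, duplication_rate = 0.15,
                             loss_prob = 0, seed = 1000 + i)
      mg <- rowMeans(sim$abundance$g)
      stats::wilcox.test(mg[sim$truth$ancestral], mg[sim$truth$derived],
                         alternative = "greater", exact = FALSE)$p.value
    }, 0)
  })
  expect_lt(median(pvals), 0.01)
})

test_that("ancestral FSFs sit below derived ones on the structure timeline", {
  fx <- make_fixture("tiny")
  cm <- recode_abundance(fx$sim$abundance)
  cms <- transpose_for_structure_tree(cm)
  rts <- lundberg_root(mp_search(cms, search_config(seed = 2)), cms)
  nd <- compute_nd(rts)
  p <- stats::wilcox.test(nd[fx$sim$truth$ancestral],
                          nd[fx$sim$truth$derived],
                          alternative = "less", exact = FALSE)$p.value
  expect_lt(p, 0.01)
})

test_that("fixture tables round-trip through the census reader", {
  fx <- make_fixture("tiny")
  dir <- tempfile()
  paths <- write_sim_tables(fx$sim, dir)
  meta <- read_proteome_meta(paths[["meta"]])
  m <- read_assignments(paths[["assignments"]], meta = meta)
  g0 <- fx$sim$abundance$g
  g0 <- g0[rowSums(g0) > 0L, , drop = FALSE]      # unborn FSFs have no rows
  expect_equal(sum(m$g), sum(g0))
  expect_setequal(rownames(m$g), rownames(g0))
  expect_identical(m$g[rownames(g0), colnames(g0)], g0)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_setequal(truth$ancestral, fx$sim$truth$ancestral)
})

test_that("tiny fixture tree length is no worse than broad topology sampling", {
  fx <- make_fixture("tiny")
  cm <- recode_abundance(fx$sim$abundance)
  best <- attr(mp_search(cm, search_config(n_addition_replicates = 3,
                                           seed = 6)), "length")
  rand <- withr::with_seed(30, {
    min(vapply(1:200, function(i)
      tree_length(ape::rtopology(nrow(cm$state), rooted = FALSE,
                                 tip.label = rownames(cm$state)), cm), 0))
  })
  expect_lte(best, rand)
})

test_that("small-census recovery: min_set precision and recall across seeds", {
  stats <- vapply(1:6, function(s) {
    sim <- simulate_census(n_per_superkingdom = 6, n_ancestral = 12,
                           n_derived = 40, loss_prob = 0.01, hgt_rate = 0,
                           seed = 500 + s)
    cm <- recode_abundance(sim$abundance)
    cfg <- search_config(seed = s)
    rt <- lundberg_root(mp_search(cm, cfg), cm)
    init <- plesiomorphic_set(root_branch_changes(rt, cm))$character
    ref <- run_refinement(cm, init, n_chains = 2, n_iter = 4, cfg = cfg,
                          seed = s)
    cms <- transpose_for_structure_tree(cm)
    rts <- lundberg_root(mp_search(cms, search_config(seed = s + 50,
                                                      n_addition_replicates = 1)),
                         cms)
    b <- basal_set(compute_nd(rts), classify_occurrence(sim$abundance))
    mn <- intersect(ref$max_set, b)
    anc <- sim$truth$ancestral
    c(precision = if (length(mn)) mean(mn %in% anc) else NA_real_,
      recall = mean(anc %in% mn))
  }, c(precision = 0, recall = 0))
  expect_gte(median(stats["precision", ], na.rm = TRUE), 0.9)
  expect_gte(median(stats["recall", ]), 0.8)
})
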