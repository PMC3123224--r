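test_that("MPR intervals: constant characters pin every node", {
  cm <- char_matrix(matrix(5L, 4, 1, dimnames = list(letters[1:4], "x")),
                    "zero_ancestral", 8L)
  rt <- lundberg_root(newick("((a,b),(c,d));"), cm)
  mpr <- mpr_intervals(rt, cm)
  expect_true(all(mpr$lo == 5L))
  expect_true(all(mpr$hi == 5L))
})

test_that("MPR root interval matches brute-force enumeration", {
  st <- setNames(c(0L, 3L, 3L, 3L), letters[1:4])
  cm <- char_matrix(matrix(st, 4, 1, dimnames = list(names(st), "x")),
                    "zero_ancestral", 4L)
  rt <- lundberg_root(newick("((a,b),(c,d));"), cm)
  mpr <- mpr_intervals(rt, cm)
  states <- brute_force_root_states(rt$phy, st, 4L, anc = 0L)
  expect_equal(mpr$lo[mpr$root, "x"], min(states))
  expect_equal(mpr$hi[mpr$root, "x"], max(states))

  # random instances: lo <= hi everywhere and root interval is exact
  for (seed in 1:5) {
    cmr <- random_cm(5, 4, 4, seed, taxa = letters[1:5])
    tr <- withr::with_seed(seed, ape::rtree(5, tip.label = letters[1:5],
                                            br = NULL))
    tr <- ape::unroot(tr)
    rtr <- lundberg_root(tr, cmr)
    mpri <- mpr_intervals(rtr, cmr)
    expect_true(all(mpri$lo <= mpri$hi))
    for (j in seq_len(ncol(cmr$state))) {
      states <- brute_force_root_states(rtr$phy, cmr$state[, j], 4L, anc = 0L)
      expect_equal(unname(mpri$lo[mpri$root, j]), min(states))
      expect_equal(unname(mpri$hi[mpri$root, j]), max(states))
    }
  }
})

test_that("clamped assignments drawn from MPR intervals rescore to the optimum", {
  # assign the root any interval value, then clamp children to their intervals:
  # the resulting full assignment must achieve exactly the minimal length
  for (seed in 1:4) {
    cm <- random_cm(6, 5, 5, seed, taxa = letters[1:6])
    tr <- ape::unroot(withr::with_seed(seed,
      ape::rtree(6, tip.label = letters[1:6], br = NULL)))
    rt <- lundberg_root(tr, cm)
    mpr <- mpr_intervals(rt, cm)
    phy <- ape::reorder.phylo(rt$phy, "cladewise")
    nt <- length(phy$tip.label)
    for (j in seq_len(ncol(cm$state))) {
      assign <- rep(NA_integer_, nt + phy$Nnode)
      assign[seq_len(nt)] <- cm$state[phy$tip.label, j]
      root <- mpr$root
      assign[root] <- mpr$lo[root, j]
      for (i in seq_len(nrow(phy$edge))) {
        p <- phy$edge[i, 1]; ch <- phy$edge[i, 2]
        if (ch > nt)
          assign[ch] <- min(max(assign[p], mpr$lo[ch, j]), mpr$hi[ch, j])
      }
      len <- sum(abs(assign[phy$edge[, 1]] - assign[phy$edge[, 2]])) +
        abs(assign[root] - rt$anc[j])
      expect_equal(len, unname(mpr$length[j]))
    }
  }
})

test_that("root-branch changes: ubiquity, ambiguity and the no-loss rule", {
  # character present in every leaf is an unambiguous root gain
  st <- cbind(ubiq = c(2L, 1L, 3L, 2L, 1L, 2L),
              rare = c(0L, 0L, 0L, 0L, 0L, 3L))
  rownames(st) <- letters[1:6]
  cm <- char_matrix(st, "zero_ancestral", 4L)
  tr <- newick("(((a,b),c),((d,e),f));")
  rt <- lundberg_root(ape::unroot(tr), cm)
  rec <- root_branch_changes(rt, cm)
  ubiq <- rec[rec$character == "ubiq", ]
  expect_true(ubiq$gain)
  expect_false(ubiq$ambiguous)
  expect_gt(ubiq$gain_steps, 0)

  # a character in a single leaf cannot be an unambiguous root gain
  rare <- rec[rec$character == "rare", ]
  expect_true(!rare$gain || rare$ambiguous)
  states <- brute_force_root_states(rt$phy, st[, "rare"], 4L, anc = 0L)
  expect_true(0L %in% states)   # the optimum admits absence at the root

  # with a zero ancestor no character can show a root-branch loss
  for (seed in 1:5) {
    cmr <- random_cm(6, 8, 6, seed)
    tres <- mp_search(cmr, search_config(seed = seed))
    rtr <- lundberg_root(tres, cmr)
    recs <- root_branch_changes(rtr, cmr)
    expect_true(all(!recs$loss))
    expect_true(all(recs$loss_steps == 0L))
  }
})

test_that("plesiomorphic_set collects gains and flags ambiguity", {
  rec <- data.frame(character = c("f1", "f2", "f3", "f4", "f5"),
                    gain = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                    loss = FALSE,
                    gain_steps = c(2L, 1L, 3L, 0L, 0L),
                    loss_steps = 0L,
                    ambiguous = c(FALSE, FALSE, FALSE, TRUE, FALSE),
                    lo = 0L, hi = 2L)
  ps <- plesiomorphic_set(rec)
  expect_equal(nrow(ps), 4)
  expect_equal(sum(ps$ambiguous), 1)
  expect_equal(nrow(plesiomorphic_set(rec[0, ])), 0)
  expect_equal(nrow(plesiomorphic_set(rec, include_ambiguous = FALSE)), 3)
})

test_that("characters present in every leaf are root gains on random trees", {
  for (seed in 1:6) {
    cm <- withr::with_seed(seed, {
      st <- matrix(sample(1:5, 7 * 4, TRUE), 7, 4,
                   dimnames = list(sprintf("t%d", 1:7), sprintf("c%d", 1:4)))
      char_matrix(st, "zero_ancestral", 6L)
    })
    rt <- lundberg_root(mp_search(cm, search_config(seed = seed)), cm)
    rec <- root_branch_changes(rt, cm)
    expect_true(all(rec$gain))
    expect_true(all(!rec$ambiguous))
  }
})
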