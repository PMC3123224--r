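#' Search configuration for maximum parsimony
#'
#' Desk-scale defaults: 2 random-addition replicates with NNI hill climbing and
#' up to 16 retained equally parsimonious trees. `preset = "paper"` switches to
#' the full-scale setting (1,000 addition replicates, unrestricted trees) used
#' for production runs on large censuses.
#'
#' @param n_addition_replicates random taxon-addition starting trees per search.
#' @param swap branch swapping scheme; `"NNI"` (nearest-neighbour interchange)
#'   is the supported rearrangement.
#' @param maxtrees maximum number of equally parsimonious trees retained.
#' @param seed integer seed making the search reproducible.
#' @param max_plateau maximum number of equal-length trees expanded while
#'   exploring a parsimony plateau.
#' @param preset `"desk"` (default) or `"paper"`.
#' @return a list of class `search_config`.
#' @export
search_config <- function(n_addition_replicates = 2L, swap = "NNI",
                          maxtrees = 16L, seed = 1L, max_plateau = 32L,
                          preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    n_addition_replicates <- 1000L
    maxtrees <- 1000L
  }
  stopifnot(n_addition_replicates >= 1L, maxtrees >= 1L)
  structure(list(n_addition_replicates = as.integer(n_addition_replicates),
                 swap = match.arg(swap, c("NNI")), maxtrees = as.integer(maxtrees),
                 seed = as.integer(seed), max_plateau = as.integer(max_plateau)),
            class = "search_config")
}

# states matrix ordered to match the tree's tip labels
.states_for <- function(tree, cm) {
  if (is.null(tree$tip.label) || !length(tree$tip.label))
    stop("tree has no tip labels (was it extracted from a compressed multiPhylo?)")
  miss <- setdiff(tree$tip.label, rownames(cm$state))
  if (length(miss)) stop("taxa missing from character matrix: ", miss[1])
  cm$state[tree$tip.label, , drop = FALSE]
}

#' Hypothetical-ancestor states implied by a matrix's polarity
#'
#' All-zero for `zero_ancestral` polarity, all-maximum for `max_ancestral`.
#'
#' @param cm a `char_matrix`.
#' @return integer vector, one ancestral state per character.
#' @export
ancestor_states <- function(cm) {
  rep(if (cm$polarity == "zero_ancestral") 0L else cm$n_states - 1L,
      ncol(cm$state))
}

#' Parsimony length of a tree under ordered (Wagner) characters
#'
#' Minimal number of steps, summing `|i - j|` along every edge over the best
#' internal-state assignment (computed by dynamic programming). With
#' `ancestor = "polarity"` the hypothetical ancestor implied by the matrix
#' polarity is attached above the root and its edge contributes steps (the
#' rooted, Lundberg-style length); with `"none"` the plain (unrooted) length is
#' returned.
#'
#' @param tree an `ape::phylo`; every leaf must carry states in `cm`.
#' @param cm a `char_matrix`.
#' @param ancestor `"none"` (default) or `"polarity"`.
#' @param per_character return the per-character length vector instead of the
#'   total.
#' @param ordered score characters as linearly ordered (default); `FALSE`
#'   switches to unordered unit cost, for contrast only.
#' @return integer total length, or a named integer vector if `per_character`.
#' @export
tree_length <- function(tree, cm, ancestor = c("none", "polarity"),
                        per_character = FALSE, ordered = TRUE) {
  stopifnot(inherits(cm, "char_matrix"))
  ancestor <- match.arg(ancestor)
  anc <- if (ancestor == "polarity") ancestor_states(cm) else integer(0)
  st <- .states_for(tree, cm)
  len <- tree_length_ordered_cpp(tree$edge, length(tree$tip.label), st,
                                 cm$n_states, anc, ordered)
  names(len) <- colnames(cm$state)
  if (per_character) len else sum(len)
}

# insert a new tip in the middle of edge `edge_row`
.add_tip <- function(tr, edge_row, label) {
  nt <- length(tr$tip.label)
  e <- tr$edge
  e[e > nt] <- e[e > nt] + 1L
  new_tip <- nt + 1L
  new_node <- nt + 1L + tr$Nnode + 1L
  child <- e[edge_row, 2]
  e[edge_row, 2] <- new_node
  e <- rbind(e, c(new_node, child), c(new_node, new_tip))
  tr$edge <- e
  tr$tip.label <- c(tr$tip.label, label)
  tr$Nnode <- tr$Nnode + 1L
  tr
}

# stepwise random addition: greedy best attachment for each taxon in `order`.
# Attaching a leaf with fixed states to every edge is the same computation as
# the Lundberg ancestor scan, so each step costs one pass over the tree.
.addition_tree <- function(cm, order) {
  tr <- structure(list(edge = cbind(rep(4L, 3), 1:3), Nnode = 1L,
                       tip.label = order[1:3]), class = "phylo")
  for (tax in order[-(1:3)]) {
    st <- cm$state[tr$tip.label, , drop = FALSE]
    lens <- lundberg_edge_lengths_cpp(tr$edge, length(tr$tip.label), st,
                                      cm$n_states, cm$state[tax, ], TRUE)
    tr <- .add_tip(tr, which.min(lens), tax)
  }
  tr
}

# batch score topologies that share the tip label vector of `ref_labels`
.score_many <- function(trees, cm, ref_labels) {
  st <- cm$state[ref_labels, , drop = FALSE]
  same <- vapply(trees, function(t) identical(t$tip.label, ref_labels), TRUE)
  if (all(same)) {
    tree_lengths_many_cpp(lapply(trees, `[[`, "edge"), length(ref_labels),
                          st, cm$n_states, integer(0), TRUE)
  } else {
    vapply(trees, tree_length, 0, cm = cm)
  }
}

# canonical topology key: root at the alphabetically first tip, then sort
# sibling subtrees by their newick strings
.topo_key <- function(tr) {
  out <- sort(tr$tip.label)[1]
  tr2 <- ape::root(tr, outgroup = out, resolve.root = TRUE)
  nt <- length(tr2$tip.label)
  kids <- split(tr2$edge[, 2], tr2$edge[, 1])
  root <- setdiff(unique(tr2$edge[, 1]), tr2$edge[, 2])[1]
  key_of <- function(v) {
    if (v <= nt) return(tr2$tip.label[v])
    k <- sort(vapply(kids[[as.character(v)]], key_of, ""))
    paste0("(", paste(k, collapse = ","), ")")
  }
  key_of(root)
}

# NNI hill climbing followed by bounded exploration of the equal-length plateau
.nni_climb <- function(tr, cm, maxtrees, max_plateau) {
  len <- tree_length(tr, cm)
  if (length(tr$tip.label) < 4L)
    return(list(length = len, trees = list(tr), keys = .topo_key(tr)))
  repeat {
    nbs <- phangorn::nni(tr)
    lens <- .score_many(nbs, cm, tr$tip.label)
    if (min(lens) < len) {
      len <- min(lens)
      tr <- nbs[[which.min(lens)]]
    } else break
  }
  pool <- list(tr)
  keys <- .topo_key(tr)
  queue <- list(tr)
  expanded <- 0L
  while (length(queue) && expanded < max_plateau && length(pool) < maxtrees) {
    t0 <- queue[[1]]
    queue <- queue[-1]
    expanded <- expanded + 1L
    nbs <- phangorn::nni(t0)
    lens <- .score_many(nbs, cm, t0$tip.label)
    if (min(lens) < len) {  # plateau walk found a deeper optimum: restart
      len <- min(lens)
      tr <- nbs[[which.min(lens)]]
      res <- .nni_climb(tr, cm, maxtrees, max_plateau)
      return(res)
    }
    for (i in which(lens == len)) {
      k <- .topo_key(nbs[[i]])
      if (!(k %in% keys) && length(pool) < maxtrees) {
        pool <- c(pool, list(nbs[[i]]))
        keys <- c(keys, k)
        queue <- c(queue, list(nbs[[i]]))
      }
    }
  }
  list(length = len, trees = pool, keys = keys)
}

#' Heuristic maximum parsimony search on ordered characters
#'
#' Random taxon-addition starting trees followed by NNI branch swapping,
#' retaining all distinct equally parsimonious topologies found (up to
#' `cfg$maxtrees`). The search optimizes unrooted length; root afterwards with
#' [lundberg_root()]. Deterministic given `cfg$seed`.
#'
#' @param cm a `char_matrix` with at least 3 taxa.
#' @param cfg a [search_config()].
#' @return an `ape::multiPhylo` of equally shortest trees, sorted by canonical
#'   topology key, with attribute `length` (the shared parsimony length).
#' @export
mp_search <- function(cm, cfg = search_config()) {
  taxa <- rownames(cm$state)
  if (length(taxa) < 3L) stop("need at least 3 taxa for a tree search")
  withr::with_seed(cfg$seed, {
    best_len <- Inf
    pool <- list()
    keys <- character(0)
    for (rep in seq_len(cfg$n_addition_replicates)) {
      tr <- .addition_tree(cm, sample(taxa))
      res <- .nni_climb(tr, cm, cfg$maxtrees, cfg$max_plateau)
      if (res$length < best_len) {
        best_len <- res$length
        pool <- res$trees
        keys <- res$keys
      } else if (res$length == best_len) {
        new <- !(res$keys %in% keys)
        pool <- c(pool, res$trees[new])[seq_len(min(cfg$maxtrees, length(pool) + sum(new)))]
        keys <- c(keys, res$keys[new])[seq_along(pool)]
      }
    }
  })
  ord <- order(keys)
  out <- structure(pool[ord], class = "multiPhylo")
  attr(out, "length") <- best_len
  out
}

# re-root an unrooted tree at the midpoint of edge `edge_row`
.root_at_edge <- function(tr, edge_row) {
  nt <- length(tr$tip.label)
  ntot <- nt + tr$Nnode
  e <- tr$edge
  u <- e[edge_row, 1]
  v <- e[edge_row, 2]
  adj <- vector("list", ntot)
  for (i in seq_len(nrow(e))) {
    if (i == edge_row) next
    adj[[e[i, 1]]] <- c(adj[[e[i, 1]]], e[i, 2])
    adj[[e[i, 2]]] <- c(adj[[e[i, 2]]], e[i, 1])
  }
  # orient away from a virtual root joining u and v
  par <- integer(ntot)        # 0 = unset, -1 = root child
  ord <- integer(0)           # visit order (old ids)
  stack <- c(u, v)
  par[u] <- -1L
  par[v] <- -1L
  while (length(stack)) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ord <- c(ord, x)
    for (y in adj[[x]]) {
      if (par[y] == 0L) {
        par[y] <- x
        stack <- c(stack, y)
      }
    }
  }
  new_id <- integer(ntot)
  new_id[seq_len(nt)] <- seq_len(nt)
  nxt <- nt + 2L              # nt + 1 is the new root
  for (x in ord) if (x > nt) { new_id[x] <- nxt; nxt <- nxt + 1L }
  e2 <- matrix(0L, 0, 2)
  for (x in ord) {
    p <- if (par[x] == -1L) nt + 1L else new_id[par[x]]
    e2 <- rbind(e2, c(p, new_id[x]))
  }
  structure(list(edge = e2, Nnode = tr$Nnode + 1L, tip.label = tr$tip.label),
            class = "phylo")
}

#' Root a tree with a hypothetical ancestor (Lundberg method)
#'
#' Attaches the hypothetical ancestor implied by the matrix polarity (all-zero
#' or all-maximum states) to every edge in turn and keeps the attachment that
#' minimizes total rooted length. No outgroup taxon is required. Ties among
#' attachment edges are reported and broken deterministically (first edge in
#' the input edge order).
#'
#' @param tree an unrooted `ape::phylo` over the taxa of `cm` (a `multiPhylo`
#'   is accepted; its first tree is used).
#' @param cm a `char_matrix` with declared polarity.
#' @return an object of class `lundberg_tree`: the rooted topology (`$phy`,
#'   root node is the ancestor attachment point), the ancestral states
#'   (`$anc`), total and per-character rooted length, the unrooted length, and
#'   the tied attachment edges.
#' @export
lundberg_root <- function(tree, cm) {
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  stopifnot(inherits(tree, "phylo"), inherits(cm, "char_matrix"))
  st <- .states_for(tree, cm)
  anc <- ancestor_states(cm)
  lens <- lundberg_edge_lengths_cpp(tree$edge, length(tree$tip.label), st,
                                    cm$n_states, anc, TRUE)
  best <- which(lens == min(lens))
  phy <- .root_at_edge(tree, best[1])
  per_char <- tree_length(phy, cm, ancestor = "polarity", per_character = TRUE)
  structure(list(phy = phy, anc = anc, polarity = cm$polarity,
                 n_states = cm$n_states, length = sum(per_char),
                 per_char = per_char,
                 unrooted_length = tree_length(tree, cm),
                 attachment_edge = tree$edge[best[1], ],
                 tied_edges = best),
            class = "lundberg_tree")
}

#' @export
print.lundberg_tree <- function(x, ...) {
  cat("Lundberg-rooted tree:", length(x$phy$tip.label), "taxa;",
      length(x$per_char), "characters\n")
  cat("  rooted length", x$length, "(unrooted", x$unrooted_length, ");",
      "polarity", x$polarity, "\n")
  if (length(x$tied_edges) > 1)
    cat("  note:", length(x$tied_edges), "equally optimal attachment edges\n")
  invisible(x)
}

#' Consistency and retention indices of a scored tree
#'
#' `CI = sum(m) / L` and `RI = (sum(g) - L) / (sum(g) - sum(m))`, where for
#' each character `m` is the minimum conceivable length (the observed state
#' range) and `g` is the maximum (the length on a star tree, i.e. the best
#' single-ancestor bush). For a `lundberg_tree` the hypothetical ancestor's
#' state participates in `m` and `g`, consistently with the rooted length.
#'
#' @param tree a `lundberg_tree`, or an unrooted `phylo` (scored without
#'   ancestor).
#' @param cm the `char_matrix` the tree was scored on.
#' @return list with elements `ci`, `ri` (NA when `sum(g) == sum(m)`) and
#'   `length`.
#' @export
ci_ri <- function(tree, cm) {
  stopifnot(inherits(cm, "char_matrix"))
  if (inherits(tree, "lundberg_tree")) {
    per_char <- tree$per_char
    extra <- tree$anc
  } else {
    per_char <- tree_length(tree, cm, per_character = TRUE)
    extra <- NULL
  }
  L <- sum(per_char)
  S <- cm$n_states
  m_c <- g_c <- numeric(ncol(cm$state))
  for (j in seq_len(ncol(cm$state))) {
    vals <- cm$state[, j]
    if (!is.null(extra)) vals <- c(vals, extra[j])
    m_c[j] <- max(vals) - min(vals)
    g_c[j] <- min(vapply(0:(S - 1L), function(a) sum(abs(vals - a)), 0))
  }
  ci <- if (L == 0) 1 else sum(m_c) / L
  ri <- if (sum(g_c) == sum(m_c)) NA_real_ else (sum(g_c) - L) / (sum(g_c) - sum(m_c))
  list(ci = ci, ri = ri, length = L)
}

#' Skewness (g1) of the random-tree length distribution
#'
#' Phylogenetic signal statistic: the Fisher-Pearson skewness of parsimony
#' lengths over uniformly drawn random topologies. Strongly structured data
#' give left-skewed (negative g1) distributions.
#'
#' @param cm a `char_matrix` with at least 4 taxa.
#' @param n_random number of random topologies (full scale: 1,000).
#' @param seed integer seed.
#' @return the g1 statistic (0 when all lengths are equal).
#' @export
g1_skewness <- function(cm, n_random = 1000L, seed = 1L) {
  taxa <- rownames(cm$state)
  if (length(taxa) < 4L) stop("need at least 4 taxa for the g1 test")
  lens <- withr::with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      tree_length(ape::rtopology(length(taxa), rooted = FALSE, tip.label = taxa), cm)
    }, 0)
  })
  m2 <- mean((lens - mean(lens))^2)
  if (m2 == 0) return(0)
  mean((lens - mean(lens))^3) / m2^1.5
}

#' Nonparametric bootstrap support for clades
#'
#' Characters are resampled with replacement to the original character count,
#' a parsimony search is run on each pseudoreplicate, and each internal edge of
#' the reference tree is scored by the percentage of replicates whose best tree
#' contains the corresponding bipartition.
#'
#' @param cm a `char_matrix`.
#' @param reps number of bootstrap replicates.
#' @param cfg a [search_config()]; its seed also seeds the resampling.
#' @param tree optional reference tree (defaults to the first tree of a fresh
#'   search on `cm`).
#' @return list with the reference `tree` and `support`, a numeric vector of
#'   percentages, one per internal node of the reference tree.
#' @export
bootstrap_support <- function(cm, reps = 100L, cfg = search_config(),
                              tree = NULL) {
  stopifnot(reps >= 1L)
  if (is.null(tree)) tree <- mp_search(cm, cfg)[[1]]
  boots <- withr::with_seed(cfg$seed + 7919L, {
    lapply(seq_len(reps), function(r) {
      idx <- sample(ncol(cm$state), replace = TRUE)
      cmb <- char_matrix(cm$state[, idx, drop = FALSE] |>
                           `colnames<-`(sprintf("bs%d", seq_along(idx))),
                         cm$polarity, cm$n_states)
      rcfg <- cfg
      rcfg$seed <- cfg$seed + r
      mp_search(cmb, rcfg)[[1]]
    })
  })
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  list(tree = tree, support = 100 * counts / reps)
}

#' Majority-rule consensus of equally parsimonious trees
#'
#' @param trees a `multiPhylo` (or list of `phylo`) on one leaf set.
#' @param cutoff clades with frequency strictly above this fraction are kept
#'   (0.5 = standard majority rule).
#' @return a `phylo`, possibly with polytomies.
#' @export
consensus_majority <- function(trees, cutoff = 0.5) {
  if (inherits(trees, "phylo")) return(trees)
  trees <- structure(trees, class = "multiPhylo")
  if (length(trees) == 1L) return(trees[[1]])
  ape::consensus(trees, p = cutoff + 1e-9, check.labels = TRUE)
}
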