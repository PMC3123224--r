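#' One chain of iterative root-branch refinement
#'
#' Starting from an initial character (FSF) set, each iteration (i) builds
#' maximum parsimony trees on the current character set, (ii) Lundberg-roots
#' them, (iii) extracts the characters gained on the root branch, and (iv)
#' makes those characters the set for the next iteration. The chain stops
#' early once the set has been identical for `converge_after` consecutive
#' iterations. Every most parsimonious tree encountered is retained for
#' post-hoc selection.
#'
#' @param cm the full `char_matrix` (taxa x all characters).
#' @param init_fsfs character vector, subset of `colnames(cm$state)`.
#' @param n_iter maximum iterations (full scale: 50).
#' @param cfg a [search_config()]; per-iteration seeds are derived from `seed`.
#' @param seed chain seed.
#' @param converge_after stop after this many consecutive identical sets.
#' @param combine `"union"` (default) pools the root sets of all equally
#'   parsimonious trees of an iteration; `"intersection"` keeps only characters
#'   at the root of every tree.
#' @return list of class `chain_trace`: `trace` data frame (iteration 0 is the
#'   initial set), `retained` list of per-tree records `(length, n_fsfs,
#'   set, iteration)`, and the final `fsf_set`.
#' @export
run_chain <- function(cm, init_fsfs, n_iter = 50L, cfg = search_config(),
                      seed = 1L, converge_after = 5L,
                      combine = c("union", "intersection")) {
  stopifnot(inherits(cm, "char_matrix"))
  combine <- match.arg(combine)
  if (!all(init_fsfs %in% colnames(cm$state)))
    stop("init_fsfs contains characters absent from the matrix")
  set <- sort(unique(init_fsfs))
  trace <- data.frame(iteration = 0L, n_fsfs = length(set),
                      tree_length = NA_real_, n_ambiguous = NA_integer_)
  sets <- list(set)
  retained <- list()
  streak <- 0L
  for (i in seq_len(n_iter)) {
    if (length(set) < 1L) break
    sub <- char_matrix(cm$state[, set, drop = FALSE], cm$polarity, cm$n_states)
    icfg <- cfg
    icfg$seed <- (seed * 131L + i) %% 2147483647L
    trees <- mp_search(sub, icfg)
    per_tree <- lapply(seq_along(trees), function(k) {
      rt <- lundberg_root(trees[[k]], sub)
      ps <- plesiomorphic_set(root_branch_changes(rt, sub))
      list(length = rt$length, n_fsfs = nrow(ps), set = ps$character,
           n_ambiguous = sum(ps$ambiguous), iteration = i, tree = rt)
    })
    retained <- c(retained, per_tree)
    all_sets <- lapply(per_tree, `[[`, "set")
    new_set <- sort(if (combine == "union") Reduce(union, all_sets)
                    else Reduce(intersect, all_sets))
    amb <- max(vapply(per_tree, `[[`, 0L, "n_ambiguous"))
    trace <- rbind(trace, data.frame(
      iteration = i, n_fsfs = length(new_set),
      tree_length = min(vapply(per_tree, `[[`, 0, "length")),
      n_ambiguous = amb))
    if (!length(new_set)) {
      warning("chain reached an empty character set at iteration ", i)
      set <- new_set
      break
    }
    streak <- if (identical(new_set, set)) streak + 1L else 0L
    set <- new_set
    sets <- c(sets, list(set))
    if (streak >= converge_after) break
  }
  structure(list(trace = trace, retained = retained, fsf_set = set,
                 seed = seed), class = "chain_trace")
}

#' Iterative refinement across chains; selection of the max_set
#'
#' Runs `n_chains` independent refinement chains (distinct derived seeds) and
#' selects, among all most parsimonious trees retained across all iterations
#' and chains, the tree with minimal rooted length and, among those, the
#' smallest root-branch FSF set. That set is the upper bound (`max_set`) of
#' the ancestral repertoire.
#'
#' @param cm full `char_matrix`.
#' @param init_fsfs initial character set (e.g. the root-branch set of the
#'   first tree of proteomes).
#' @param n_chains number of chains (full scale: 30).
#' @param n_iter iterations per chain (full scale: 50).
#' @param cfg a [search_config()].
#' @param seed master seed; chain `k` uses `seed + k`.
#' @param ... passed to [run_chain()].
#' @return list of class `refinement_result`: `chains` (list of
#'   `chain_trace`), `max_set`, `selected_tree` (a `lundberg_tree`),
#'   `selected` (chain/iteration/length bookkeeping) and `ties`, the number of
#'   equally good candidates.
#' @export
run_refinement <- function(cm, init_fsfs, n_chains = 30L, n_iter = 50L,
                           cfg = search_config(), seed = 1L, ...) {
  stopifnot(n_chains >= 1L)
  chains <- lapply(seq_len(n_chains), function(k) {
    run_chain(cm, init_fsfs, n_iter = n_iter, cfg = cfg, seed = seed + k, ...)
  })
  cand <- do.call(rbind, lapply(seq_along(chains), function(k) {
    ret <- chains[[k]]$retained
    if (!length(ret)) return(NULL)
    data.frame(chain = k, idx = seq_along(ret),
               iteration = vapply(ret, `[[`, 0L, "iteration"),
               length = vapply(ret, `[[`, 0, "length"),
               n_fsfs = vapply(ret, `[[`, 0L, "n_fsfs"))
  }))
  if (is.null(cand) || !nrow(cand)) stop("refinement retained no trees")
  best <- cand[cand$length == min(cand$length), , drop = FALSE]
  best <- best[best$n_fsfs == min(best$n_fsfs), , drop = FALSE]
  pick <- best[order(best$chain, best$idx), , drop = FALSE][1, ]
  rec <- chains[[pick$chain]]$retained[[pick$idx]]
  structure(list(chains = chains, max_set = sort(rec$set),
                 selected_tree = rec$tree, selected = pick,
                 ties = nrow(best)),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat("Iterative refinement:", length(x$chains), "chains\n")
  cat("  selected tree: chain", x$selected$chain, "iteration",
      x$selected$iteration, "length", x$selected$length, "\n")
  cat("  max_set size:", length(x$max_set),
      if (x$ties > 1) sprintf("(%d equally good candidates)", x$ties) else "", "\n")
  invisible(x)
}
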