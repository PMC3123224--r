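#' Most-parsimonious reconstruction (MPR) state intervals
#'
#' For each node and each ordered character, the interval `[lo, hi]` of states
#' that the node takes across all most-parsimonious assignments on the rooted
#' tree (the hypothetical ancestor's fixed states participate in the optimum).
#' Leaves have point intervals at their observed states.
#'
#' @param tree a `lundberg_tree` (see [lundberg_root()]).
#' @param cm the `char_matrix` the tree was built from.
#' @return list with integer matrices `lo` and `hi` (rows: tips then internal
#'   nodes, in `ape` node numbering; columns: characters), the per-character
#'   minimal length, and `root`, the root node id.
#' @export
mpr_intervals <- function(tree, cm) {
  stopifnot(inherits(tree, "lundberg_tree"), inherits(cm, "char_matrix"))
  phy <- tree$phy
  st <- .states_for(phy, cm)
  res <- mpr_intervals_cpp(phy$edge, length(phy$tip.label), st, cm$n_states,
                           tree$anc)
  rn <- c(phy$tip.label,
          sprintf("node%d", seq_len(nrow(res$lo) - length(phy$tip.label)) +
                    length(phy$tip.label)))
  dimnames(res$lo) <- dimnames(res$hi) <- list(rn, colnames(cm$state))
  names(res$length) <- colnames(cm$state)
  res
}

#' Character-state changes on the root branch
#'
#' The root branch connects the hypothetical ancestor to the root (attachment)
#' node. A character is a root-branch gain when the root's MPR interval admits
#' a state above the ancestral state, and a loss when it admits a state below
#' it; the change is flagged ambiguous when the interval also admits the
#' ancestral state itself, i.e. the change can be deferred to deeper branches
#' at no cost. With a zero-state ancestor no losses are possible (states
#' cannot drop below 0).
#'
#' @param tree a `lundberg_tree`.
#' @param cm the `char_matrix`.
#' @return data frame with one row per character: `character`, `gain`, `loss`,
#'   `gain_steps`, `loss_steps`, `ambiguous`, `lo`, `hi` (root interval).
#' @export
root_branch_changes <- function(tree, cm) {
  mpr <- mpr_intervals(tree, cm)
  lo <- mpr$lo[mpr$root, ]
  hi <- mpr$hi[mpr$root, ]
  anc <- tree$anc
  gain <- hi > anc
  loss <- lo < anc
  ambiguous <- (gain | loss) & lo <= anc & hi >= anc
  data.frame(character = colnames(cm$state),
             gain = gain, loss = loss,
             gain_steps = ifelse(gain & !ambiguous, lo - anc, 0L),
             loss_steps = ifelse(loss & !ambiguous, anc - hi, 0L),
             ambiguous = ambiguous, lo = lo, hi = hi,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Plesiomorphic (root-branch) character set
#'
#' Characters gained on the root branch of a Lundberg-rooted tree; ambiguous
#' gains are included but flagged, mirroring the ambiguity bookkeeping of the
#' iterative refinement.
#'
#' @param records output of [root_branch_changes()].
#' @param include_ambiguous include ambiguous root gains (default TRUE).
#' @return data frame with columns `character` and `ambiguous`.
#' @export
plesiomorphic_set <- function(records, include_ambiguous = TRUE) {
  keep <- records$gain | records$loss
  if (!include_ambiguous) keep <- keep & !records$ambiguous
  records[keep, c("character", "ambiguous"), drop = FALSE]
}
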