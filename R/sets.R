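#' Superkingdom occurrence class of each FSF
#'
#' Labels every FSF by the superkingdoms in which it is present (`g > 0` in at
#' least one proteome): `"A"`, `"B"`, `"E"`, `"AB"`, `"AE"`, `"BE"` or
#' `"ABE"`.
#'
#' @param m an `abundance_matrix` whose metadata covers all three
#'   superkingdoms.
#' @return named character vector of labels, one per FSF.
#' @export
classify_occurrence <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  sk <- m$meta$superkingdom[match(colnames(m$g), m$meta$proteome_id)]
  if (!all(c("A", "B", "E") %in% sk))
    stop("a superkingdom has zero proteomes; occurrence classes undefined")
  lab <- vapply(seq_len(nrow(m$g)), function(i) {
    paste(sort(unique(sk[m$g[i, ] > 0L])), collapse = "")
  }, "")
  setNames(lab, rownames(m$g))
}

#' Popularity indices f and mean of G
#'
#' `f` is the fraction of proteomes containing an FSF (0-1); `mean_g` is the
#' FSF's total abundance summed over proteomes divided by the number of
#' proteomes.
#'
#' @param m an `abundance_matrix`.
#' @return data frame with columns `fsf`, `f`, `mean_g`.
#' @export
popularity <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (!length(m$g)) stop("empty abundance matrix")
  data.frame(fsf = rownames(m$g),
             f = rowMeans(m$g > 0L),
             mean_g = rowMeans(m$g),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Basal set of FSFs on the structure-tree timeline
#'
#' The FSFs that appeared before the first appearance of an FSF not shared by
#' all three superkingdoms: all FSFs with `nd` strictly below the minimum `nd`
#' among non-ABE FSFs. Ties at that boundary are excluded (conservative, as
#' befits a lower bound).
#'
#' @param fsf_nd named numeric vector of node distances of FSFs on the tree of
#'   domain structures (see [compute_nd()]).
#' @param occ named occurrence labels from [classify_occurrence()].
#' @return character vector of FSF ids, with attribute `boundary_nd`.
#' @export
basal_set <- function(fsf_nd, occ) {
  occ <- occ[names(fsf_nd)]
  non_abe <- names(fsf_nd)[!is.na(occ) & occ != "ABE"]
  if (!length(non_abe)) {
    warning("no non-ABE FSF present; basal set is the whole timeline")
    out <- names(fsf_nd)
    attr(out, "boundary_nd") <- NA_real_
    return(out)
  }
  boundary <- min(fsf_nd[non_abe])
  out <- names(fsf_nd)[fsf_nd < boundary]
  attr(out, "boundary_nd") <- boundary
  out
}

#' Append an artificial urancestral taxon to a character matrix
#'
#' The artificial proteome carries the maximum state (symbol `N`) for every
#' member of the urancestral set and state 0 for every other character, i.e.
#' maximum abundance for the urancestral FSFs and absence otherwise.
#'
#' @param cm a `char_matrix` whose taxa are proteomes.
#' @param ur_set character vector, subset of the matrix's characters.
#' @param label taxon name for the artificial urancestor.
#' @return the extended `char_matrix`.
#' @export
inject_urancestor <- function(cm, ur_set, label = "urancestor") {
  stopifnot(inherits(cm, "char_matrix"))
  if (!all(ur_set %in% colnames(cm$state)))
    stop("ur_set contains characters absent from the matrix")
  if (label %in% rownames(cm$state))
    stop("taxon label '", label, "' already present")
  row <- ifelse(colnames(cm$state) %in% ur_set, cm$n_states - 1L, 0L)
  st <- rbind(cm$state, matrix(as.integer(row), 1,
                               dimnames = list(label, NULL)))
  char_matrix(st, cm$polarity, cm$n_states)
}

#' Assemble the nested urancestral sets
#'
#' Bookkeeping helper: intersects the refinement `max_set` with the structure
#' tree's `basal_set` to give the `min_set` lower bound.
#'
#' @param set352 initial root-branch set of the first tree of proteomes.
#' @param max_set refinement fixed point.
#' @param basal character vector from [basal_set()].
#' @return list of class `urancestral_sets` with `set352`, `basal_set`,
#'   `max_set`, `min_set`.
#' @export
urancestral_sets <- function(set352, max_set, basal) {
  structure(list(set352 = sort(set352), basal_set = sort(basal),
                 max_set = sort(max_set),
                 min_set = sort(intersect(max_set, basal))),
            class = "urancestral_sets")
}

#' @export
print.urancestral_sets <- function(x, ...) {
  cat(sprintf("Urancestral sets: initial %d -> max_set %d; basal %d; min_set %d\n",
              length(x$set352), length(x$max_set), length(x$basal_set),
              length(x$min_set)))
  invisible(x)
}
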