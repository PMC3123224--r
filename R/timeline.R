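#' Node-distance (nd) timeline of a rooted tree
#'
#' The relative age proxy of each leaf: the number of internal nodes strictly
#' between the root and the leaf (the root itself is not counted), divided by
#' the maximum such count over all leaves. The most ancestral taxon (attached
#' directly at the root) has `nd = 0`; the most derived has `nd = 1`.
#'
#' @param tree a `lundberg_tree` or a rooted `ape::phylo`.
#' @param root_inclusive count the root node as well (sensitivity flag;
#'   default FALSE, which gives the stated boundary behaviour).
#' @return named numeric vector of `nd` values in `[0, 1]`, one per leaf.
#' @export
compute_nd <- function(tree, root_inclusive = FALSE) {
  phy <- if (inherits(tree, "lundberg_tree")) tree$phy else tree
  stopifnot(inherits(phy, "phylo"))
  nt <- length(phy$tip.label)
  if (nt < 2L) stop("need at least 2 leaves")
  ntot <- nt + phy$Nnode
  depth <- rep(NA_real_, ntot)
  root <- setdiff(unique(phy$edge[, 1]), phy$edge[, 2])[1]
  depth[root] <- 0
  e <- phy$edge[order(phy$edge[, 1]), , drop = FALSE]
  # edges sorted by parent do not guarantee parent-before-child; iterate until set
  repeat {
    done <- TRUE
    for (i in seq_len(nrow(e))) {
      if (is.na(depth[e[i, 2]])) {
        if (is.na(depth[e[i, 1]])) done <- FALSE
        else depth[e[i, 2]] <- depth[e[i, 1]] + 1
      }
    }
    if (done || !anyNA(depth[unique(as.vector(e))])) break
  }
  counts <- depth[seq_len(nt)] - if (root_inclusive) 0 else 1
  counts[counts < 0] <- 0   # leaf attached directly at the root
  m <- max(counts)
  nd <- if (m == 0) {
    warning("degenerate tree: all leaves attach at the root; nd set to 0")
    counts
  } else counts / m
  names(nd) <- phy$tip.label
  nd
}

#' Fit the linear molecular clock of domain structures
#'
#' Ordinary least squares of `nd` (response) on geological age in Ga
#' (predictor), as used to calibrate fold-superfamily ages against the
#' geological record.
#'
#' @param calibrations data frame with columns `age_ga` and `nd` (an optional
#'   `fsf_id` column is carried along).
#' @return list of class `clock_model`: `slope` (nd per Ga), `intercept`,
#'   `r2` (squared Pearson correlation), `n`, and the underlying `lm` fit.
#' @export
fit_clock <- function(calibrations) {
  calibrations <- as.data.frame(calibrations)
  stopifnot(all(c("age_ga", "nd") %in% names(calibrations)))
  if (nrow(calibrations) < 2L || length(unique(calibrations$age_ga)) < 2L)
    stop("need at least 2 calibration points with distinct ages")
  fit <- lm(nd ~ age_ga, data = calibrations)
  r2 <- stats::cor(calibrations$age_ga, calibrations$nd)^2
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r2 = r2, n = nrow(calibrations), fit = fit),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("Molecular clock: nd = %.4g * age + %.4g (R2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Convert a node distance to a geological age
#'
#' Inverts the fitted clock: `age = (nd - intercept) / slope`, in Ga before
#' present.
#'
#' @param nd numeric vector of node distances.
#' @param model a `clock_model`, or a list with `slope` and `intercept` (e.g.
#'   published coefficients used as inputs).
#' @return numeric vector of ages in Ga.
#' @export
nd_to_age <- function(nd, model) {
  (nd - model$intercept) / model$slope
}

#' Read a clock calibration table
#'
#' TSV with columns `fsf_id`, `nd`, `age_ga` (header required).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_calibrations <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
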