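#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` when drawing `n` items without replacement from a population of
#' `N` containing `M` successes. This is the enrichment P value: the chance of
#' observing at least `k` members of a functional sub-category in the sample.
#' Computed with the log-stable exact tail; the point mass `P(X = k)` is
#' exposed separately as [hypergeom_point()].
#'
#' @param N population size.
#' @param M number of successes in the population.
#' @param n sample size.
#' @param k observed successes in the sample.
#' @return the tail probability, in `(0, 1]` (1 when `k = 0`).
#' @export
hypergeom_tail <- function(N, M, n, k) {
  stopifnot(M >= 0, M <= N, n >= 0, n <= N, k >= 0)
  if (k > min(n, M)) stop("k cannot exceed min(n, M)")
  phyper(k - 1, M, N - M, n, lower.tail = FALSE)
}

#' @rdname hypergeom_tail
#' @export
hypergeom_point <- function(N, M, n, k) {
  stopifnot(M >= 0, M <= N, n >= 0, n <= N, k >= 0, k <= min(n, M))
  dhyper(k, M, N - M, n)
}

#' Read a coarse-grained FSF function map
#'
#' TSV with columns `fsf_id`, `category`, `subcategory` (the Vogel-Chothia
#' style scheme: 7 major categories, ~50 sub-categories, one sub-category per
#' FSF; `"not annotated"` marks FSFs excluded from testing).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_function_map <- function(path) {
  fm <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("fsf_id", "category", "subcategory") %in% names(fm)))
  if (anyDuplicated(fm$fsf_id)) stop("an FSF maps to more than one subcategory")
  fm
}

.annotated <- function(fmap) fmap[fmap$subcategory != "not annotated", , drop = FALSE]

#' Functional enrichment of an FSF set by the hypergeometric test
#'
#' For every sub-category with at least one member in the sample, reports the
#' counts `k` (sample), `n` (annotated sample size), `M` (background count),
#' `N` (annotated background size), the two rates and their ratio, and, for
#' sub-categories over-represented in the sample (`k/n > M/N`), the
#' hypergeometric upper-tail P value. Unannotated FSFs are excluded from both
#' `n` and `N`. No multiple-testing correction is applied by default (raw
#' `P < alpha`); `adjust = "BH"` switches on Benjamini-Hochberg.
#'
#' @param sample character vector of FSF ids, subset of `background`.
#' @param background character vector of FSF ids (the extant universe).
#' @param fmap function map data frame (see [read_function_map()]).
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data frame sorted by P value, one row per sub-category present in
#'   the sample.
#' @export
enrich <- function(sample, background, fmap, alpha = 0.05,
                   adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!all(sample %in% background)) stop("sample must be a subset of background")
  fmap <- .annotated(fmap)
  bk <- intersect(background, fmap$fsf_id)
  sm <- intersect(sample, bk)
  N <- length(bk)
  n <- length(sm)
  sub_of <- setNames(fmap$subcategory, fmap$fsf_id)
  cat_of <- setNames(fmap$category, fmap$fsf_id)
  ks <- table(sub_of[sm])
  out <- do.call(rbind, lapply(names(ks), function(sc) {
    k <- as.integer(ks[[sc]])
    M <- sum(sub_of[bk] == sc)
    tested <- (k / n) > (M / N)
    data.frame(subcategory = sc,
               category = cat_of[names(which(sub_of == sc))[1]],
               k = k, n = n, M = M, N = N,
               rate_sample = k / n, rate_bkgd = M / N,
               ratio = (k / n) / (M / N),
               p = if (tested) hypergeom_tail(N, M, n, k) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (adjust == "BH") {
    tested <- !is.na(out$p)
    out$p[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  }
  out$significant <- !is.na(out$p) & out$p < alpha
  rownames(out) <- NULL
  out[order(out$p, -out$ratio), , drop = FALSE]
}

#' Character matrix of functional sub-categories
#'
#' Pools FSFs by sub-category: the raw cell value for (sub-category, proteome)
#' is the number of distinct FSFs of that sub-category present in the
#' proteome, then the matrix is recoded exactly like an abundance matrix, so
#' the character states describe numbers of functional sub-category members.
#'
#' @param m an `abundance_matrix`.
#' @param fmap function map data frame.
#' @param ... passed to [recode_abundance()].
#' @return a `char_matrix` with proteomes as taxa and sub-categories as
#'   characters; the raw counts are in attribute `raw`.
#' @export
function_character_matrix <- function(m, fmap, ...) {
  stopifnot(inherits(m, "abundance_matrix"))
  fmap <- .annotated(fmap)
  fsfs <- intersect(rownames(m$g), fmap$fsf_id)
  if (!length(fsfs)) stop("no annotated FSFs in the matrix")
  sub <- factor(fmap$subcategory[match(fsfs, fmap$fsf_id)])
  present <- (m$g[fsfs, , drop = FALSE] > 0L) * 1L
  counts <- rowsum(present, sub)
  counts <- matrix(as.integer(counts), nrow(counts), dimnames = dimnames(counts))
  fm <- abundance_matrix(counts, m$meta)
  out <- recode_abundance(fm, ...)
  attr(out, "raw") <- counts
  out
}

#' Functional diversity per proteome
#'
#' Number of distinct annotated sub-categories represented in each proteome.
#'
#' @param m an `abundance_matrix`.
#' @param fmap function map data frame.
#' @return named integer vector, one count per proteome.
#' @export
function_diversity <- function(m, fmap) {
  stopifnot(inherits(m, "abundance_matrix"))
  fmap <- .annotated(fmap)
  fsfs <- intersect(rownames(m$g), fmap$fsf_id)
  sub <- fmap$subcategory[match(fsfs, fmap$fsf_id)]
  vapply(colnames(m$g), function(p) {
    length(unique(sub[m$g[fsfs, p] > 0L]))
  }, integer(1))
}
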