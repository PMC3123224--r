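#' Abundance matrix of fold superfamilies across proteomes
#'
#' Container for a genomic census: the count `g[a, b]` of domain assignments of
#' FSF `a` in proteome `b`, together with per-proteome metadata (superkingdom
#' and lifestyle).
#'
#' @param g integer matrix, rows named by FSF id, columns by proteome id; all
#'   counts must be non-negative.
#' @param meta data frame with columns `proteome_id`, `superkingdom` (one of
#'   `"A"`, `"B"`, `"E"`) and `lifestyle` (one of `"FL"`, `"parasitic"`,
#'   `"obligate"`), one row per column of `g`.
#' @return an object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(g, meta) {
  g <- as.matrix(g)
  storage.mode(g) <- "integer"
  if (is.null(rownames(g)) || is.null(colnames(g)))
    stop("g must have FSF row names and proteome column names")
  if (anyDuplicated(rownames(g)) || anyDuplicated(colnames(g)))
    stop("duplicate FSF or proteome ids")
  if (any(is.na(g)) || any(g < 0)) stop("g counts must be non-negative integers")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("proteome_id", "superkingdom", "lifestyle")
  if (!all(need %in% names(meta))) stop("meta needs columns ", paste(need, collapse = ", "))
  if (!setequal(meta$proteome_id, colnames(g)) || anyDuplicated(meta$proteome_id))
    stop("meta must have exactly one row per proteome in g")
  if (!all(meta$superkingdom %in% c("A", "B", "E")))
    stop("superkingdom must be A, B or E")
  if (!all(meta$lifestyle %in% c("FL", "parasitic", "obligate")))
    stop("lifestyle must be FL, parasitic or obligate")
  meta <- meta[match(colnames(g), meta$proteome_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(g = g, meta = meta), class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("Abundance matrix:", nrow(x$g), "FSFs x", ncol(x$g), "proteomes\n")
  cat("  superkingdoms:", paste(sprintf("%s=%d", names(table(x$meta$superkingdom)),
                                        table(x$meta$superkingdom)), collapse = " "), "\n")
  cat("  total assignments:", sum(x$g), " g_max:", max(x$g), "\n")
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$g)

ccs_pattern <- "^[a-z]\\.[0-9]+\\.[0-9]+(\\.[0-9]+)?$"

#' Extract the FSF identifier from a SCOP concise classification string
#'
#' The FSF id is the first three dot-separated fields of a ccs, e.g.
#' `"c.37.1.12"` (a fold family) belongs to FSF `"c.37.1"`.
#'
#' @param ccs character vector of concise classification strings.
#' @return character vector of three-field FSF ids.
#' @export
ccs_to_fsf <- function(ccs) {
  bad <- !grepl(ccs_pattern, ccs)
  if (any(bad))
    stop("malformed ccs: ", paste(utils::head(ccs[bad], 5), collapse = ", "))
  sub("^([a-z]\\.[0-9]+\\.[0-9]+).*$", "\\1", ccs)
}

#' Read a SUPERFAMILY-style domain-assignment table into an abundance matrix
#'
#' The table is tab-separated with at least four columns: proteome id, protein
#' id, SCOP concise classification string, and HMM E-value. A header line is
#' optional (detected by a non-numeric fourth field) and lines starting with
#' `#` are skipped; extra columns are ignored. Each assignment row surviving
#' the E-value cutoff contributes one count to `g[FSF, proteome]` (abundance,
#' not mere occurrence), with fold families collapsed to their parent FSF.
#'
#' @param path path to the TSV file.
#' @param evalue_cutoff keep rows with E-value `<=` this cutoff (default `1e-4`,
#'   the conventional threshold for reliable HMM hits).
#' @param meta optional metadata data frame (see [abundance_matrix()]); if
#'   omitted, all proteomes are labelled free-living bacteria, which is only
#'   suitable for format round-trips.
#' @return an `abundance_matrix`.
#' @export
read_assignments <- function(path, evalue_cutoff = 1e-4, meta = NULL) {
  stopifnot(evalue_cutoff > 0)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (!length(fields)) stop("no assignment rows in ", path)
  if (any(lengths(fields) < 4))
    stop("line ", lineno[which(lengths(fields) < 4)[1]], ": fewer than 4 columns")
  tab <- data.frame(proteome_id = vapply(fields, `[[`, "", 1),
                    protein_id  = vapply(fields, `[[`, "", 2),
                    ccs         = vapply(fields, `[[`, "", 3),
                    evalue      = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4))),
                    line        = lineno, stringsAsFactors = FALSE)
  if (is.na(tab$evalue[1]) && nrow(tab) > 1) tab <- tab[-1, , drop = FALSE]  # header
  if (anyNA(tab$evalue))
    stop("line ", tab$line[which(is.na(tab$evalue))[1]], ": E-value is not numeric")
  bad <- !grepl(ccs_pattern, tab$ccs)
  if (any(bad))
    stop("line ", tab$line[which(bad)[1]], ": malformed ccs '", tab$ccs[which(bad)[1]], "'")
  tab <- tab[tab$evalue <= evalue_cutoff, , drop = FALSE]
  if (!nrow(tab))
    stop("no assignments at E-value cutoff ", evalue_cutoff, ": empty matrix")
  fsf <- ccs_to_fsf(tab$ccs)
  g <- table(factor(fsf), factor(tab$proteome_id))
  g <- matrix(as.integer(g), nrow = nrow(g),
              dimnames = list(rownames(g), colnames(g)))
  if (is.null(meta))
    meta <- data.frame(proteome_id = colnames(g), superkingdom = "B",
                       lifestyle = "FL", stringsAsFactors = FALSE)
  abundance_matrix(g, meta[meta$proteome_id %in% colnames(g), , drop = FALSE])
}

#' Read a proteome metadata table
#'
#' TSV with columns `proteome_id`, `superkingdom`, `lifestyle` (header
#' required; `#` comments allowed).
#'
#' @param path path to the TSV file.
#' @return a data frame suitable for [abundance_matrix()].
#' @export
read_proteome_meta <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Filter proteomes by lifestyle, optionally balancing superkingdom sampling
#'
#' Removes proteomes whose lifestyle is outside `keep_lifestyles` and drops
#' FSF rows left with all-zero counts (reported in attribute `dropped_fsfs`).
#' With `balanced`, the same number of proteomes is drawn at random from each
#' superkingdom, reproducibly under `seed`.
#'
#' @param m an `abundance_matrix`.
#' @param keep_lifestyles character vector of lifestyles to keep
#'   (default free-living only).
#' @param balanced optional integer: per-superkingdom sample size.
#' @param seed integer seed used for balanced sampling.
#' @return filtered `abundance_matrix` with attribute `dropped_fsfs`.
#' @export
filter_proteomes <- function(m, keep_lifestyles = "FL", balanced = NULL, seed = 1L) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (!all(keep_lifestyles %in% c("FL", "parasitic", "obligate")))
    stop("invalid lifestyle in keep_lifestyles")
  keep <- m$meta$lifestyle %in% keep_lifestyles
  meta <- m$meta[keep, , drop = FALSE]
  if (!nrow(meta)) stop("no proteomes left after lifestyle filtering")
  if (!is.null(balanced)) {
    balanced <- as.integer(balanced)
    sel <- withr::with_seed(seed, {
      unlist(lapply(sort(unique(meta$superkingdom)), function(k) {
        ids <- meta$proteome_id[meta$superkingdom == k]
        if (length(ids) < balanced)
          stop("superkingdom ", k, " has only ", length(ids),
               " proteomes, cannot sample ", balanced)
        sort(sample(ids, balanced))
      }))
    })
    meta <- meta[meta$proteome_id %in% sel, , drop = FALSE]
  }
  g <- m$g[, meta$proteome_id, drop = FALSE]
  zero <- rowSums(g) == 0L
  out <- abundance_matrix(g[!zero, , drop = FALSE], meta)
  attr(out, "dropped_fsfs") <- rownames(g)[zero]
  out
}
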