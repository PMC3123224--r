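#' Write a character matrix to a PAUP*-compatible NEXUS file
#'
#' Emits a `DATA` block with `SYMBOLS="0~9A~N"` and an `ASSUMPTIONS` block
#' declaring all characters ordered, so the file can be analysed with Wagner
#' parsimony in PAUP* directly.
#'
#' @param cm a `char_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(cm, path) {
  stopifnot(inherits(cm, "char_matrix"))
  st <- cm$state
  rows <- apply(st, 1, function(s) paste(encode_states(s, cm$n_states), collapse = ""))
  tax <- rownames(st)
  if (any(grepl("[ \t\\(\\);,\\[\\]']", tax))) tax <- sprintf("'%s'", tax)
  sym <- if (cm$n_states > 10L) "0~9A~N" else paste(cm$symbols, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    sprintf("[ polarity: %s ]", cm$polarity),
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(st), ncol(st)),
    sprintf("  FORMAT SYMBOLS=\"%s\" MISSING=? GAP=-;", sym),
    "  MATRIX",
    sprintf("    %-*s  %s", max(nchar(tax)), tax, rows),
    "  ;",
    "END;",
    "BEGIN ASSUMPTIONS;",
    sprintf("  TYPESET * default = ord: 1-%d;", ncol(st)),
    "END;",
    sprintf("[ characters: %s ]", paste(colnames(st), collapse = " "))
  ), con)
  invisible(path)
}

#' Read a character matrix written by [write_nexus()]
#'
#' Parses the NEXUS dialect this package writes (single DATA block, one taxon
#' per line, alphanumeric state symbols, polarity and character ids carried in
#' comments).
#'
#' @param path NEXUS file path.
#' @return a `char_matrix`.
#' @export
read_nexus <- function(path) {
  lines <- readLines(path)
  if (!grepl("^#NEXUS", lines[1])) stop("not a NEXUS file: ", path)
  pol <- if (any(grepl("polarity: max_ancestral", lines))) "max_ancestral" else "zero_ancestral"
  dims <- grep("DIMENSIONS", lines, value = TRUE)[1]
  ntax <- as.integer(sub(".*NTAX=([0-9]+).*", "\\1", dims))
  nchr <- as.integer(sub(".*NCHAR=([0-9]+).*", "\\1", dims))
  i <- grep("^\\s*MATRIX\\s*$", lines)[1]
  body <- lines[(i + 1):(i + ntax)]
  body <- trimws(body)
  tax <- sub("^'?([^' ]+)'?\\s+.*$", "\\1", body)
  rows <- sub("^.*\\s+(\\S+)$", "\\1", body)
  if (any(nchar(rows) != nchr)) stop("matrix row width does not match NCHAR")
  n_states <- if (any(grepl("0~9A~N", lines))) 24L else
    max(decode_states(unique(unlist(strsplit(rows, ""))))) + 1L
  n_states <- max(n_states, 2L)
  st <- t(vapply(strsplit(rows, ""), decode_states, integer(nchr),
                 n_states = n_states))
  chars <- grep("^\\[ characters:", lines, value = TRUE)
  cn <- if (length(chars)) {
    strsplit(sub("^\\[ characters: (.*) \\]$", "\\1", chars[1]), " ")[[1]]
  } else sprintf("char%d", seq_len(nchr))
  dimnames(st) <- list(tax, cn)
  char_matrix(st, pol, n_states)
}

#' Write a character matrix as relaxed PHYLIP or TSV
#'
#' @param cm a `char_matrix`.
#' @param path output file path.
#' @param format `"phylip"` (relaxed names, encoded symbols) or `"tsv"`
#'   (integer states, header row of character ids).
#' @return `path`, invisibly.
#' @export
write_char_matrix <- function(cm, path, format = c("phylip", "tsv")) {
  stopifnot(inherits(cm, "char_matrix"))
  format <- match.arg(format)
  if (format == "phylip") {
    rows <- apply(cm$state, 1, function(s) paste(encode_states(s, cm$n_states), collapse = ""))
    writeLines(c(sprintf("%d %d", nrow(cm$state), ncol(cm$state)),
                 sprintf("%s  %s", rownames(cm$state), rows)), path)
  } else {
    df <- data.frame(taxon = rownames(cm$state), cm$state, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write trees in Newick format
#'
#' Thin wrappers over [ape::read.tree()] and [ape::write.tree()] so pipeline
#' artifacts use a single entry point.
#'
#' @param path file path.
#' @param tree an `ape::phylo` object (or a `lundberg_tree`, whose topology is
#'   written).
#' @return `read_tree`: a `phylo`; `write_tree`: `path`, invisibly.
#' @export
read_tree <- function(path) ape::read.tree(path)

#' @rdname read_tree
#' @export
write_tree <- function(tree, path) {
  if (inherits(tree, "lundberg_tree")) tree <- tree$phy
  ape::write.tree(tree, file = path)
  invisible(path)
}
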