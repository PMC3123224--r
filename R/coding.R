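#' Ordered character-state matrix
#'
#' Holds recoded abundance states on the 0..(n_states-1) scale (24 states by
#' default, written with the alphanumeric symbols `0`-`9`, `A`-`N`), the taxa in
#' rows and the characters in columns, and the declared evolutionary polarity:
#' `"zero_ancestral"` (abundance grows from 0, used for trees of proteomes) or
#' `"max_ancestral"` (the maximum state is most ancient, used for trees of
#' domain structures).
#'
#' @param state integer matrix (taxa x characters) of states in
#'   `0:(n_states-1)`, with dimnames.
#' @param polarity `"zero_ancestral"` or `"max_ancestral"`.
#' @param n_states number of ordered states (2..24 with the bundled symbols).
#' @return an object of class `char_matrix`.
#' @export
char_matrix <- function(state, polarity = c("zero_ancestral", "max_ancestral"),
                        n_states = 24L) {
  polarity <- match.arg(polarity)
  state <- as.matrix(state)
  storage.mode(state) <- "integer"
  n_states <- as.integer(n_states)
  if (n_states < 2L || n_states > length(STATE_SYMBOLS))
    stop("n_states must be between 2 and ", length(STATE_SYMBOLS))
  if (is.null(rownames(state)) || is.null(colnames(state)))
    stop("state needs taxon row names and character column names")
  if (any(is.na(state)) || any(state < 0L) || any(state >= n_states))
    stop("states must lie in 0..", n_states - 1L)
  structure(list(state = state, polarity = polarity, n_states = n_states,
                 symbols = STATE_SYMBOLS[seq_len(n_states)]),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("Character matrix:", nrow(x$state), "taxa x", ncol(x$state),
      "characters;", x$n_states, "ordered states; polarity", x$polarity, "\n")
  invisible(x)
}

#' @export
dim.char_matrix <- function(x) dim(x$state)

#' Round half away from zero
#'
#' Fixed tie-breaking rule used by the recoding formula; base `round()` rounds
#' half to even, which would silently change matrices.
#'
#' @param x numeric vector.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Recode genomic abundance into ordered character states
#'
#' Normalizes each count relative to the matrix maximum and standardizes it to
#' a 0..(n_states-1) scale: `state = round(g / g_max * (n_states - 1))` for the
#' linear scale, or `round(log(g + 1) / log(g_max + 1) * (n_states - 1))` for
#' the log scale. Rounding is half away from zero. Taxa of the resulting
#' matrix are proteomes and characters are FSFs, with polarity
#' `"zero_ancestral"` (absence is the ancestral condition).
#'
#' @param m an `abundance_matrix`.
#' @param n_states number of ordered states (default 24).
#' @param scale `"linear"` (default) or `"log"`.
#' @param per_character normalize by each character's own maximum instead of
#'   the matrix-wide maximum (sensitivity analysis only).
#' @return a `char_matrix` with proteomes as taxa.
#' @export
recode_abundance <- function(m, n_states = 24L, scale = c("linear", "log"),
                             per_character = FALSE) {
  stopifnot(inherits(m, "abundance_matrix"))
  scale <- match.arg(scale)
  g <- t(m$g)  # taxa (proteomes) x characters (FSFs)
  if (!length(g) || max(g) == 0L) stop("empty abundance matrix: g_max is 0")
  n_states <- as.integer(n_states)
  stopifnot(n_states >= 2L)
  gmax <- if (per_character) rep(apply(g, 2, max), each = nrow(g)) else max(g)
  st <- if (scale == "linear") {
    round_half_up(g / gmax * (n_states - 1L))
  } else {
    round_half_up(log(g + 1) / log(gmax + 1) * (n_states - 1L))
  }
  st[g == 0L] <- 0
  char_matrix(matrix(as.integer(st), nrow(g), ncol(g), dimnames = dimnames(g)),
              "zero_ancestral", n_states)
}

#' Transpose a character matrix to build trees of domain structures
#'
#' Swaps taxa and characters so that FSFs become the taxa and proteomes the
#' characters, and flips the polarity to `"max_ancestral"`: on the structure
#' tree the maximum state is the most ancient condition, because ancient, widely
#' reused domains are the most abundant.
#'
#' @param cm a `char_matrix`.
#' @return the transposed `char_matrix`.
#' @export
transpose_for_structure_tree <- function(cm) {
  stopifnot(inherits(cm, "char_matrix"))
  pol <- if (cm$polarity == "zero_ancestral") "max_ancestral" else "zero_ancestral"
  char_matrix(t(cm$state), pol, cm$n_states)
}

#' Encode / decode states with the 0-9, A-N alphanumeric symbols
#'
#' @param states integer vector of states.
#' @param n_states number of states in the encoding.
#' @return `encode_states`: character vector of single symbols;
#'   `decode_states`: integer vector of states.
#' @export
encode_states <- function(states, n_states = 24L) {
  if (any(states < 0L | states >= n_states))
    stop("state outside 0..", n_states - 1L, ": cannot encode")
  STATE_SYMBOLS[states + 1L]
}

#' @rdname encode_states
#' @param symbols character vector of single symbols.
#' @export
decode_states <- function(symbols, n_states = 24L) {
  idx <- match(symbols, STATE_SYMBOLS[seq_len(n_states)])
  if (anyNA(idx)) stop("unknown state symbol: ", symbols[which(is.na(idx))[1]])
  idx - 1L
}
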