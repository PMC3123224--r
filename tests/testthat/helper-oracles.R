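# Independent brute-force oracles and small fixture builders used across tests.

# Minimal cost of one ordered character on a topology by exhaustive enumeration
# of every internal-node state assignment (optionally with a fixed-state
# hypothetical ancestor attached above the root).
brute_force_char_length <- function(tree, tip_states, S, anc = NULL) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
  grid <- as.matrix(expand.grid(rep(list(0:(S - 1)), nn)))
  vals <- cbind(matrix(rep(tip_states[tree$tip.label], each = nrow(grid)),
                       nrow(grid)), grid)
  lens <- rowSums(abs(vals[, tree$edge[, 1], drop = FALSE] -
                        vals[, tree$edge[, 2], drop = FALSE]))
  if (!is.null(anc)) lens <- lens + abs(vals[, root] - anc)
  min(lens)
}

# The set of root states achieving the optimum (for MPR interval checks).
brute_force_root_states <- function(tree, tip_states, S, anc = NULL,
                                    node = NULL) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
  if (is.null(node)) node <- root
  grid <- as.matrix(expand.grid(rep(list(0:(S - 1)), nn)))
  vals <- cbind(matrix(rep(tip_states[tree$tip.label], each = nrow(grid)),
                       nrow(grid)), grid)
  lens <- rowSums(abs(vals[, tree$edge[, 1], drop = FALSE] -
                        vals[, tree$edge[, 2], drop = FALSE]))
  if (!is.null(anc)) lens <- lens + abs(vals[, root] - anc)
  sort(unique(vals[lens == min(lens), node]))
}

# random ordered character matrix
random_cm <- function(n_taxa, n_char, S, seed,
                      polarity = "zero_ancestral", taxa = NULL) {
  withr::with_seed(seed, {
    if (is.null(taxa)) taxa <- sprintf("t%02d", seq_len(n_taxa))
    st <- matrix(sample(0:(S - 1L), n_taxa * n_char, replace = TRUE),
                 n_taxa, n_char,
                 dimnames = list(taxa, sprintf("c%02d", seq_len(n_char))))
    char_matrix(st, polarity, S)
  })
}

# abundance matrix spanning the three superkingdoms, built by hand
toy_census <- function(g, sk = NULL, lifestyle = NULL) {
  if (is.null(sk)) sk <- substr(colnames(g), 1, 1)
  if (is.null(lifestyle)) lifestyle <- rep("FL", ncol(g))
  abundance_matrix(g, data.frame(proteome_id = colnames(g),
                                 superkingdom = sk, lifestyle = lifestyle,
                                 stringsAsFactors = FALSE))
}

newick <- function(txt) ape::read.tree(text = txt)

# background universe of 1416 annotated FSFs with sub-category counts laid out
# to match the published enrichment table, plus samples with the published k
enrich_fixture <- function() {
  ids <- sprintf("f%04d", 1:1416)
  sub <- rep("other enzymes", 1416)
  sub[1:29] <- "transferases"
  sub[30:51] <- "small molecule binding"
  sub[52:80] <- "nucleotide m/tr"
  sub[81:169] <- "translation"
  cat_of <- c("transferases" = "Metabolism", "small molecule binding" = "General",
              "nucleotide m/tr" = "Metabolism", "translation" = "Information",
              "other enzymes" = "Metabolism")
  fmap <- data.frame(fsf_id = ids, category = cat_of[sub], subcategory = sub,
                     stringsAsFactors = FALSE)
  min_like <- c(ids[1:6],      # 6 transferases
                ids[30:33],    # 4 small molecule binding
                ids[52:58],    # 7 nucleotide m/tr
                ids[200:252])  # 53 fillers -> n = 70
  max_like <- c(ids[52:59],    # 8 nucleotide m/tr
                ids[81:114],   # 34 translation
                ids[300:409])  # 110 fillers -> n = 152
  list(fmap = fmap, ids = ids, min_like = min_like, max_like = max_like)
}
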