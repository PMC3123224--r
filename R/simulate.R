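#' Simulate a fold-superfamily census with known ground truth
#'
#' Generates a proteome x FSF abundance matrix by evolving domain counts along
#' a guide tree with three superkingdom clades (Archaea, Bacteria, Eukarya).
#' Ancestral FSFs are implanted at the root and inherited by every lineage;
#' derived FSFs are born on internal branches and confined to their subtree
#' (absent horizontal transfer). Abundance grows by per-branch geometric
#' duplication (each copy duplicates with probability `duplication_rate` per
#' branch step), matching the assumption that ancient domains are the most
#' abundant and widespread. Losses zero an FSF in a subtree; horizontal
#' transfer copies a derived FSF into a lineage outside its birth clade.
#' Fully reproducible under `seed`.
#'
#' @param n_per_superkingdom proteomes per superkingdom clade.
#' @param n_ancestral number of FSFs implanted at the root (the ground-truth
#'   urancestral set).
#' @param n_derived number of FSFs born on internal branches.
#' @param duplication_rate mean per-copy, per-branch duplication probability.
#'   Each FSF draws its own rate from a gamma distribution with this mean
#'   (shape `rate_shape`), giving the heavy-tailed abundance spread of real
#'   censuses, where a few superfamilies dominate the matrix maximum.
#' @param rate_shape gamma shape of the per-FSF duplication-rate mixture
#'   (smaller = heavier tail).
#' @param loss_prob per-branch probability that a present FSF is lost in the
#'   subtree below.
#' @param hgt_rate probability that a derived FSF undergoes one horizontal
#'   transfer event.
#' @param tree_shape guide-tree shape within each clade.
#' @param init_abundance root copy number of ancestral FSFs.
#' @param seed integer seed.
#' @return list of class `census_sim`: `abundance` (an `abundance_matrix`),
#'   and `truth` with the guide tree, implanted ancestral ids, per-FSF birth
#'   edges, loss and HGT event tables.
#' @export
simulate_census <- function(n_per_superkingdom = 10L, n_ancestral = 40L,
                            n_derived = 260L, duplication_rate = 0.1,
                            rate_shape = 0.7, loss_prob = 0.02, hgt_rate = 0,
                            tree_shape = c("random", "ladder", "balanced"),
                            init_abundance = 2L, seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  stopifnot(n_per_superkingdom >= 1L, n_ancestral >= 1L,
            duplication_rate >= 0, duplication_rate <= 1,
            loss_prob >= 0, loss_prob <= 1, hgt_rate >= 0, hgt_rate <= 1)
  withr::with_seed(seed, {
    phy <- ape::reorder.phylo(.guide_tree(n_per_superkingdom, tree_shape),
                              "cladewise")
    nt <- length(phy$tip.label)
    nf <- n_ancestral + n_derived
    fsf_ids <- .synthetic_fsf_ids(nf)
    ancestral <- fsf_ids[seq_len(n_ancestral)]
    derived <- setdiff(fsf_ids, ancestral)
    dup_rate <- if (duplication_rate > 0)
      pmin(1, stats::rgamma(nf, shape = rate_shape,
                            rate = rate_shape / duplication_rate))
      else rep(0, nf)

    e <- phy$edge                                    # parents before children
    internal_edges <- which(e[, 2] > nt)
    birth_edge <- if (n_derived)
      sample(internal_edges, n_derived, replace = TRUE) else integer(0)
    births_on <- split(which(fsf_ids %in% derived), birth_edge)

    hgt <- data.frame(fsf = character(0), edge = integer(0))
    if (hgt_rate > 0 && n_derived) {
      moved <- derived[runif(n_derived) < hgt_rate]
      if (length(moved))
        hgt <- data.frame(fsf = moved,
                          edge = sample(internal_edges, length(moved),
                                        replace = TRUE))
    }
    arrivals <- split(match(hgt$fsf, fsf_ids), hgt$edge)

    counts <- vector("list", nt + phy$Nnode)
    root <- setdiff(unique(e[, 1]), e[, 2])[1]
    counts[[root]] <- ifelse(fsf_ids %in% ancestral, as.integer(init_abundance), 0L)
    losses <- list()
    for (i in seq_len(nrow(e))) {
      vec <- counts[[e[i, 1]]]
      present <- vec > 0L
      lost <- present & runif(nf) < loss_prob
      if (any(lost))
        losses[[length(losses) + 1L]] <- data.frame(fsf = fsf_ids[lost], edge = i)
      vec[lost] <- 0L
      alive <- vec > 0L
      vec[alive] <- vec[alive] + rbinom(sum(alive), vec[alive], dup_rate[alive])
      key <- as.character(i)
      if (!is.null(births_on[[key]])) vec[births_on[[key]]] <- 1L
      if (!is.null(arrivals[[key]])) vec[arrivals[[key]]] <- pmax(vec[arrivals[[key]]], 1L)
      counts[[e[i, 2]]] <- vec
    }
    g <- vapply(seq_len(nt), function(tip) counts[[tip]], integer(nf))
    dimnames(g) <- list(fsf_ids, phy$tip.label)
    meta <- data.frame(proteome_id = phy$tip.label,
                       superkingdom = substr(phy$tip.label, 1, 1),
                       lifestyle = "FL", stringsAsFactors = FALSE)
    structure(list(
      abundance = abundance_matrix(g, meta),
      truth = list(tree = phy, ancestral = ancestral, derived = derived,
                   birth_edge = setNames(birth_edge, derived),
                   losses = if (length(losses)) do.call(rbind, losses)
                            else data.frame(fsf = character(0), edge = integer(0)),
                   hgt = hgt),
      config = list(n_per_superkingdom = n_per_superkingdom,
                    n_ancestral = n_ancestral, n_derived = n_derived,
                    duplication_rate = duplication_rate,
                    rate_shape = rate_shape, loss_prob = loss_prob,
                    hgt_rate = hgt_rate, tree_shape = tree_shape,
                    init_abundance = init_abundance, seed = seed)),
      class = "census_sim")
  })
}

# three-clade guide tree (A, (B, E)), clades shaped per `shape`
.guide_tree <- function(n, shape) {
  clade <- function(prefix) {
    tips <- sprintf("%s%02d", prefix, seq_len(n))
    if (n == 1L) return(tips)
    nwk <- switch(shape,
      ladder = {
        s <- sprintf("(%s,%s)", tips[1], tips[2])
        for (t in tips[-(1:2)]) s <- sprintf("(%s,%s)", s, t)
        s
      },
      balanced = .balanced_newick(tips),
      random = {
        tr <- ape::rtree(n, tip.label = tips, br = NULL)
        sub(";$", "", ape::write.tree(tr))
      })
    nwk
  }
  txt <- sprintf("(%s,(%s,%s));", clade("A"), clade("B"), clade("E"))
  ape::read.tree(text = txt)
}

.balanced_newick <- function(tips) {
  if (length(tips) == 1L) return(tips)
  h <- ceiling(length(tips) / 2)
  sprintf("(%s,%s)", .balanced_newick(tips[seq_len(h)]),
          .balanced_newick(tips[-seq_len(h)]))
}

.synthetic_fsf_ids <- function(n) {
  cls <- letters[1:7]
  sprintf("%s.%d.1", cls[(seq_len(n) - 1L) %% 7L + 1L],
          (seq_len(n) - 1L) %/% 7L + 1L)
}

#' @export
print.census_sim <- function(x, ...) {
  cat("Simulated census:", nrow(x$abundance$g), "FSFs x", ncol(x$abundance$g),
      "proteomes;", length(x$truth$ancestral), "implanted ancestral FSFs\n")
  invisible(x)
}

#' Bundled synthetic fixtures
#'
#' `"tiny"` is a 9-proteome x 24-FSF census small enough for exhaustive
#' verification; `"paper_like"` is a 30-proteome x 300-FSF census with 40
#' implanted ancestral FSFs, lineage losses and light horizontal transfer,
#' sized for end-to-end recovery tests. Both are generated in code under
#' fixed seeds (they are datasets, not tuning knobs) and come with a
#' synthetic function map and clock calibration table.
#'
#' @param name `"tiny"` or `"paper_like"`.
#' @return list: `sim` (a `census_sim`), `fmap` (function map data frame),
#'   `calibrations` (data frame `fsf_id`, `nd`, `age_ga`).
#' @export
make_fixture <- function(name = c("tiny", "paper_like")) {
  name <- match.arg(name)
  sim <- switch(name,
    tiny = simulate_census(n_per_superkingdom = 3L, n_ancestral = 8L,
                           n_derived = 16L, duplication_rate = 0.15,
                           loss_prob = 0.02, hgt_rate = 0,
                           tree_shape = "random", seed = 101L),
    paper_like = simulate_census(n_per_superkingdom = 10L, n_ancestral = 40L,
                                 n_derived = 260L, duplication_rate = 0.1,
                                 loss_prob = 0.02, hgt_rate = 0.02,
                                 tree_shape = "random", seed = 42L))
  scheme <- read.delim(system.file("extdata", "function_scheme.tsv",
                                   package = "urproteome"),
                       stringsAsFactors = FALSE)
  fsfs <- rownames(sim$abundance$g)
  fmap <- withr::with_seed(7L, {
    sub <- sample(scheme$subcategory[scheme$subcategory != "not annotated"],
                  length(fsfs), replace = TRUE)
    sub[seq_len(min(2L, length(sub)))] <- "not annotated"
    data.frame(fsf_id = fsfs,
               category = scheme$category[match(sub, scheme$subcategory)],
               subcategory = sub, stringsAsFactors = FALSE)
  })
  calibrations <- withr::with_seed(11L, {
    age <- seq(3.6, 0.4, length.out = 12)
    data.frame(fsf_id = sprintf("calib%02d", seq_along(age)),
               nd = pmax(0, -0.25 * age + 0.9 + rnorm(length(age), 0, 0.02)),
               age_ga = age)
  })
  list(sim = sim, fmap = fmap, calibrations = calibrations)
}

#' Write a simulated census as assignment and metadata TSV files
#'
#' Expands the abundance matrix back into SUPERFAMILY-style assignment rows
#' (one row per domain count, E-value 1e-10) so the census reader can be
#' exercised end to end; also writes the metadata table and the ground truth
#' as JSON.
#'
#' @param sim a `census_sim`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_sim_tables <- function(sim, dir) {
  stopifnot(inherits(sim, "census_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- sim$abundance$g
  idx <- which(g > 0L, arr.ind = TRUE)
  rows <- do.call(rbind, lapply(seq_len(nrow(idx)), function(i) {
    k <- g[idx[i, 1], idx[i, 2]]
    data.frame(proteome_id = colnames(g)[idx[i, 2]],
               protein_id = sprintf("%s_p%d_%d", colnames(g)[idx[i, 2]],
                                    idx[i, 1], seq_len(k)),
               ccs = paste0(rownames(g)[idx[i, 1]], ".1"),
               evalue = 1e-10, stringsAsFactors = FALSE)
  }))
  af <- file.path(dir, "assignments.tsv")
  mf <- file.path(dir, "meta.tsv")
  tf <- file.path(dir, "truth.json")
  write.table(rows, af, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$abundance$meta, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(ancestral = sim$truth$ancestral,
                            derived = sim$truth$derived,
                            config = sim$config),
                       tf, auto_unbox = TRUE)
  invisible(c(assignments = af, meta = mf, truth = tf))
}
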