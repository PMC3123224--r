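#' Run the full urancestral-reconstruction pipeline
#'
#' Orchestrates the analysis end to end on an abundance census: recode to
#' ordered characters, build and root the tree of proteomes, extract the
#' initial root-branch (plesiomorphic) FSF set, refine it iteratively to the
#' `max_set`, build the tree of domain structures and its nd timeline, derive
#' the `basal_set` and intersect to the `min_set`, compute popularity indices,
#' test functional enrichment (when a function map is supplied), fit the
#' molecular clock (when calibrations are supplied), and re-place the
#' reconstructed urancestor as an artificial taxon. Deterministic given
#' `seed`.
#'
#' @param census an `abundance_matrix`, already lifestyle-filtered.
#' @param fmap optional function map (see [read_function_map()]).
#' @param calibrations optional calibration data frame (`fsf_id`, `nd`,
#'   `age_ga`).
#' @param out_dir optional directory; when given, trees (Newick), matrices
#'   (NEXUS), set lists, tables (TSV) and a JSON run manifest are written.
#' @param cfg a [search_config()] for the proteome-tree searches.
#' @param n_chains,n_iter refinement schedule (desk-scale defaults; the
#'   full-scale schedule is 30 chains of 50 iterations).
#' @param seed master seed for every stage.
#' @param inject re-place the reconstructed `min_set` urancestor as an
#'   artificial taxon and report its node distance (0 = basal).
#' @param ... passed to [recode_abundance()].
#' @return list of class `urproteome_run` with components `char_matrix`,
#'   `proteome_tree`, `set352`, `refinement`, `structure_tree`, `fsf_nd`,
#'   `occurrence`, `sets`, `popularity`, `enrichment`, `clock`,
#'   `urancestor_nd`, `seed`.
#' @export
run_all <- function(census, fmap = NULL, calibrations = NULL, out_dir = NULL,
                    cfg = search_config(), n_chains = 4L, n_iter = 10L,
                    seed = 1L, inject = TRUE, ...) {
  stopifnot(inherits(census, "abundance_matrix"))
  cm <- recode_abundance(census, ...)

  pcfg <- cfg
  pcfg$seed <- seed
  trees0 <- mp_search(cm, pcfg)
  rt0 <- lundberg_root(trees0, cm)
  set352 <- plesiomorphic_set(root_branch_changes(rt0, cm))$character

  ref <- run_refinement(cm, set352, n_chains = n_chains, n_iter = n_iter,
                        cfg = cfg, seed = seed)

  cms <- transpose_for_structure_tree(cm)
  scfg <- cfg
  scfg$seed <- seed + 555L
  scfg$n_addition_replicates <- 1L
  scfg$maxtrees <- 4L
  trees_s <- mp_search(cms, scfg)
  rts <- lundberg_root(trees_s, cms)
  fsf_nd <- compute_nd(rts)
  occ <- classify_occurrence(census)
  basal <- basal_set(fsf_nd, occ)
  sets <- urancestral_sets(set352, ref$max_set, basal)

  pop <- popularity(census)

  enr <- if (!is.null(fmap)) {
    bg <- rownames(census$g)
    list(max_set = enrich(sets$max_set, bg, fmap),
         min_set = enrich(sets$min_set, bg, fmap))
  }

  clock <- if (!is.null(calibrations)) {
    model <- fit_clock(calibrations)
    list(model = model,
         min_set_age = nd_to_age(max(fsf_nd[sets$min_set]), model),
         max_set_age = nd_to_age(max(fsf_nd[sets$max_set]), model))
  }

  ur_nd <- NULL
  if (inject && length(sets$min_set)) {
    icfg <- cfg
    icfg$seed <- seed + 777L
    cmi <- inject_urancestor(cm, sets$min_set)
    # graft the artificial taxon at its optimal attachment edge on the best
    # proteome tree, polish by NNI, and keep the better of graft vs de novo
    base <- trees0[[1]]
    st <- cm$state[base$tip.label, , drop = FALSE]
    lens <- lundberg_edge_lengths_cpp(base$edge, length(base$tip.label), st,
                                      cm$n_states,
                                      cmi$state["urancestor", ], TRUE)
    graft <- .nni_climb(.add_tip(base, which.min(lens), "urancestor"),
                        cmi, icfg$maxtrees, icfg$max_plateau)
    denovo <- mp_search(cmi, icfg)
    tri <- if (graft$length <= attr(denovo, "length"))
      graft$trees[[1]] else denovo[[1]]
    rti <- lundberg_root(tri, cmi)
    ur_nd <- compute_nd(rti)["urancestor"]
  } else rti <- NULL

  run <- structure(list(char_matrix = cm, proteome_tree = rt0,
                        set352 = sort(set352), refinement = ref,
                        structure_tree = rts, fsf_nd = fsf_nd,
                        occurrence = occ, sets = sets, popularity = pop,
                        enrichment = enr, clock = clock,
                        urancestor_nd = ur_nd, urancestor_tree = rti,
                        seed = seed),
                   class = "urproteome_run")
  if (!is.null(out_dir)) .write_run(run, census, out_dir)
  run
}

.write_run <- function(run, census, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_nexus(run$char_matrix, p("proteome_matrix.nex"))
  write_tree(run$proteome_tree, p("proteome_tree.nwk"))
  write_tree(run$structure_tree, p("structure_tree.nwk"))
  for (s in c("set352", "basal_set", "max_set", "min_set")) {
    ids <- if (s == "set352") run$set352 else run$sets[[s]]
    writeLines(ids, p(paste0(s, ".txt")))
  }
  write.table(run$popularity, p("popularity.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(fsf = names(run$fsf_nd), nd = run$fsf_nd),
              p("fsf_nd.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$enrichment)) {
    write.table(run$enrichment$max_set, p("enrichment_max_set.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(run$enrichment$min_set, p("enrichment_min_set.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(seed = run$seed,
                   n_proteomes = ncol(census$g), n_fsfs = nrow(census$g),
                   proteome_tree_length = run$proteome_tree$length,
                   structure_tree_length = run$structure_tree$length,
                   set_sizes = lapply(run$sets, length),
                   urancestor_nd = run$urancestor_nd,
                   clock = if (!is.null(run$clock))
                     list(slope = run$clock$model$slope,
                          intercept = run$clock$model$intercept,
                          r2 = run$clock$model$r2,
                          min_set_age = run$clock$min_set_age,
                          max_set_age = run$clock$max_set_age))
  jsonlite::write_json(manifest, p("run_manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.urproteome_run <- function(x, ...) {
  cat("Urancestral reconstruction run (seed", x$seed, ")\n")
  cat("  proteome tree:", length(x$proteome_tree$phy$tip.label), "taxa, length",
      x$proteome_tree$length, "\n")
  cat("  structure tree:", length(x$structure_tree$phy$tip.label),
      "taxa, length", x$structure_tree$length, "\n")
  print(x$sets)
  if (!is.null(x$urancestor_nd))
    cat("  injected urancestor nd:", unname(x$urancestor_nd), "\n")
  if (!is.null(x$clock))
    cat(sprintf("  clock ages: min_set %.2f Ga, max_set %.2f Ga\n",
                x$clock$min_set_age, x$clock$max_set_age))
  invisible(x)
}
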