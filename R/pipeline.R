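#' Assemble and validate a pipeline configuration
#'
#' Bundles the inputs and tuning parameters of the full analysis for one
#' kingdom (one table). Inputs may be in-memory objects or file paths
#' (TSV for table/metadata/taxonomy, Newick for the tree); paths are
#' checked at validation time.
#'
#' @param table a [feature_table()] or TSV path.
#' @param metadata optional metadata tibble or TSV path (ignored when
#'   `table` is a `feature_table` that already carries metadata).
#' @param taxonomy optional taxonomy tibble or TSV path; enables
#'   genus-level summaries.
#' @param tree optional [ape::phylo] or Newick path; required for
#'   assembly inference.
#' @param kingdom label used in output names and to pick the default
#'   stage map (`"bacteria"` or `"fungi"`).
#' @param stage_map day ranges per stage; default
#'   [default_stage_map()] for `kingdom`.
#' @param filter_threshold global frequency filter (default 5e-5).
#' @param rarity_low,rarity_high rarity thresholds (defaults 1e-4,
#'   1e-2).
#' @param rho_min,alpha,min_prevalence,p_adjust network parameters (see
#'   [build_network()], [spearman_matrix()]).
#' @param reps null-model replicates for betaNTI (default 999).
#' @param rc_reps replicates for Raup-Crick (default `reps`).
#' @param weighted abundance-weighted beta-MNTD (default `TRUE`).
#' @param permanova_perms label permutations for PERMANOVA
#'   (default 999).
#' @param run_assembly run the assembly stage? Defaults to `TRUE` when
#'   a tree is supplied.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(table, metadata = NULL, taxonomy = NULL,
                            tree = NULL, kingdom = "bacteria",
                            stage_map = NULL, filter_threshold = 5e-5,
                            rarity_low = 1e-4, rarity_high = 1e-2,
                            rho_min = 0.8, alpha = 0.05,
                            min_prevalence = 3, p_adjust = "none",
                            reps = 999, rc_reps = reps, weighted = TRUE,
                            permanova_perms = 999,
                            run_assembly = !is.null(tree)) {
  for (nm in c("table", "metadata", "taxonomy", "tree")) {
    v <- get(nm)
    if (is.character(v) && !file.exists(v)) {
      stop("config: `", nm, "` path does not exist: ", v, call. = FALSE)
    }
  }
  if (run_assembly && is.null(tree)) {
    stop("config: assembly enabled but `tree` is missing", call. = FALSE)
  }
  if (is.null(stage_map)) {
    stage_map <- default_stage_map(
      if (kingdom %in% c("bacteria", "fungi")) kingdom else "bacteria")
  }
  structure(list(
    table = table, metadata = metadata, taxonomy = taxonomy, tree = tree,
    kingdom = kingdom, stage_map = stage_map,
    filter_threshold = filter_threshold,
    rarity_low = rarity_low, rarity_high = rarity_high,
    rho_min = rho_min, alpha = alpha, min_prevalence = min_prevalence,
    p_adjust = p_adjust, reps = reps, rc_reps = rc_reps,
    weighted = weighted, permanova_perms = permanova_perms,
    run_assembly = run_assembly
  ), class = "pipeline_config")
}

resolve_inputs <- function(cfg) {
  md <- cfg$metadata
  if (is.character(md)) md <- read_sample_metadata(md)
  tab <- cfg$table
  if (is.character(tab)) tab <- read_feature_table(tab, metadata = md)
  else if (!is.null(md)) tab <- feature_table(tab$counts, metadata = md)
  if (!"stage" %in% names(tab$metadata) ||
      all(is.na(tab$metadata$stage))) {
    tab$metadata <- assign_stages(tab$metadata, cfg$stage_map)
  }
  tax <- cfg$taxonomy
  if (is.character(tax)) tax <- read_taxonomy(tax)
  tree <- cfg$tree
  if (is.character(tree)) tree <- read_phylogeny(tree)
  list(table = tab, taxonomy = tax, tree = tree)
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run the full analysis pipeline for one kingdom
#'
#' Executes, in order: frequency filter, rarity classification,
#' diversity (Shannon per rarity group, PCoA, PERMANOVA by stage),
#' per-stage co-occurrence networks over the abundant+rare features,
#' and (when a tree is configured) per-group assembly inference
#' (betaNTI + Raup-Crick + process fractions). All outputs are plain
#' TSV/JSON/GraphML files under `outdir`, prefixed with the kingdom
#' label, plus a run manifest with parameters, seed and artifact
#' checksums. Identical config and seed give byte-identical artifacts.
#' A failure in any stage aborts with the stage name.
#'
#' @param cfg a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param seed integer seed governing every stochastic step.
#' @return Invisibly, a tibble `artifact`, `path`, `md5`.
#' @export
run_pipeline <- function(cfg, outdir, seed = 1) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(outdir, paste0(cfg$kingdom, "_"))
  paths <- character(0)
  emit <- function(name, path) {
    paths[[name]] <<- path
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  inp <- stage("input", resolve_inputs(cfg))
  tab <- stage("filter", filter_min_frequency(inp$table,
                                              cfg$filter_threshold))
  emit("filtered_table", write_feature_table(tab, paste0(pre, "filtered_table.tsv")))

  # rarity ------------------------------------------------------------
  assignment <- stage("rarity",
                      classify_rarity(tab, cfg$rarity_low, cfg$rarity_high))
  readr::write_tsv(assignment, emit("rarity_assignment",
                                    paste0(pre, "rarity_assignment.tsv")))
  readr::write_tsv(rarity_counts(assignment),
                   emit("rarity_counts", paste0(pre, "rarity_counts.tsv")))
  fractions <- group_fractions(tab, assignment)
  readr::write_tsv(fractions, emit("group_fractions",
                                   paste0(pre, "group_fractions.tsv")))

  # diversity ----------------------------------------------------------
  stage("diversity", {
    alpha <- purrr::map_dfr(
      list(all = NULL, abundant = "abundant", rare = "rare"),
      function(g) {
        sub <- if (is.null(g)) tab else subset_group(tab, assignment, g)
        keep <- colSums(sub$counts) > 0
        if (!any(keep)) return(NULL)
        shannon_index(sub$counts[, keep, drop = FALSE])
      }, .id = "group")
    readr::write_tsv(alpha[, c("sample_id", "group", "shannon")],
                     emit("alpha_diversity",
                          paste0(pre, "alpha_diversity.tsv")))
    d <- bray_curtis(tab)
    ord <- pcoa_ordination(d)
    coords <- tidy(ord)
    readr::write_tsv(coords, emit("pcoa_coordinates",
                                  paste0(pre, "pcoa_coordinates.tsv")))
    pm <- permanova(d, tab$metadata$stage, n_perm = cfg$permanova_perms,
                    seed = seed + 1L)
    write_json_artifact(
      list(pseudo_f = pm$f, r2 = pm$r2, p_value = pm$p_value,
           n_perm = pm$n_perm, seed = seed + 1L, grouping = "stage"),
      emit("permanova", paste0(pre, "permanova.json")))
  })

  # per-stage networks -------------------------------------------------
  net_summaries <- list()
  stage("network", {
    ar <- subset_group(tab, assignment, c("abundant", "rare"))
    for (st in sort(unique(tab$metadata$stage))) {
      ss <- tab$metadata$sample_id[tab$metadata$stage == st]
      if (length(ss) < 4) {
        message("network: stage ", st, " has < 4 samples, skipped")
        next
      }
      sub <- subset_table(ar, samples = ss)
      sp <- spearman_matrix(sub, min_prevalence = cfg$min_prevalence)
      net <- build_network(sp, rho_min = cfg$rho_min, alpha = cfg$alpha,
                           assignment = assignment,
                           p_adjust = cfg$p_adjust)
      net <- detect_modules(net)
      metrics <- zipi(net)
      readr::write_tsv(net$edges,
                       emit(paste0("network_edges_", st),
                            paste0(pre, "network_edges_", st, ".tsv")))
      readr::write_tsv(metrics,
                       emit(paste0("network_nodes_", st),
                            paste0(pre, "network_nodes_", st, ".tsv")))
      write_network_graphml(net,
                            emit(paste0("network_graphml_", st),
                                 paste0(pre, "network_", st, ".graphml")),
                            node_metrics = metrics)
      net_summaries[[st]] <- as.list(network_summary(net, metrics))
    }
    write_json_artifact(net_summaries,
                        emit("network_summary",
                             paste0(pre, "network_summary.json")))
  })

  # per-group assembly --------------------------------------------------
  if (cfg$run_assembly) {
    stage("assembly", {
      g_idx <- 0L
      for (g in c("abundant", "rare")) {
        g_idx <- g_idx + 1L
        sub <- subset_group(tab, assignment, g)
        keep <- colSums(sub$counts) > 0
        sub <- subset_table(sub, samples = colnames(sub$counts)[keep])
        if (nrow(sub$counts) < 3 || ncol(sub$counts) < 3) {
          message("assembly: group ", g, " too small, skipped")
          next
        }
        bn <- beta_nti(sub, inp$tree, reps = cfg$reps,
                       weighted = cfg$weighted,
                       seed = seed + 10L + g_idx)
        rc <- raup_crick(sub, reps = cfg$rc_reps,
                         seed = seed + 20L + g_idx)
        proc <- classify_processes(bn, rc)
        readr::write_tsv(proc,
                         emit(paste0("assembly_pairs_", g),
                              paste0(pre, "assembly_pairs_", g, ".tsv")))
        fr <- process_fractions(proc, metadata = sub$metadata)
        readr::write_tsv(fr,
                         emit(paste0("process_fractions_", g),
                              paste0(pre, "process_fractions_", g,
                                     ".tsv")))
      }
    })
  }

  # manifest -----------------------------------------------------------
  manifest_path <- paste0(pre, "manifest.json")
  params <- cfg[setdiff(names(cfg), c("table", "metadata", "taxonomy",
                                      "tree"))]
  artifacts <- tibble::tibble(
    artifact = names(paths),
    path = unname(unlist(paths)),
    md5 = unname(tools::md5sum(unlist(paths)))
  )
  write_json_artifact(list(
    package = "fermecol",
    version = as.character(utils::packageVersion("fermecol")),
    kingdom = cfg$kingdom,
    seed = seed,
    parameters = params,
    input = list(n_features = nrow(inp$table$counts),
                 n_samples = ncol(inp$table$counts)),
    artifacts = stats::setNames(as.list(artifacts$md5), artifacts$artifact)
  ), manifest_path)
  artifacts <- dplyr::bind_rows(artifacts, tibble::tibble(
    artifact = "manifest", path = manifest_path,
    md5 = unname(tools::md5sum(manifest_path))
  ))
  invisible(artifacts)
}

#' Bundled two-kingdom synthetic scenario
#'
#' One call that emulates the full study design: a bacterial-like table
#' (190 features, stage boundary at day 7, one strong takeover feature)
#' and a fungal-like table (500 features, stage boundary at day 2, two
#' takeover features), each with a matching Yule phylogeny and mock
#' genus taxonomy, 10 sampling days in 2 batches.
#'
#' @param seed integer seed.
#' @return A named list with `bacteria` and `fungi`, each holding
#'   `table`, `truth`, `tree`, `taxonomy`.
#' @export
bundled_scenario <- function(seed = 1) {
  bact <- simulate_succession(succession_scenario(
    n_features = 190, stage2_start = 7, n_takeover = 1, seed = seed))
  fung <- simulate_succession(succession_scenario(
    n_features = 500, stage2_start = 2, n_takeover = 2,
    takeover_share = 0.6, seed = seed + 1000L))
  list(
    bacteria = list(
      table = bact$table, truth = bact$truth,
      tree = simulate_tree(190, seed = seed + 1L),
      taxonomy = simulate_taxonomy(rownames(bact$table$counts),
                                   n_genera = 40, seed = seed + 2L)
    ),
    fungi = list(
      table = fung$table, truth = fung$truth,
      tree = simulate_tree(500, seed = seed + 1001L),
      taxonomy = simulate_taxonomy(rownames(fung$table$counts),
                                   n_genera = 80, seed = seed + 1002L)
    )
  )
}
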