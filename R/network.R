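#' Spearman correlation and significance matrices for a table
#'
#' Pairwise Spearman rank correlations between features (midrank ties),
#' with two-sided p-values from the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees of
#' freedom. Features present (count > 0) in fewer than `min_prevalence`
#' samples, and features constant across samples, are excluded up front
#' — a rank correlation carries no information without variation.
#'
#' @param x a [feature_table()] or count matrix (features x samples),
#'   typically already subset to one fermentation stage.
#' @param min_prevalence minimum number of samples a feature must occur
#'   in (default 3).
#' @return A list with `rho` and `p` (square matrices over the retained
#'   features) and `n_samples`.
#' @export
spearman_matrix <- function(x, min_prevalence = 3) {
  m <- if (inherits(x, "feature_table")) x$counts else x
  n <- ncol(m)
  if (n < 4) stop("need at least 4 samples for correlation", call. = FALSE)
  prev <- rowSums(m > 0)
  keep <- prev >= min_prevalence
  constant <- apply(m, 1, function(r) length(unique(r)) == 1)
  if (any(keep & constant)) {
    message(sprintf("spearman_matrix: excluded %d constant feature(s)",
                    sum(keep & constant)))
  }
  keep <- keep & !constant
  if (sum(keep) < 2) stop("fewer than 2 features pass the prevalence filter",
                          call. = FALSE)
  m <- m[keep, , drop = FALSE]
  rho <- stats::cor(t(m), method = "spearman")
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  diag(p) <- 0
  list(rho = rho, p = p, n_samples = n)
}

#' Build a thresholded co-occurrence network
#'
#' Retains an edge between two features iff `|rho| > rho_min` (strictly)
#' and `p < alpha` (strictly); features left without any edge are
#' dropped from the node set. The defaults (|rho| > 0.8, p < 0.05 on raw
#' p-values) are the conventional stringent thresholds for amplicon
#' co-occurrence networks; set `p_adjust = "BH"` for
#' Benjamini-Hochberg-corrected significance.
#'
#' @param sp list from [spearman_matrix()].
#' @param rho_min correlation magnitude threshold (default 0.8).
#' @param alpha significance threshold (default 0.05).
#' @param assignment optional rarity tibble from [classify_rarity()];
#'   nodes are annotated with their group.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return An object of class `cooc_network`: `graph` (igraph), `edges`
#'   (tibble `from`, `to`, `rho`, `p`, `sign`), `nodes` (tibble
#'   `feature_id`, `group`), `params`.
#' @export
build_network <- function(sp, rho_min = 0.8, alpha = 0.05,
                          assignment = NULL,
                          p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  rho <- sp$rho
  p <- sp$p
  ut <- upper.tri(rho)
  if (p_adjust == "BH") p[ut] <- stats::p.adjust(p[ut], method = "BH")
  hit <- ut & abs(rho) > rho_min & p < alpha
  idx <- which(hit, arr.ind = TRUE)
  ids <- rownames(rho)
  rho_v <- rho[hit]
  p_v <- p[hit]
  edges <- tibble::tibble(
    from = ids[idx[, 1]],
    to = ids[idx[, 2]],
    rho = rho_v,
    p = p_v,
    sign = ifelse(rho_v > 0, "positive", "negative")
  )
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  node_ids <- sort(unique(c(edges$from, edges$to)))
  nodes <- tibble::tibble(feature_id = node_ids)
  if (!is.null(assignment)) {
    nodes$group <- assignment$group[match(node_ids, assignment$feature_id)]
  } else {
    nodes$group <- NA_character_
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = nodes["feature_id"]
  )
  structure(list(graph = g, edges = edges, nodes = nodes,
                 params = list(rho_min = rho_min, alpha = alpha,
                               p_adjust = p_adjust)),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("<cooc_network> %d nodes, %d edges (%.0f%% positive)\n",
              nrow(x$nodes), nrow(x$edges),
              if (nrow(x$edges)) 100 * mean(x$edges$sign == "positive")
              else NA_real_))
  if ("module" %in% names(x$nodes)) {
    cat(sprintf("modules: %d (Q = %.3f)\n",
                length(unique(x$nodes$module)), x$modularity))
  }
  invisible(x)
}

#' Detect network modules by greedy modularity maximization
#'
#' Clauset-Newman-Moore greedy agglomeration on the unweighted,
#' unsigned graph (edge presence only), which is deterministic for a
#' fixed vertex order; vertices are held in lexicographic id order so
#' repeated runs agree exactly. Each connected component is partitioned
#' independently; singleton components become singleton modules.
#'
#' @param net a `cooc_network` from [build_network()].
#' @return `net` with a `module` column on `nodes` and a `modularity`
#'   element (Q of the final partition).
#' @export
detect_modules <- function(net) {
  stopifnot(inherits(net, "cooc_network"))
  if (igraph::ecount(net$graph) == 0) {
    net$nodes$module <- seq_len(nrow(net$nodes))
    net$modularity <- 0
    return(net)
  }
  cl <- igraph::cluster_fast_greedy(net$graph)
  net$nodes$module <- as.integer(igraph::membership(cl))
  net$modularity <- igraph::modularity(net$graph, igraph::membership(cl))
  net
}

#' Classify node topological roles from Zi and Pi
#'
#' Quadrant rule on within-module connectivity (Zi) and among-module
#' connectivity (Pi): module hub if `Zi > 2.5` only, connector if
#' `Pi > 0.62` only, network hub if both thresholds are exceeded,
#' peripheral otherwise. Non-peripheral nodes are keystone candidates.
#'
#' @param zi,pi numeric vectors.
#' @param zi_threshold,pi_threshold role thresholds (defaults 2.5, 0.62).
#' @return Character vector of roles.
#' @export
classify_node_roles <- function(zi, pi, zi_threshold = 2.5,
                                pi_threshold = 0.62) {
  hub <- zi > zi_threshold
  conn <- pi > pi_threshold
  dplyr::case_when(
    hub & conn ~ "network hub",
    hub ~ "module hub",
    conn ~ "connector",
    .default = "peripheral"
  )
}

#' Zi-Pi node metrics and keystone calls
#'
#' For every node: degree \eqn{k_i}; within-module degree \eqn{\kappa_i}
#' (edges into the node's own module); \eqn{Z_i = (\kappa_i -
#' \bar\kappa_{m(i)}) / \sigma_{\kappa, m(i)}} standardized over the
#' node's module with the population (divide-by-n) standard deviation,
#' set to 0 when the module is degenerate (\eqn{\sigma = 0}); and the
#' participation coefficient \eqn{P_i = 1 - \sum_m (\kappa_{im}/k_i)^2},
#' 0 for isolated nodes. Computed on the unsigned graph.
#'
#' @param net a `cooc_network` with modules assigned
#'   (see [detect_modules()]).
#' @param zi_threshold,pi_threshold passed to [classify_node_roles()].
#' @return A tibble `feature_id`, `group`, `module`, `degree`,
#'   `within_module_degree`, `zi`, `pi`, `role`, `keystone`.
#' @export
zipi <- function(net, zi_threshold = 2.5, pi_threshold = 0.62) {
  stopifnot(inherits(net, "cooc_network"))
  if (!"module" %in% names(net$nodes)) {
    stop("run detect_modules() first", call. = FALSE)
  }
  ids <- net$nodes$feature_id
  module <- net$nodes$module
  names(module) <- ids
  adj <- as.matrix(igraph::as_adjacency_matrix(net$graph, sparse = FALSE))
  adj <- adj[ids, ids, drop = FALSE]
  k <- rowSums(adj)
  mods <- sort(unique(module))
  # kappa[i, m]: edges from node i into module m
  kappa <- vapply(mods, function(m) {
    rowSums(adj[, module == m, drop = FALSE])
  }, numeric(length(ids)))
  kappa <- matrix(kappa, nrow = length(ids),
                  dimnames = list(ids, as.character(mods)))
  own <- kappa[cbind(seq_along(ids), match(module, mods))]
  zi <- numeric(length(ids))
  for (m in mods) {
    in_m <- module == m
    mu <- mean(own[in_m])
    sdev <- sqrt(mean((own[in_m] - mu)^2))
    zi[in_m] <- if (sdev > 0) (own[in_m] - mu) / sdev else 0
  }
  pi <- ifelse(k > 0, 1 - rowSums((kappa / pmax(k, 1))^2), 0)
  role <- classify_node_roles(zi, pi, zi_threshold, pi_threshold)
  tibble::tibble(
    feature_id = ids,
    group = net$nodes$group,
    module = module,
    degree = as.integer(k),
    within_module_degree = as.integer(own),
    zi = zi,
    pi = unname(pi),
    role = role,
    keystone = role != "peripheral"
  )
}

#' Topology summary of a co-occurrence network
#'
#' Node and edge counts, percentage of positive edges, percentage of
#' rare-group nodes (overall and among keystones), average degree,
#' average local clustering coefficient (triangles over wedges per node,
#' taken as 0 for degree < 2), Freeman degree centralization
#' \eqn{\sum_i (k_{max} - k_i) / ((n-1)(n-2))} (undefined below 3
#' nodes), and modularity Q.
#'
#' @param net a `cooc_network`, ideally after [detect_modules()].
#' @param node_metrics optional tibble from [zipi()]; computed on the
#'   fly when omitted and modules are available.
#' @return A one-row tibble.
#' @export
network_summary <- function(net, node_metrics = NULL) {
  stopifnot(inherits(net, "cooc_network"))
  g <- net$graph
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  pct_pos <- if (e > 0) 100 * mean(net$edges$sign == "positive") else NA_real_
  pct_rare <- if (all(is.na(net$nodes$group))) NA_real_ else
    100 * mean(net$nodes$group == "rare", na.rm = TRUE)
  if (is.null(node_metrics) && "module" %in% names(net$nodes)) {
    node_metrics <- zipi(net)
  }
  pct_rare_keystone <- NA_real_
  n_keystone <- NA_integer_
  if (!is.null(node_metrics)) {
    ks <- node_metrics[node_metrics$keystone, ]
    n_keystone <- nrow(ks)
    if (nrow(ks) > 0 && !all(is.na(ks$group))) {
      pct_rare_keystone <- 100 * mean(ks$group == "rare", na.rm = TRUE)
    }
  }
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0   # degree < 2 contributes 0
  centralization <- if (n >= 3) {
    igraph::centr_degree(g, loops = FALSE)$centralization
  } else NA_real_
  tibble::tibble(
    n_nodes = n,
    n_edges = e,
    pct_positive_edges = pct_pos,
    pct_rare_nodes = pct_rare,
    n_keystones = n_keystone,
    pct_rare_keystones = pct_rare_keystone,
    avg_degree = if (n > 0) 2 * e / n else NA_real_,
    avg_clustering = if (n > 0) mean(cc) else NA_real_,
    degree_centralization = centralization,
    modularity = if (!is.null(net$modularity)) net$modularity else NA_real_
  )
}

#' @export
tidy.cooc_network <- function(x, ...) {
  if ("module" %in% names(x$nodes)) zipi(x) else x$nodes
}

#' @export
glance.cooc_network <- function(x, ...) network_summary(x)

#' Export a network to GraphML
#'
#' Node attributes (rarity group, module, Zi, Pi, role) and edge
#' attributes (rho, p, sign) are attached when available, so the file
#' loads directly into Gephi or Cytoscape.
#'
#' @param net a `cooc_network`.
#' @param path output file path.
#' @param node_metrics optional tibble from [zipi()].
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path, node_metrics = NULL) {
  g <- net$graph
  igraph::E(g)$rho <- net$edges$rho
  igraph::E(g)$p <- net$edges$p
  igraph::E(g)$sign <- net$edges$sign
  ids <- igraph::V(g)$name
  if (!all(is.na(net$nodes$group))) {
    igraph::V(g)$group <- net$nodes$group[match(ids, net$nodes$feature_id)]
  }
  if (is.null(node_metrics) && "module" %in% names(net$nodes)) {
    node_metrics <- zipi(net)
  }
  if (!is.null(node_metrics)) {
    at <- node_metrics[match(ids, node_metrics$feature_id), ]
    igraph::V(g)$module <- at$module
    igraph::V(g)$zi <- at$zi
    igraph::V(g)$pi <- at$pi
    igraph::V(g)$role <- at$role
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Zi-Pi scatter with role thresholds
#'
#' @param node_metrics tibble from [zipi()].
#' @param zi_threshold,pi_threshold threshold lines (defaults 2.5, 0.62).
#' @return A ggplot object.
#' @export
plot_zipi <- function(node_metrics, zi_threshold = 2.5,
                      pi_threshold = 0.62) {
  ggplot2::ggplot(node_metrics,
                  ggplot2::aes(x = .data$pi, y = .data$zi,
                               colour = .data$role)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = zi_threshold, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = pi_threshold, linetype = "dashed") +
    ggplot2::labs(x = "among-module connectivity (Pi)",
                  y = "within-module connectivity (Zi)") +
    ggplot2::theme_minimal()
}
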