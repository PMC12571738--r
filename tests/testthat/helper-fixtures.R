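# small in-code fixtures shared across test files

# feature table from a plain matrix, auto-naming axes
ft <- function(m, metadata = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("f%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  feature_table(m, metadata = metadata)
}

# a 3-tip tree with known path lengths: d(A,B)=2, d(A,C)=d(B,C)=4
tree_abc <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# a 2-tip cherry with unit branches: d(A,B)=2
tree_ab <- function() ape::read.tree(text = "(A:1,B:1);")

# deterministic 4-tip tree for exhaustive null tests
tree_4tip <- function() {
  ape::read.tree(text = "((t1:0.6,t2:0.4):0.5,(t3:0.3,t4:0.7):0.2);")
}

# independent brute-force beta-MNTD (direct transcription of the
# definition; deliberately naive)
brute_beta_mntd <- function(xa, xb, d, weighted = TRUE) {
  ta <- names(xa)[xa > 0]
  tb <- names(xb)[xb > 0]
  mins_a <- vapply(ta, function(i) min(d[i, tb]), numeric(1))
  mins_b <- vapply(tb, function(j) min(d[ta, j]), numeric(1))
  if (weighted) {
    wa <- xa[ta] / sum(xa[ta]); wb <- xb[tb] / sum(xb[tb])
  } else {
    wa <- rep(1 / length(ta), length(ta))
    wb <- rep(1 / length(tb), length(tb))
  }
  0.5 * (sum(wa * mins_a) + sum(wb * mins_b))
}

# igraph from an edge list matrix (two columns of vertex names)
graph_from_edges <- function(e) {
  igraph::graph_from_data_frame(as.data.frame(e), directed = FALSE)
}

# build a cooc_network directly from an edge tibble (bypassing the
# correlation step) so graph-metric tests are independent of Spearman
network_from_edges <- function(edges, groups = NULL) {
  nodes <- tibble::tibble(feature_id = sort(unique(c(edges$from, edges$to))))
  nodes$group <- if (is.null(groups)) NA_character_ else
    groups[match(nodes$feature_id, names(groups))]
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = nodes["feature_id"])
  if (!"rho" %in% names(edges)) edges$rho <- 1
  if (!"p" %in% names(edges)) edges$p <- 0
  if (!"sign" %in% names(edges)) edges$sign <- "positive"
  structure(list(graph = g, edges = edges, nodes = nodes,
                 params = list(rho_min = 0.8, alpha = 0.05,
                               p_adjust = "none")),
            class = "cooc_network")
}

# complete-graph edge tibble over given vertex names
clique_edges <- function(ids) {
  cmb <- utils::combn(ids, 2)
  tibble::tibble(from = cmb[1, ], to = cmb[2, ])
}
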