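test_that("Spearman matrix matches the brute-force midrank formula", {
  m <- rbind(a = c(1, 2, 2, 4), b = c(3, 1, 2, 4),
             c = c(10, 8, 6, 1), d = c(2, 4, 6, 9),
             e = c(1, 3, 5, 9))
  colnames(m) <- paste0("s", 1:4)
  sp <- spearman_matrix(m, min_prevalence = 1)

  # independent oracle: Pearson correlation of midranks
  brute <- stats::cor(rank(m["a", ]), rank(m["b", ]))
  expect_equal(sp$rho["a", "b"], brute, tolerance = 1e-12)

  # perfect co- and anti-monotone pairs (strictly monotone vectors)
  expect_equal(sp$rho["d", "e"], 1, tolerance = 1e-12)
  expect_equal(sp$rho["d", "c"], -1, tolerance = 1e-12)
  expect_equal(sp$p["d", "e"], 0)

  # t-approximation p-value oracle
  n <- 4
  r <- sp$rho["a", "b"]
  p_hand <- 2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  expect_equal(sp$p["a", "b"], p_hand, tolerance = 1e-12)

  expect_error(spearman_matrix(m[, 1:3]), "4 samples")
})

test_that("edges require |rho| strictly above threshold and significant p", {
  rho <- matrix(c(1, 0.8, 0.81, 0.8, 1, -0.9, 0.81, -0.9, 1), 3,
                dimnames = list(letters[1:3], letters[1:3]))
  p <- matrix(0.001, 3, 3, dimnames = dimnames(rho))
  p["a", "c"] <- p["c", "a"] <- 0.2   # strong rho but not significant
  net <- build_network(list(rho = rho, p = p), rho_min = 0.8, alpha = 0.05)
  # a-b at exactly 0.8: excluded; a-c significant-but-p 0.2: excluded
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$from, "b")
  expect_equal(net$edges$to, "c")
  expect_equal(net$edges$sign, "negative")
})

test_that("a planted co-monotone block yields its full positive clique", {
  sim <- simulate_correlated_block(30, list(list(size = 6, sign = 1)),
                                   n_samples = 20, seed = 1)
  sp <- spearman_matrix(sim$table)
  net <- build_network(sp, assignment = classify_rarity(sim$table))
  blk <- sim$truth$feature_id[!is.na(sim$truth$block)]
  in_block <- net$edges$from %in% blk & net$edges$to %in% blk
  expect_equal(sum(in_block), 15)
  expect_true(all(net$edges$sign[in_block] == "positive"))
  # positive + negative percentages partition the edge set
  s <- network_summary(net)
  expect_equal(s$pct_positive_edges +
                 100 * mean(net$edges$sign == "negative"), 100)
})

test_that("anti-correlated members produce negative edges", {
  sim <- simulate_correlated_block(
    20, list(list(size = 4, sign = c(1, 1, -1, -1))),
    n_samples = 20, seed = 3)
  sp <- spearman_matrix(sim$table)
  net <- build_network(sp)
  mem <- sim$truth[!is.na(sim$truth$block), ]
  pos_ids <- mem$feature_id[mem$sign == 1]
  neg_ids <- mem$feature_id[mem$sign == -1]
  cross <- (net$edges$from %in% pos_ids & net$edges$to %in% neg_ids) |
    (net$edges$from %in% neg_ids & net$edges$to %in% pos_ids)
  expect_true(all(net$edges$sign[cross] == "negative"))
  expect_true(any(cross))
})

test_that("background features rarely exceed the correlation threshold", {
  sim <- simulate_correlated_block(30, list(list(size = 6, sign = 1)),
                                   n_samples = 20, seed = 1)
  sp <- spearman_matrix(sim$table, min_prevalence = 1)
  bg <- sim$truth$feature_id[is.na(sim$truth$block)]
  bg <- intersect(bg, rownames(sp$rho))
  sub <- sp$rho[bg, bg]
  frac <- mean(abs(sub[upper.tri(sub)]) > 0.8)
  expect_lt(frac, 0.10)
})

test_that("module detection separates disconnected cliques deterministically", {
  e <- dplyr::bind_rows(clique_edges(paste0("a", 1:4)),
                        clique_edges(paste0("b", 1:4)))
  net <- network_from_edges(e)
  net <- detect_modules(net)
  mods <- split(net$nodes$feature_id, net$nodes$module)
  expect_length(mods, 2)
  expect_true(all(vapply(mods, function(m)
    all(startsWith(m, "a")) || all(startsWith(m, "b")), logical(1))))
  # determinism
  net2 <- detect_modules(network_from_edges(e))
  expect_identical(net$nodes$module, net2$nodes$module)
})

test_that("modularity of two bridged cliques matches the hand formula", {
  e <- dplyr::bind_rows(clique_edges(paste0("a", 1:4)),
                        clique_edges(paste0("b", 1:4)),
                        tibble::tibble(from = "a1", to = "b1"))
  net <- detect_modules(network_from_edges(e))
  # hand: m = 13 edges; each module has 6 internal edges and total
  # degree 13, so Q = 2 * (6/13 - (13/26)^2)
  expect_equal(net$modularity, 2 * (6 / 13 - 0.25), tolerance = 1e-12)
  expect_length(unique(net$nodes$module), 2)
})

test_that("Zi and Pi match a brute-force recomputation on a 12-node graph", {
  # two 5-cliques bridged through two connector nodes
  e <- dplyr::bind_rows(
    clique_edges(paste0("a", 1:5)),
    clique_edges(paste0("b", 1:5)),
    tibble::tibble(from = c("x1", "x1", "x2", "x2", "x1"),
                   to   = c("a1", "b1", "a2", "b2", "x2"))
  )
  net <- detect_modules(network_from_edges(e))
  metrics <- zipi(net)

  # independent brute force from the adjacency and module vectors
  g <- net$graph
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  adj <- adj[metrics$feature_id, metrics$feature_id]
  mod <- metrics$module
  names(mod) <- metrics$feature_id
  mods <- sort(unique(mod))
  for (i in metrics$feature_id) {
    k_i <- sum(adj[i, ])
    kappa <- vapply(mods, function(m)
      sum(adj[i, names(mod)[mod == m]]), numeric(1))
    own <- kappa[match(mod[i], mods)]
    members <- names(mod)[mod == mod[i]]
    own_all <- vapply(members, function(j)
      sum(adj[j, names(mod)[mod == mod[j]]]), numeric(1))
    sd_pop <- sqrt(mean((own_all - mean(own_all))^2))
    zi_brute <- if (sd_pop > 0) (own - mean(own_all)) / sd_pop else 0
    pi_brute <- if (k_i > 0) 1 - sum((kappa / k_i)^2) else 0
    row <- metrics[metrics$feature_id == i, ]
    expect_equal(row$zi, unname(zi_brute), tolerance = 1e-12)
    expect_equal(row$pi, unname(pi_brute), tolerance = 1e-12)
  }
})

test_that("a node split 2/2 across two modules has Pi = 0.5", {
  # hub h with 2 edges into each clique; cliques form the modules
  e <- dplyr::bind_rows(
    clique_edges(paste0("a", 1:4)),
    clique_edges(paste0("b", 1:4)),
    tibble::tibble(from = c("h", "h", "h", "h"),
                   to = c("a1", "a2", "b1", "b2"))
  )
  net <- detect_modules(network_from_edges(e))
  metrics <- zipi(net)
  h <- metrics[metrics$feature_id == "h", ]
  expect_equal(h$degree, 4L)
  expect_equal(h$pi, 0.5, tolerance = 1e-12)
  # all-internal nodes have Pi = 0
  internal <- metrics[metrics$feature_id %in% c("a3", "a4", "b3", "b4"), ]
  expect_true(all(internal$pi == 0))
})

test_that("role quadrants follow the Zi/Pi thresholds", {
  expect_identical(classify_node_roles(3.0, 0.30), "module hub")
  expect_identical(classify_node_roles(1.0, 0.70), "connector")
  expect_identical(classify_node_roles(1.0, 0.30), "peripheral")
  expect_identical(classify_node_roles(3.0, 0.70), "network hub")
  # boundary values are not exceedances
  expect_identical(classify_node_roles(2.5, 0.62), "peripheral")
})

test_that("topology summary matches hand counts on canonical graphs", {
  # star on 5 nodes: centralization 1, clustering 0
  star <- tibble::tibble(from = "c", to = paste0("l", 1:4))
  s_star <- network_summary(detect_modules(network_from_edges(star)))
  expect_equal(s_star$degree_centralization, 1)
  expect_equal(s_star$avg_clustering, 0)

  # triangle: clustering 1, centralization 0
  tri <- clique_edges(c("a", "b", "c"))
  s_tri <- network_summary(detect_modules(network_from_edges(tri)))
  expect_equal(s_tri$avg_clustering, 1)
  expect_equal(s_tri$degree_centralization, 0)

  # 4-cycle: no triangles, regular degrees
  ring <- tibble::tibble(from = c("a", "b", "c", "d"),
                         to = c("b", "c", "d", "a"))
  s_ring <- network_summary(detect_modules(network_from_edges(ring)))
  expect_equal(s_ring$avg_clustering, 0)
  expect_equal(s_ring$degree_centralization, 0)
  expect_equal(s_ring$avg_degree, 2)
})

test_that("rarity accounting covers all nodes and keystones only", {
  e <- dplyr::bind_rows(
    clique_edges(paste0("a", 1:4)),
    clique_edges(paste0("b", 1:4)),
    tibble::tibble(from = c("h", "h", "h", "h"),
                   to = c("a1", "a2", "b1", "b2"))
  )
  groups <- stats::setNames(
    c(rep("abundant", 4), rep("rare", 4), "rare"),
    c(paste0("a", 1:4), paste0("b", 1:4), "h"))
  net <- detect_modules(network_from_edges(e, groups = groups))
  metrics <- zipi(net)
  s <- network_summary(net, metrics)
  expect_equal(s$n_nodes, 9)
  expect_equal(s$pct_rare_nodes, 100 * 5 / 9)
  # h (Pi = 0.5) is peripheral under 0.62; keystone stats may be empty
  expect_equal(sum(metrics$keystone), s$n_keystones)
})

test_that("graphml export round-trips the topology", {
  sim <- simulate_correlated_block(15, list(list(size = 5, sign = 1)),
                                   n_samples = 12, seed = 2)
  sp <- spearman_matrix(sim$table)
  net <- detect_modules(build_network(sp))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, path)
  g2 <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g2), nrow(net$nodes))
  expect_equal(igraph::ecount(g2), nrow(net$edges))
})
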