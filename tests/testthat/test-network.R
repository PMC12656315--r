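rel_ft <- function(m, kingdom = "bacteria") {
  rownames(m) <- paste0("t", seq_len(nrow(m)))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  feature_table(m, kingdom)
}

test_that("Spearman correlations hit the rank closed forms", {
  set.seed(41)
  b <- sample(10) * 3                        # distinct, tie-free
  t4 <- sample(50, 10)
  t5 <- sample(50, 10)
  partial <- rbind(2 * b, 5 * b, 40 - b, t4, t5)
  filler <- max(colSums(partial)) + 20 - colSums(partial)
  m <- rbind(partial, filler)                # equal column totals
  co <- pairwise_correlation(rel_ft(m), min_prevalence = 1)
  expect_equal(co$r["t1", "t2"], 1)          # identical ranks
  expect_equal(co$r["t1", "t3"], -1)         # reversed ranks
  expect_equal(co$p["t1", "t2"], 0)
  # brute-force sum-of-squared-rank-differences formula on a tie-free pair
  ra <- rank(t4); rb <- rank(t5)
  n <- length(ra)
  rho_oracle <- 1 - 6 * sum((ra - rb)^2) / (n * (n^2 - 1))
  expect_equal(co$r["t4", "t5"], rho_oracle, tolerance = 1e-12)
  small <- rel_ft(matrix(rpois(12, 9), nrow = 3))
  expect_error(pairwise_correlation(small), "5 samples")
})

test_that("edge thresholding follows |r| > 0.7 and p < 0.05 exactly", {
  ids <- c("a", "b", "c", "d")
  r <- diag(4); dimnames(r) <- list(ids, ids)
  p <- matrix(1, 4, 4, dimnames = list(ids, ids))
  r["a", "b"] <- r["b", "a"] <- 0.71; p["a", "b"] <- p["b", "a"] <- 0.01
  r["a", "c"] <- r["c", "a"] <- -0.9; p["a", "c"] <- p["c", "a"] <- 0.001
  r["b", "d"] <- r["d", "b"] <- 0.9;  p["b", "d"] <- p["d", "b"] <- 0.2
  r["c", "d"] <- r["d", "c"] <- 0.7;  p["c", "d"] <- p["d", "c"] <- 0.001
  corr <- list(r = r, p = p, n = 16,
               kingdom = setNames(rep("bacteria", 4), ids))
  net <- build_network(corr)
  key <- paste(net$edges$from, net$edges$to)
  expect_setequal(key, c("a b", "a c"))
  expect_equal(net$edges$sign[key == "a b"], "+")
  expect_equal(net$edges$sign[key == "a c"], "-")
  expect_false("d" %in% net$nodes$id)        # isolated node dropped
})

test_that("topology metrics match closed forms on tiny graphs", {
  tri <- network_topology(toy_network(clique_edges(c("a", "b", "c"))))
  expect_equal(tri$avg_degree, 2)
  expect_equal(tri$clustering, 1)
  expect_equal(tri$avg_path_length, 1)
  path3 <- network_topology(toy_network(edge_df(c("a", "b"), c("b", "c"))))
  expect_equal(path3$clustering, 0)
  expect_equal(path3$avg_path_length, 4 / 3)
  two_tri <- network_topology(toy_network(rbind(
    clique_edges(c("a", "b", "c")), clique_edges(c("x", "y", "z")))))
  expect_equal(two_tri$avg_path_length, 1)   # largest-component rule
})

test_that("greedy modules recover planted structure and the clique oracle", {
  g8 <- rbind(clique_edges(paste0("a", 1:4)), clique_edges(paste0("b", 1:4)))
  net <- detect_modules(toy_network(g8))
  expect_equal(length(unique(net$nodes$module)), 2)
  expect_equal(net$modularity, 0.5, tolerance = 1e-12)
  ig <- igraph::graph_from_data_frame(g8, directed = FALSE)
  expect_equal(net$modularity, best_modularity_exhaustive(ig),
               tolerance = 1e-12)
  full <- detect_modules(toy_network(clique_edges(paste0("n", 1:5))))
  expect_equal(length(unique(full$nodes$module)), 1)
})

test_that("Zi and Pi hit their closed-form cases", {
  # two 4-cliques joined by one bridge: bridge ends split edges 3:1
  edges <- rbind(clique_edges(paste0("a", 1:4)), clique_edges(paste0("b", 1:4)),
                 edge_df("a1", "b1"))
  net <- zipi(detect_modules(toy_network(edges)))
  nd <- net$nodes
  # nodes with all edges inside their module
  expect_equal(nd$pi[nd$id == "a2"], 0)
  expect_equal(nd$pi[nd$id == "a1"], 1 - (3 / 4)^2 - (1 / 4)^2)
  # equal split across two modules -> Pi = 0.5
  edges2 <- rbind(clique_edges(paste0("a", 1:4)),
                  clique_edges(paste0("b", 1:4)),
                  edge_df(rep("hub", 6), c("a1", "a2", "a3", "b1", "b2", "b3")))
  net2 <- zipi(detect_modules(toy_network(edges2)))
  hubrow <- net2$nodes[net2$nodes$id == "hub", ]
  expect_equal(hubrow$pi, 0.5)
  # within-module degree equal to the module mean -> Zi = 0
  sym <- zipi(detect_modules(toy_network(clique_edges(paste0("c", 1:4)))))
  expect_true(all(sym$nodes$zi == 0))
  # Zi has zero mean within each module when sd > 0
  for (mo in unique(net2$nodes$module)) {
    zim <- net2$nodes$zi[net2$nodes$module == mo]
    expect_lt(abs(mean(zim)), 1e-9)
  }
  # Pi bounded by 1 - 1/m
  m <- length(unique(net2$nodes$module))
  expect_true(all(net2$nodes$pi <= 1 - 1 / m + 1e-12))
})

test_that("role classification partitions the Zi-Pi plane as defined", {
  expect_equal(classify_roles(3.0, 0.7), "network hub")
  expect_equal(classify_roles(3.0, 0.1), "module hub")
  expect_equal(classify_roles(0.0, 0.0), "peripheral")
  grid <- expand.grid(zi = c(-1, 0, 2.5, 2.51, 4),
                      pi = c(0, 0.3, 0.62, 0.63, 0.9))
  roles <- classify_roles(grid$zi, grid$pi)
  expect_equal(roles[grid$zi > 2.5 & grid$pi > 0.62], rep("network hub", 4))
  expect_equal(roles[grid$zi > 2.5 & grid$pi <= 0.62],
               rep("module hub", 6))
  expect_equal(roles[grid$zi <= 2.5 & grid$pi > 0.62], rep("connector", 6))
  expect_equal(roles[grid$zi <= 2.5 & grid$pi <= 0.62],
               rep("peripheral", 9))
})

test_that("a node with large excess within-module degree is a module hub", {
  # module 1: hub wired to 11 members that form a sparse ring; module 2:
  # separate clique. With planted module labels the hub's within-module
  # degree sits far above the module mean, and all its edges stay inside.
  ring <- paste0("m", 1:11)
  edges <- rbind(edge_df(rep("hub", 11), ring),
                 edge_df(ring, c(ring[-1], ring[1])),
                 clique_edges(paste0("q", 1:4)))
  net <- toy_network(edges)
  net$nodes$module <- ifelse(grepl("^q", net$nodes$id), 2L, 1L)
  net <- assign_roles(zipi(net))
  hub <- net$nodes[net$nodes$id == "hub", ]
  expect_gt(hub$zi, 2.5)
  expect_equal(hub$pi, 0)
  expect_equal(hub$role, "module hub")
  expect_true("hub" %in% net$keystones)
})

test_that("module eigengenes align with member profiles", {
  set.seed(42)
  depth <- 1000
  prof <- rpois(10, 50) + 1
  m <- sapply(1:10, function(s) c(prof[s], prof[s], rpois(8, 30)))
  rownames(m) <- paste0("t", 1:10); colnames(m) <- paste0("s", 1:10)
  ft <- feature_table(m)
  eg <- module_eigengene(ft, c("t1", "t2"))
  z1 <- as.numeric(scale(unclass(ft)["t1", ] / colSums(unclass(ft))))
  expect_equal(abs(cor(eg, z1)), 1, tolerance = 1e-9)
  expect_gt(cor(eg, z1), 0)                  # orientation rule
  # two anti-correlated taxa: first PC carries all variance
  m2 <- m
  m2[2, ] <- max(m[1, ]) + 5 - m[1, ]
  ft2 <- feature_table(m2)
  eg2 <- module_eigengene(ft2, c("t1", "t2"))
  expect_true(sd(eg2) > 0)
  # eigen-decomposition oracle up to sign
  taxa <- paste0("t", 3:7)
  rel <- sweep(unclass(ft)[taxa, ], 2, colSums(unclass(ft)), "/")
  z <- t(scale(t(rel)))
  ev <- eigen(cov(t(z)) * (nrow(t(z)) - 1) / nrow(t(z)))$vectors[, 1]
  oracle <- drop(t(z) %*% ev)
  eg3 <- module_eigengene(ft, taxa)
  expect_equal(abs(cor(eg3, oracle)), 1, tolerance = 1e-9)
  expect_warning(e1 <- module_eigengene(ft, "t5"), "single-taxon")
  expect_equal(unname(e1),
               as.numeric(scale(unclass(ft)["t5", ] / colSums(unclass(ft)))),
               tolerance = 1e-12)
})

test_that("kingdom partition counts reconcile with the edge total", {
  king <- setNames(c(rep("bacteria", 4), rep("fungi", 3)),
                   c(paste0("b", 1:4), paste0("f", 1:3)))
  bac_only <- toy_network(clique_edges(paste0("b", 1:4)), kingdom = king)
  ks <- kingdom_partition_stats(bac_only)
  expect_equal(unname(ks$counts["fungi_fungi"]), 0)
  expect_equal(unname(ks$counts["bacteria_fungi"]), 0)
  mixed <- toy_network(rbind(clique_edges(paste0("b", 1:4)),
                             clique_edges(paste0("f", 1:3)),
                             edge_df("b1", "f1")), kingdom = king)
  km <- kingdom_partition_stats(mixed)
  expect_equal(unname(km$counts["bacteria_fungi"]), 1)
  expect_equal(sum(km$counts[1:3]), unname(km$counts["total"]))
})

test_that("edge sets are invariant to taxon input ordering", {
  set.seed(43)
  m <- matrix(rpois(30 * 16, 15), nrow = 30)
  rownames(m) <- paste0("t", 1:30); colnames(m) <- paste0("s", 1:16)
  ft <- feature_table(m)
  n1 <- build_network(pairwise_correlation(ft, min_prevalence = 1),
                      r_threshold = 0.4)
  perm <- sample(30)
  ft2 <- feature_table(m[perm, ], attr(ft, "kingdom")[perm])
  n2 <- build_network(pairwise_correlation(ft2, min_prevalence = 1),
                      r_threshold = 0.4)
  key <- function(e) sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  expect_equal(key(n1$edges), key(n2$edges))
})
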