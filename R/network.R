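#' Pairwise taxon correlations on relative abundances
#'
#' Converts counts to per-sample relative abundance, applies a
#' prevalence filter, then computes rank (Spearman, default) or Pearson
#' correlation for every retained taxon pair. Two-sided p-values use the
#' t approximation t = r sqrt((n - 2) / (1 - r^2)); perfectly
#' correlated pairs get p = 0.
#'
#' @param ft `feature_table` covering one or both kingdoms.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param min_prevalence keep taxa present in at least this many samples
#'   (default 4).
#' @return list with `r` and `p` matrices (taxa x taxa), `n` samples,
#'   `kingdom` labels of the retained taxa.
#' @export
pairwise_correlation <- function(ft, method = c("spearman", "pearson"),
                                 min_prevalence = 4) {
  method <- match.arg(method)
  n <- ncol(ft)
  if (n < 5) stop("correlation needs at least 5 samples")
  keep <- rowSums(ft > 0) >= min_prevalence
  m <- unclass(ft)[keep, , drop = FALSE]
  kingdom <- attr(ft, "kingdom")[keep]
  rel <- sweep(m, 2, colSums(m), "/")
  x <- t(rel)                              # samples x taxa
  if (method == "spearman") x <- apply(x, 2, rank)
  r <- cor(x)
  r_c <- pmin(pmax(r, -1), 1)
  tt <- abs(r_c) * sqrt((n - 2) / pmax(1 - r_c^2, .Machine$double.eps))
  p <- 2 * pt(tt, df = n - 2, lower.tail = FALSE)
  p[abs(r_c) >= 1 - 1e-12] <- 0
  diag(p) <- 0
  list(r = r, p = p, n = n, kingdom = setNames(kingdom, rownames(m)))
}

#' Build a co-occurrence network from a correlation matrix
#'
#' An edge joins every taxon pair with |r| > `r_threshold` and
#' p < `p_threshold`; edge sign is the sign of r. Isolated taxa are
#' dropped. Benjamini-Hochberg adjustment of the edge p-values is
#' available via `p_adjust`.
#'
#' @param corr result of [pairwise_correlation()].
#' @param r_threshold absolute correlation threshold (default 0.7).
#' @param p_threshold p-value threshold (default 0.05).
#' @param p_adjust `"none"` (default, raw p) or `"BH"`.
#' @return `cooccurrence_network`: list with `nodes` (id, kingdom,
#'   degree) and `edges` (from, to, r, p, sign) data.frames.
#' @export
build_network <- function(corr, r_threshold = 0.7, p_threshold = 0.05,
                          p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  r <- corr$r
  p <- corr$p
  ut <- which(upper.tri(r), arr.ind = TRUE)
  pvals <- p[ut]
  if (p_adjust == "BH") pvals <- stats::p.adjust(pvals, method = "BH")
  sel <- abs(r[ut]) > r_threshold & pvals < p_threshold
  if (!any(sel)) {
    warning("no taxon pair passes the thresholds: empty network")
    return(structure(list(
      nodes = data.frame(id = character(), kingdom = character(),
                         degree = integer(), stringsAsFactors = FALSE),
      edges = data.frame(from = character(), to = character(), r = numeric(),
                         p = numeric(), sign = character(),
                         stringsAsFactors = FALSE),
      modularity = NA_real_), class = "cooccurrence_network"))
  }
  ii <- ut[sel, , drop = FALSE]
  edges <- data.frame(from = rownames(r)[ii[, 1]], to = rownames(r)[ii[, 2]],
                      r = r[ut][sel], p = pvals[sel],
                      sign = ifelse(r[ut][sel] > 0, "+", "-"),
                      stringsAsFactors = FALSE)
  ids <- sort(unique(c(edges$from, edges$to)))
  deg <- table(factor(c(edges$from, edges$to), levels = ids))
  nodes <- data.frame(id = ids,
                      kingdom = unname(corr$kingdom[ids]),
                      degree = as.integer(deg), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, modularity = NA_real_),
            class = "cooccurrence_network")
}

#' Network topology metrics
#'
#' Average path length is computed over the largest connected component;
#' the clustering coefficient is the mean local clustering over all
#' nodes with degree-1 nodes contributing 0. Modularity refers to the
#' module assignment from [detect_modules()] when present.
#'
#' @param net `cooccurrence_network`.
#' @return list of metrics: nodes, edges, positive/negative edge counts,
#'   `pn_ratio` (NA when no negative edges), average degree, average
#'   path length, clustering coefficient, modularity, intra- and
#'   cross-kingdom edge counts.
#' @export
network_topology <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  nn <- nrow(net$nodes); ne <- nrow(net$edges)
  if (nn == 0) {
    return(list(nodes = 0L, edges = 0L, positive = 0L, negative = 0L,
                pn_ratio = NA_real_, avg_degree = 0, avg_path_length = 0,
                clustering = 0, modularity = NA_real_,
                kingdom_edges = kingdom_partition_stats(net)$counts))
  }
  g <- network_as_igraph(net)
  pos <- sum(net$edges$sign == "+")
  neg <- ne - pos
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  apl <- if (igraph::vcount(sub) > 1) {
    igraph::mean_distance(sub, directed = FALSE)
  } else 0
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  loc[is.na(loc)] <- 0
  list(nodes = nn, edges = ne, positive = pos, negative = neg,
       pn_ratio = if (neg > 0) pos / neg else NA_real_,
       avg_degree = 2 * ne / nn, avg_path_length = apl,
       clustering = mean(loc), modularity = net$modularity,
       kingdom_edges = kingdom_partition_stats(net)$counts)
}

#' Detect network modules by greedy modularity maximisation
#'
#' Fast-greedy agglomerative community detection on the unsigned,
#' unweighted graph. Modules are relabelled by descending size (module 1
#' largest); ties broken by smallest member id.
#'
#' @param net `cooccurrence_network` with at least one edge.
#' @param seed integer seed (kept for interface stability; the greedy
#'   algorithm is deterministic).
#' @return the network with `nodes$module` filled and `modularity` set.
#' @export
detect_modules <- function(net, seed = 1) {
  stopifnot(inherits(net, "cooccurrence_network"))
  if (nrow(net$edges) == 0) stop("module detection needs at least one edge")
  local_seed(seed)
  g <- network_as_igraph(net)
  cl <- igraph::cluster_fast_greedy(g)
  # cut the dendrogram at the best modularity; among ties prefer the
  # coarsest partition (a complete graph is one module, not several)
  kmin <- igraph::vcount(g) - nrow(cl$merges)
  qs <- vapply(kmin:igraph::vcount(g), function(k)
    igraph::modularity(g, igraph::cut_at(cl, no = k)), numeric(1))
  kbest <- (kmin:igraph::vcount(g))[which(qs >= max(qs) - 1e-12)[1]]
  mem <- igraph::cut_at(cl, no = kbest)
  names(mem) <- igraph::V(g)$name
  sizes <- table(mem)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  net$nodes$module <- as.integer(relabel[as.character(mem[net$nodes$id])])
  net$modularity <- igraph::modularity(g, mem)
  net
}

#' Within-module degree z-score and participation coefficient
#'
#' Zi = (k_is - mean_s) / sd_s where k_is is node i's degree inside its
#' own module s and mean/sd are taken over the nodes of module s
#' (population sd; Zi = 0 when the sd is 0). Pi = 1 - sum_t
#' (k_it / k_i)^2 over modules t.
#'
#' @param net network with modules assigned ([detect_modules()]).
#' @return the network with `nodes$zi` and `nodes$pi` filled.
#' @export
zipi <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  if (is.null(net$nodes$module)) stop("assign modules first (detect_modules)")
  ids <- net$nodes$id
  mod <- setNames(net$nodes$module, ids)
  # per-node degree into each module
  ends <- rbind(data.frame(node = net$edges$from, other = net$edges$to),
                data.frame(node = net$edges$to, other = net$edges$from))
  ends$other_mod <- mod[ends$other]
  kit <- table(factor(ends$node, levels = ids), ends$other_mod)
  ki <- rowSums(kit)
  pi <- 1 - rowSums((kit / ki)^2)
  kis <- kit[cbind(seq_along(ids), match(mod[ids], colnames(kit)))]
  kis[is.na(kis)] <- 0
  zi <- numeric(length(ids))
  for (s in unique(mod)) {
    members <- mod[ids] == s
    v <- kis[members]
    mu <- mean(v)
    sdv <- sqrt(mean((v - mu)^2))
    zi[members] <- if (sdv > 0) (v - mu) / sdv else 0
  }
  net$nodes$zi <- unname(zi)
  net$nodes$pi <- unname(pi[ids])
  net
}

#' Classify node roles from Zi and Pi
#'
#' Network hub: Zi > `zi_threshold` and Pi > `pi_threshold`; module hub:
#' Zi > `zi_threshold` and Pi <= `pi_threshold`; connector: Zi <=
#' `zi_threshold` and Pi > `pi_threshold`; otherwise peripheral.
#' Keystone taxa are the module hubs, network hubs and connectors.
#'
#' @param zi,pi numeric vectors of equal length.
#' @param zi_threshold default 2.5.
#' @param pi_threshold default 0.62.
#' @return character vector of roles.
#' @export
classify_roles <- function(zi, pi, zi_threshold = 2.5, pi_threshold = 0.62) {
  ifelse(zi > zi_threshold & pi > pi_threshold, "network hub",
  ifelse(zi > zi_threshold, "module hub",
  ifelse(pi > pi_threshold, "connector", "peripheral")))
}

#' Assign roles and list keystone taxa on a network
#' @param net network with Zi/Pi computed ([zipi()]).
#' @param zi_threshold,pi_threshold see [classify_roles()].
#' @return the network with `nodes$role` filled and a `keystones`
#'   character vector element.
#' @export
assign_roles <- function(net, zi_threshold = 2.5, pi_threshold = 0.62) {
  stopifnot(inherits(net, "cooccurrence_network"))
  if (is.null(net$nodes$zi)) stop("compute Zi/Pi first (zipi)")
  net$nodes$role <- classify_roles(net$nodes$zi, net$nodes$pi,
                                   zi_threshold, pi_threshold)
  net$keystones <- net$nodes$id[net$nodes$role != "peripheral"]
  net
}

#' Module eigengene
#'
#' First principal component of the standardised relative abundance
#' matrix of a module's member taxa, one score per sample, sign-oriented
#' to correlate positively with the module's mean standardised profile.
#'
#' @param ft feature table the network was built from.
#' @param taxa member taxon ids of one module.
#' @return named numeric vector, one value per sample.
#' @export
module_eigengene <- function(ft, taxa) {
  m <- unclass(ft)[taxa, , drop = FALSE]
  rel <- sweep(m, 2, colSums(unclass(ft)), "/")
  z <- t(scale(t(rel)))                     # standardise each taxon profile
  if (length(taxa) == 1) {
    warning("single-taxon module: returning its standardised profile")
    return(setNames(as.numeric(z), colnames(z)))
  }
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
  eg <- pc$x[, 1]
  ref <- colMeans(z)
  if (sum(eg * ref) < 0) eg <- -eg
  eg
}

#' Edge counts and sign ratios per kingdom partition
#'
#' Splits edges into bacteria-bacteria, fungi-fungi and bacteria-fungi
#' partitions; counts always reconcile with the total edge count.
#'
#' @param net `cooccurrence_network` with kingdom node labels.
#' @return list with `counts` (named integer vector incl. total) and
#'   `pn_ratio` per partition (NA when a partition has no negative edge).
#' @export
kingdom_partition_stats <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  king <- setNames(net$nodes$kingdom, net$nodes$id)
  part <- function(a, b) {
    ka <- king[net$edges$from]; kb <- king[net$edges$to]
    (ka == a & kb == b) | (ka == b & kb == a)
  }
  if (nrow(net$edges) == 0) {
    counts <- c(bacteria_bacteria = 0L, fungi_fungi = 0L,
                bacteria_fungi = 0L, total = 0L)
    return(list(counts = counts,
                pn_ratio = setNames(rep(NA_real_, 3), names(counts)[1:3])))
  }
  bb <- part("bacteria", "bacteria")
  ff <- part("fungi", "fungi")
  bf <- part("bacteria", "fungi")
  counts <- c(bacteria_bacteria = sum(bb), fungi_fungi = sum(ff),
              bacteria_fungi = sum(bf), total = nrow(net$edges))
  pn <- sapply(list(bb, ff, bf), function(sel) {
    pos <- sum(net$edges$sign[sel] == "+")
    neg <- sum(sel) - pos
    if (neg > 0) pos / neg else NA_real_
  })
  list(counts = counts,
       pn_ratio = setNames(pn, c("bacteria_bacteria", "fungi_fungi",
                                 "bacteria_fungi")))
}
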