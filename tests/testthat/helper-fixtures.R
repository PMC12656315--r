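# shared fixtures and independent oracles, built in code at test time

toy_sieve <- function(masses = c(5, 10, 15, 10, 5, 5), max_d = 5,
                      id = "s1") {
  sieve_fractions(c(2, 1, 0.5, 0.25, 0.106), masses, max_d, id)
}

# build a cooccurrence_network directly from an edge list (for topology,
# module and Zi-Pi tests that plant graph structure by hand)
toy_network <- function(edges, kingdom = NULL) {
  ids <- sort(unique(c(edges$from, edges$to)))
  if (is.null(kingdom)) kingdom <- setNames(rep("bacteria", length(ids)), ids)
  deg <- table(factor(c(edges$from, edges$to), levels = ids))
  edges$r <- if (is.null(edges$r)) rep(0.9, nrow(edges)) else edges$r
  edges$p <- if (is.null(edges$p)) rep(0.001, nrow(edges)) else edges$p
  edges$sign <- ifelse(edges$r > 0, "+", "-")
  nodes <- data.frame(id = ids, kingdom = unname(kingdom[ids]),
                      degree = as.integer(deg), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, modularity = NA_real_),
            class = "cooccurrence_network")
}

edge_df <- function(from, to) {
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

clique_edges <- function(ids) {
  cmb <- t(combn(ids, 2))
  edge_df(cmb[, 1], cmb[, 2])
}

# exhaustive best-partition modularity by enumerating restricted growth
# strings (all set partitions); tractable to ~10 nodes
best_modularity_exhaustive <- function(g) {
  n <- igraph::vcount(g)
  best <- -Inf
  rec <- function(assign, k) {
    i <- length(assign) + 1
    if (i > n) {
      q <- igraph::modularity(g, assign)
      if (q > best) best <<- q
      return(invisible())
    }
    for (m in seq_len(k + 1)) rec(c(assign, m), max(k, m))
  }
  rec(integer(), 0)
  best
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# columns of x orthogonalised (exact zero sample correlation) and scaled
orthogonal_columns <- function(n, k, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * k), n, k)
  x <- scale(x, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(x))
  scale(q)
}

# independent pairwise Duncan declaration oracle: sorted means, span
# ranges from the studentized-range quantile, all-pairs comparison
duncan_oracle_different <- function(values, groups, alpha = 0.05) {
  g <- as.character(groups)
  n <- table(g)[1]
  f <- factor(g)
  av <- anova(aov(values ~ f))
  mse <- av$`Mean Sq`[2]
  dfe <- av$Df[2]
  means <- sort(tapply(values, g, mean), decreasing = TRUE)
  k <- length(means)
  diffm <- matrix(FALSE, k, k, dimnames = list(names(means), names(means)))
  # raw span tests, then the protection closure in matrix form: a pair
  # differs iff every range enclosing it exceeds its critical range
  raw <- matrix(TRUE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p <- j - i + 1
      ap <- 1 - (1 - alpha)^(p - 1)
      raw[i, j] <- (means[i] - means[j]) >
        qtukey(1 - ap, p, dfe) * sqrt(mse / n)
    }
  }
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      idx <- cbind(rep(seq_len(i), each = k - j + 1), rep(j:k, times = i))
      diffm[i, j] <- diffm[j, i] <- all(raw[idx])
    }
  }
  diffm
}

# does a letter display realise a given difference matrix?
letters_match_relation <- function(letter_df, diffm) {
  lets <- setNames(strsplit(letter_df$letters, ""), letter_df$group)
  groups <- rownames(diffm)
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i >= j) next
      share <- length(intersect(lets[[groups[i]]], lets[[groups[j]]])) > 0
      if (share == diffm[groups[i], groups[j]]) return(FALSE)
    }
  }
  TRUE
}
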