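#' Rarefy a feature table to even depth
#'
#' Subsamples each sample's counts without replacement to exactly
#' `depth` reads. With `depth = "min"` the lowest sample total is used,
#' so no sample is dropped; with an explicit depth, samples below it are
#' dropped with a warning.
#'
#' @param ft `feature_table` (taxa x samples).
#' @param depth positive integer or `"min"`.
#' @param seed integer seed; subsampling is deterministic given the seed.
#' @return rarefied `feature_table` with every column summing to `depth`.
#' @export
rarefy <- function(ft, depth = "min", seed = 1) {
  totals <- colSums(ft)
  if (identical(depth, "min")) depth <- min(totals)
  depth <- as.integer(depth)
  if (depth <= 0) stop("depth must be positive")
  kingdom <- attr(ft, "kingdom")
  if (is.null(kingdom)) kingdom <- "bacteria"
  low <- totals < depth
  if (any(low)) {
    warning(sum(low), " sample(s) below depth dropped: ",
            paste(colnames(ft)[low], collapse = ", "))
    ft <- unclass(ft)[, !low, drop = FALSE]
  }
  local_seed(seed)
  out <- apply(unclass(ft), 2, function(v) {
    picked <- sample.int(sum(v), depth)
    # map draw indices back to taxa via the cumulative count boundaries
    tabulate(findInterval(picked - 1L, cumsum(v), left.open = FALSE) + 1L,
             nbins = length(v))
  })
  rownames(out) <- rownames(ft)
  feature_table(out, kingdom = kingdom)
}

#' Chao1 richness estimate
#'
#' Bias-corrected estimator S_obs + F1 (F1 - 1) / (2 (F2 + 1)) with F1
#' the singleton count and F2 the doubleton count, defined even when no
#' doubletons are observed. Equals observed richness when F1 = 0.
#'
#' @param counts non-negative integer vector for one sample.
#' @return estimated richness.
#' @export
chao1 <- function(counts) {
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  if (sum(counts) == 0) {
    warning("all-zero sample: Chao1 reported as 0")
    return(0)
  }
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity (nats)
#' @param counts non-negative vector for one sample.
#' @return -sum p log p over taxa with positive proportion.
#' @export
shannon <- function(counts) {
  tot <- sum(counts)
  if (tot <= 0) stop("zero total count: Shannon undefined")
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Per-sample alpha diversity
#' @param ft feature table.
#' @return data.frame with sample_id, chao1, shannon, observed richness.
#' @export
alpha_diversity <- function(ft) {
  data.frame(sample_id = colnames(ft),
             observed = colSums(ft > 0),
             chao1 = apply(unclass(ft), 2, chao1),
             shannon = apply(unclass(ft), 2, shannon),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(i, j) = sum |x - y| / sum (x + y) over taxa.
#'
#' @param ft feature table (taxa x samples) or numeric matrix.
#' @return `dist`-convertible symmetric matrix with zero diagonal.
#' @export
bray_curtis <- function(ft) {
  m <- unclass(as.matrix(ft))
  n <- ncol(m)
  if (n < 2) stop("need at least 2 samples")
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- sum(m[, i] + m[, j])
      if (tot == 0) stop("samples ", colnames(m)[i], " and ", colnames(m)[j],
                         " are both all-zero")
      d[i, j] <- d[j, i] <- sum(abs(m[, i] - m[, j])) / tot
    }
  }
  d
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: double-centring of -d^2/2, then
#' eigen-decomposition. Coordinates are eigenvectors scaled by the
#' square root of the positive eigenvalues; negative eigenvalues are
#' reported, not corrected.
#'
#' @param d square symmetric distance matrix.
#' @return list with `coordinates` (samples x axes), `eigenvalues`,
#'   `prop_explained` (over positive eigenvalues), `negative_eigenvalues`.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("PCoA needs at least 3 samples")
  a <- -0.5 * d^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  g <- ctr %*% a %*% ctr
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  pos <- e$values > 1e-9 * max(abs(e$values))
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), nrow = sum(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = e$values,
       prop_explained = e$values[pos] / sum(e$values[pos]),
       negative_eigenvalues = e$values[e$values < -1e-9 * max(abs(e$values))])
}

# one-way pseudo-F from a squared-distance matrix and group labels
permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  lev <- unique(groups)
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (g in lev) {
    idx <- groups == g
    ng <- sum(idx)
    ss_w <- ss_w + sum(d2[idx, idx]) / (2 * ng)
  }
  k <- length(lev)
  ((ss_tot - ss_w) / (k - 1)) / (ss_w / (n - k))
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix.
#' The pseudo-F is computed from distance sums of squares; the p-value
#' uses label permutations with the add-one rule
#' p = (1 + #permuted F >= observed) / (1 + n_perm).
#'
#' @param d distance matrix.
#' @param groups group labels, one per sample; every group needs >= 2
#'   samples.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return list with `statistic` (pseudo-F), `p_value`, `n_perm`, `seed`,
#'   `r_squared` (between-group SS over total SS).
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) stop("groups length must match distance matrix")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 samples")
  d2 <- d^2
  f_obs <- permanova_f(d2, groups)
  n <- nrow(d)
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (g in names(sizes)) {
    idx <- groups == g
    ss_w <- ss_w + sum(d2[idx, idx]) / (2 * sum(idx))
  }
  r2 <- (ss_tot - ss_w) / ss_tot
  local_seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (permanova_f(d2, groups[sample.int(n)]) >= f_obs) hits <- hits + 1L
  }
  list(statistic = f_obs, p_value = (1 + hits) / (1 + n_perm),
       n_perm = n_perm, seed = seed, r_squared = r2)
}

anosim_r <- function(rk, groups) {
  n <- length(groups)
  within <- outer(groups, groups, "==")[upper.tri(matrix(0, n, n))]
  m <- n * (n - 1) / 2
  (mean(rk[!within]) - mean(rk[within])) / (m / 2)
}

#' ANOSIM test
#'
#' Analysis of similarities: R = (mean between-group rank distance -
#' mean within-group rank distance) / (M / 2), M = N (N - 1) / 2.
#' Rank-based, so invariant to monotone transforms of the distances.
#' Permutation p-value with the add-one rule.
#'
#' @inheritParams permanova
#' @return list with `statistic` (R), `p_value`, `n_perm`, `seed`.
#' @export
anosim <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) stop("groups length must match distance matrix")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 samples")
  n <- nrow(d)
  rk <- rank(d[upper.tri(d)])
  r_obs <- anosim_r(rk, groups)
  local_seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (anosim_r(rk, groups[sample.int(n)]) >= r_obs) hits <- hits + 1L
  }
  list(statistic = r_obs, p_value = (1 + hits) / (1 + n_perm),
       n_perm = n_perm, seed = seed)
}

#' Mantel test between two distance matrices
#'
#' Correlates the upper-triangle entries of two distance matrices over
#' the same samples; significance by simultaneous row/column permutation
#' of the second matrix, add-one p-value rule.
#'
#' @param d1,d2 square symmetric distance matrices over the same samples.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `statistic` (Mantel r), `p_value`, `n_perm`, `seed`.
#' @export
mantel <- function(d1, d2, n_perm = 999, seed = 1,
                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2))) stop("distance matrices differ in size")
  n <- nrow(d1)
  ut <- upper.tri(d1)
  r_obs <- cor(d1[ut], d2[ut], method = method)
  local_seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    if (cor(d1[ut], d2[p, p][ut], method = method) >= r_obs) hits <- hits + 1L
  }
  list(statistic = r_obs, p_value = (1 + hits) / (1 + n_perm),
       n_perm = n_perm, seed = seed, method = method)
}
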