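make_ft <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("t", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  feature_table(m)
}

test_that("rarefaction draws exactly depth reads without replacement", {
  m <- make_ft(matrix(c(10, 20, 30, 5, 5, 50), ncol = 2))
  r <- rarefy(m, depth = 60, seed = 1)
  expect_equal(unname(unclass(r)[, 1]), c(10, 20, 30))  # exhaustive draw
  r2 <- rarefy(m, depth = 40, seed = 2)
  expect_equal(unname(colSums(r2)), c(40, 40))
  expect_true(all(unclass(r2) <= unclass(m)))
  expect_error(rarefy(m, depth = 0), "positive")
  m3 <- make_ft(matrix(c(10, 20, 30, 5, 5, 90, 40, 30, 30), ncol = 3))
  expect_warning(r3 <- rarefy(m3, depth = 80, seed = 1), "dropped")
  expect_equal(ncol(r3), 2)
})

test_that("rarefied counts match the hypergeometric mean", {
  v <- c(200, 300, 500)
  m <- make_ft(cbind(v, v))
  depth <- 100
  draws <- sapply(1:1000, function(s)
    unclass(rarefy(m, depth, seed = s))[1, 1])
  p <- v[1] / sum(v)
  var_hyper <- depth * p * (1 - p) * (sum(v) - depth) / (sum(v) - 1)
  se_mean <- sqrt(var_hyper / 1000)
  expect_lt(abs(mean(draws) - depth * p), 3 * se_mean)
})

test_that("Chao1 follows the bias-corrected estimator", {
  expect_equal(chao1(c(5, 3, 2, 2, 4)), 5)          # no singletons
  expect_equal(chao1(c(1, 1, 2, 3, 4)), 5.5)        # S=5, F1=2, F2=1
  set.seed(31)
  v <- rpois(60, 1.2)
  s_obs <- sum(v > 0); f1 <- sum(v == 1); f2 <- sum(v == 2)
  expect_equal(chao1(v), s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)))
  expect_warning(z <- chao1(integer(3)), "all-zero")
  expect_equal(z, 0)
})

test_that("Shannon diversity matches closed forms and brute force", {
  expect_equal(shannon(rep(7, 4)), log(4))
  expect_equal(shannon(c(0, 12, 0)), 0)
  set.seed(32)
  v <- rpois(30, 4)
  p <- v[v > 0] / sum(v)
  expect_equal(shannon(v), -sum(p * log(p)), tolerance = 1e-12)
  expect_error(shannon(c(0, 0)), "zero")
  ft <- make_ft(matrix(rpois(40, 5), ncol = 2))
  ad <- alpha_diversity(ft)
  expect_true(all(ad$chao1 >= ad$observed))
  expect_true(all(ad$shannon <= log(ad$observed)))
})

test_that("Bray-Curtis worked values and range hold", {
  m <- make_ft(cbind(c(3, 1, 4), c(3, 1, 4)))
  expect_equal(bray_curtis(m)[1, 2], 0)
  m2 <- make_ft(cbind(c(5, 2, 0, 0), c(0, 0, 3, 7)))
  expect_equal(bray_curtis(m2)[1, 2], 1)
  m3 <- make_ft(cbind(c(1, 1, 0), c(0, 1, 1)))
  expect_equal(bray_curtis(m3)[1, 2], 0.5)
  set.seed(33)
  m4 <- make_ft(matrix(rpois(80, 6), ncol = 4))
  d <- bray_curtis(m4)
  expect_equal(unname(d),
               unname(as.matrix(vegan::vegdist(t(unclass(m4))))),
               tolerance = 1e-12)
})

test_that("PCoA reproduces Euclidean geometry and reports eigenvalues", {
  pts <- cbind(c(0, 3, 0, 3), c(0, 0, 4, 4))
  d <- as.matrix(dist(pts))
  ord <- pcoa(d)
  rec <- as.matrix(dist(ord$coordinates))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)
  # equilateral triangle: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  e3 <- pcoa(d3)$eigenvalues
  expect_equal(e3[1], e3[2], tolerance = 1e-9)
  expect_lt(abs(e3[3]), 1e-9)
  # collinear points: exactly one positive eigenvalue
  d1 <- as.matrix(dist(c(0, 1, 2.5, 4)))
  ev <- pcoa(d1)$eigenvalues
  expect_equal(sum(ev > 1e-9 * max(ev)), 1)
  expect_error(pcoa(matrix(0, 2, 2)), "3")
})

test_that("PERMANOVA matches vegan and its permutation contract", {
  set.seed(34)
  m <- make_ft(matrix(rpois(12 * 25, 8), ncol = 12))
  g <- rep(c("A", "B", "C"), each = 4)
  d <- bray_curtis(m)
  res <- permanova(d, g, n_perm = 99, seed = 5)
  ref <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(res$statistic, ref$F[1], tolerance = 1e-9)
  expect_equal(res$r_squared, ref$R2[1], tolerance = 1e-9)
  # observed F invariant to sample reordering
  perm <- sample(12)
  res2 <- permanova(d[perm, perm], g[perm], n_perm = 9, seed = 1)
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-12)
  # deterministic p under seed, add-one floor under complete separation
  set.seed(39)
  pts <- c(rnorm(4, 0, 0.1), rnorm(4, 10, 0.1), rnorm(4, 20, 0.1),
           rnorm(4, 30, 0.1))
  sep <- as.matrix(dist(pts))
  gs <- rep(c("w", "x", "y", "z"), each = 4)
  p1 <- permanova(sep, gs, n_perm = 999, seed = 3)
  p2 <- permanova(sep, gs, n_perm = 999, seed = 3)
  expect_equal(p1$p_value, 1 / 1000)
  expect_identical(p1, p2)
  expect_error(permanova(sep[1:8, 1:8], c("x", rep("y", 7)), 99, 1),
               "at least 2")
})

test_that("ANOSIM matches vegan, is rank-based and maximal at separation", {
  set.seed(38)
  pts <- c(rnorm(4, 0, 0.1), rnorm(4, 10, 0.1), rnorm(4, 20, 0.1),
           rnorm(4, 30, 0.1))
  sep <- as.matrix(dist(pts))
  gs <- rep(c("w", "x", "y", "z"), each = 4)
  a <- anosim(sep, gs, n_perm = 99, seed = 2)
  expect_equal(a$statistic, 1)
  expect_equal(a$p_value, 1 / 100)
  set.seed(35)
  m <- make_ft(matrix(rpois(12 * 25, 8), ncol = 12))
  g <- rep(c("A", "B", "C"), each = 4)
  d <- bray_curtis(m)
  ours <- anosim(d, g, n_perm = 99, seed = 1)
  ref <- vegan::anosim(as.dist(d), grouping = g, permutations = 99)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
  # monotone transform leaves R unchanged
  ours2 <- anosim(d^3, g, n_perm = 9, seed = 1)
  expect_equal(ours2$statistic, ours$statistic, tolerance = 1e-12)
})

test_that("ANOSIM R is centred at zero under random labels", {
  set.seed(36)
  rs <- replicate(1000, {
    d <- as.matrix(dist(rnorm(12)))
    anosim(d, sample(rep(c("A", "B"), each = 6)), n_perm = 1, seed = 1)$statistic
  })
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("Mantel correlation and permutation behave as specified", {
  set.seed(37)
  d1 <- as.matrix(dist(matrix(rnorm(20), ncol = 2)))
  m1 <- mantel(d1, d1, n_perm = 99, seed = 1)
  expect_equal(m1$statistic, 1)
  m2 <- mantel(d1, 3 * d1 + 2, n_perm = 99, seed = 1)
  expect_equal(m2$statistic, 1, tolerance = 1e-12)
  d2 <- as.matrix(dist(matrix(rnorm(20), ncol = 2)))
  ours <- mantel(d1, d2, n_perm = 99, seed = 4)
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 99)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_error(mantel(d1, d2[1:8, 1:8], 9, 1), "size")
})
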