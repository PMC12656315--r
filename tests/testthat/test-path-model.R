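chain_spec <- function() {
  plspm_spec(list(x = "x1", m = "m1", y = "y1"),
             rbind(c("x", "m"), c("m", "y"), c("x", "y")))
}

test_that("single-indicator blocks reproduce standardized regressions", {
  set.seed(51)
  n <- 120
  x <- rnorm(n)
  m <- 0.6 * x + rnorm(n, 0, 0.6)
  y <- 0.4 * m - 0.3 * x + rnorm(n, 0, 0.5)
  dat <- data.frame(x1 = x, m1 = m, y1 = y)
  fit <- fit_plspm(dat, chain_spec())
  zs <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  o1 <- coef(lm(zs(m) ~ zs(x)))[2]
  o2 <- coef(lm(zs(y) ~ zs(m) + zs(x)))[2:3]
  pc <- fit$path_coefficients
  expect_equal(pc$estimate[pc$source == "x" & pc$target == "m"],
               unname(o1), tolerance = 1e-8)
  expect_equal(pc$estimate[pc$source == "m" & pc$target == "y"],
               unname(o2[1]), tolerance = 1e-8)
  expect_equal(pc$estimate[pc$source == "x" & pc$target == "y"],
               unname(o2[2]), tolerance = 1e-8)
  # latent scores are unit variance (population)
  expect_equal(unname(apply(fit$scores, 2, function(v) mean(v^2))),
               rep(1, 3), tolerance = 1e-9)
})

test_that("identical blocks give a path coefficient of one", {
  set.seed(52)
  v <- rnorm(40)
  dat <- data.frame(a1 = v, a2 = v + 0, b1 = v, b2 = v)
  spec <- plspm_spec(list(A = c("a1", "a2"), B = c("b1", "b2")),
                     rbind(c("A", "B")))
  fit <- fit_plspm(dat, spec)
  expect_equal(fit$path_coefficients$estimate, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared[["B"]], 1, tolerance = 1e-9)
})

test_that("noise-free indicator blocks recover the latent regressions", {
  cfg <- synth_config(seed = 53, sem_loading = 1)
  sem <- generate_sem_data(cfg, n = 200)
  fit <- fit_plspm(sem$data, sem$spec)
  zs <- function(v) (v - mean(v)) / sd(v)
  with(sem$data, {
    o1 <- unname(coef(lm(zs(chem1) ~ zs(dose)))[2])
    o2 <- unname(coef(lm(zs(qual1) ~ zs(chem1)))[2])
    pc <- fit$path_coefficients
    expect_equal(pc$estimate[pc$target == "chemical"], o1, tolerance = 1e-6)
    expect_equal(pc$estimate[pc$target == "quality"], o2, tolerance = 1e-6)
  })
})

test_that("planted path coefficients are recovered at n = 1000", {
  ests <- sapply(1:6, function(s) {
    sem <- generate_sem_data(synth_config(seed = 53 + s), n = 1000)
    pc <- fit_plspm(sem$data, sem$spec)$path_coefficients
    c(pc$estimate[pc$target == "quality"], pc$estimate[pc$target == "yield"])
  })
  expect_lt(abs(mean(ests[1, ]) - 0.6), 0.05)
  expect_lt(abs(mean(ests[2, ]) - 0.3), 0.05)
})

test_that("GOF follows sqrt(mean communality x mean R2)", {
  set.seed(54)
  v <- rnorm(30)
  dat <- data.frame(x1 = v, y1 = v)          # perfect chain
  fit <- fit_plspm(dat, plspm_spec(list(x = "x1", y = "y1"),
                                   rbind(c("x", "y"))))
  expect_equal(gof(fit), 1, tolerance = 1e-9)
  sem <- generate_sem_data(synth_config(seed = 55), n = 400)
  f2 <- fit_plspm(sem$data, sem$spec)
  manual <- sqrt(mean(unlist(f2$loadings)^2) * mean(f2$r_squared))
  expect_equal(gof(f2), manual, tolerance = 1e-12)
  expect_false(gof_acceptable(0.4))
  expect_true(gof_acceptable(0.401))
  expect_false(gof_acceptable(1.2))
})

test_that("loading pruning removes strictly-below-threshold indicators", {
  mock <- structure(list(
    loadings = list(A = c(a1 = 0.49, a2 = 0.9), B = c(b1 = 0.5, b2 = 0.8)),
    spec = plspm_spec(list(A = c("a1", "a2"), B = c("b1", "b2")),
                      rbind(c("A", "B")))), class = "plspm_fit")
  red <- prune_loadings(mock)
  expect_equal(red$blocks$A, "a2")
  expect_equal(red$blocks$B, c("b1", "b2"))  # 0.5 retained (strict below)
  mock2 <- mock
  mock2$loadings$A <- c(a1 = 0.3, a2 = 0.4)
  expect_error(prune_loadings(mock2), "A")
  sem <- generate_sem_data(synth_config(seed = 56), n = 500,
                           weak_indicator = TRUE)
  fit <- fit_plspm(sem$data, sem$spec)
  red2 <- prune_loadings(fit)
  expect_false("chem_weak" %in% red2$blocks$chemical)
  expect_setequal(setdiff(sem$spec$blocks$chemical, red2$blocks$chemical),
                  "chem_weak")
})

test_that("sign-reversing an indicator flips its loading, not the GOF", {
  sem <- generate_sem_data(synth_config(seed = 57), n = 300)
  f1 <- fit_plspm(sem$data, sem$spec)
  dat2 <- sem$data
  dat2$chem2 <- -dat2$chem2
  f2 <- fit_plspm(dat2, sem$spec)
  expect_equal(unname(f2$loadings$chemical["chem2"]),
               -unname(f1$loadings$chemical["chem2"]), tolerance = 1e-6)
  expect_equal(gof(f2), gof(f1), tolerance = 1e-6)
})

test_that("bootstrap intervals are seed-deterministic and cover null paths", {
  set.seed(58)
  n <- 80
  x <- rnorm(n)
  dat <- data.frame(x1 = x, y1 = rnorm(n))   # true path 0
  spec <- plspm_spec(list(x = "x1", y = "y1"), rbind(c("x", "y")))
  b1 <- bootstrap_paths(dat, spec, n_boot = 99, seed = 9)
  b2 <- bootstrap_paths(dat, spec, n_boot = 99, seed = 9)
  expect_identical(b1, b2)
  b0 <- bootstrap_paths(dat, spec, n_boot = 0, seed = 9)
  expect_null(b0$lower)
  covered <- sapply(1:60, function(s) {
    set.seed(100 + s)
    d <- data.frame(x1 = rnorm(60), y1 = rnorm(60))
    ci <- bootstrap_paths(d, spec, n_boot = 99, seed = s)
    ci$lower <= 0 && 0 <= ci$upper
  })
  expect_gte(mean(covered), 0.85)
})

test_that("the spec constructor rejects cyclic and ill-formed models", {
  expect_error(plspm_spec(list(A = "a", B = "b"),
                          rbind(c("A", "B"), c("B", "A"))), "cycle")
  expect_error(plspm_spec(list(A = "a", B = "a"), rbind(c("A", "B"))),
               "more than one block")
  expect_error(plspm_spec(list(A = "a"), rbind(c("A", "Z"))), "unknown")
})
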