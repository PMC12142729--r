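random_dist <- function(n, seed, kind = "genetic") {
  set.seed(seed)
  pts <- matrix(rnorm(n * 3), n)
  dist_matrix(as.matrix(dist(pts)), paste0("s", seq_len(n)), kind, "test")
}

test_that("regressing a distance matrix on itself gives beta 1 and R2 1", {
  y <- random_dist(15, 1)
  fit <- mmrr(y, list(self = y), n_perm = 99, seed = 1)
  expect_equal(unname(fit$beta), 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(unname(fit$beta_p), 1 / 100)
})

test_that("mmrr coefficients equal plain OLS on the unfolded standardized triangles", {
  y <- random_dist(20, 2)
  x1 <- random_dist(20, 3, "geographic")
  x2 <- random_dist(20, 4, "environmental")
  fit <- mmrr(y, list(a = x1, b = x2), n_perm = 99, seed = 5)
  ols <- lm(scale(unfold(y)) ~ scale(unfold(x1)) + scale(unfold(x2)))
  expect_lt(max(abs(fit$beta - coef(ols)[-1])), 1e-10)
  expect_equal(fit$r_squared, summary(ols)$r.squared, tolerance = 1e-10)
  expect_equal(fit$f_statistic, unname(summary(ols)$fstatistic[1]),
               tolerance = 1e-8)
})

test_that("mmrr permutation p-values are seed-reproducible and stable in n_perm", {
  y <- random_dist(15, 6)
  x <- random_dist(15, 7)
  a <- mmrr(y, list(x = x), n_perm = 199, seed = 3)
  b <- mmrr(y, list(x = x), n_perm = 199, seed = 3)
  expect_identical(a$beta_p, b$beta_p)
  # strong-signal example: doubling permutations barely moves p
  self <- mmrr(y, list(x = y), n_perm = 199, seed = 3)
  self2 <- mmrr(y, list(x = y), n_perm = 399, seed = 3)
  expect_lt(abs(self$beta_p - self2$beta_p), 2 / 200)
})

test_that("mmrr rejects collinear predictor pairs by name", {
  x <- random_dist(12, 8)
  x2 <- x
  x2$values <- x$values * 2
  expect_error(mmrr(random_dist(12, 9), list(a = x, b = x2), n_perm = 99),
               "collinear.*(a.*b|b.*a)")
})

test_that("a real predictor is kept and pure noise eliminated by backward selection", {
  kept_signal <- 0; dropped_noise <- 0
  for (s in 1:5) {
    set.seed(s)
    x1 <- random_dist(20, 100 + s, "geographic")
    noise <- random_dist(20, 200 + s, "environmental")
    yv <- 2 * x1$values + matrix(0.3 * abs(rnorm(400)), 20)
    yv <- (yv + t(yv)) / 2; diag(yv) <- 0
    y <- dist_matrix(yv, x1$ids, "genetic", "sim")
    fit <- mmrr(y, list(signal = x1, noise = noise), n_perm = 99, seed = s)
    expect_gt(fit$beta["signal"], fit$beta["noise"])
    bk <- mmrr_backward(y, list(signal = x1, noise = noise), alpha = 0.05,
                        n_perm = 99, seed = s)
    kept_signal <- kept_signal + ("signal" %in% bk$kept_predictors)
    dropped_noise <- dropped_noise + !("noise" %in% bk$kept_predictors)
  }
  expect_gte(kept_signal, 4)
  expect_gte(dropped_noise, 4)
})

test_that("backward elimination with alpha 1 or all-significant predictors is a no-op", {
  y <- random_dist(15, 10)
  x1 <- random_dist(15, 11)
  noise <- random_dist(15, 12)
  bk <- mmrr_backward(y, list(a = x1, b = noise), alpha = 1.0, n_perm = 99,
                      seed = 1)
  expect_setequal(bk$kept_predictors, c("a", "b"))
  expect_length(bk$eliminated, 0)
  # self-regression is always significant: identical to plain mmrr
  bk2 <- mmrr_backward(y, list(self = y), alpha = 0.05, n_perm = 99, seed = 2)
  plain <- mmrr(y, list(self = y), n_perm = 99, seed = 2)
  expect_equal(bk2$beta, plain$beta)
})

test_that("I-spline basis has 0/1 boundaries, monotone continuous columns", {
  kn <- c(0, 0.3, 1)
  expect_equal(unname(ispline_basis(0, kn)[1, ]), c(0, 0, 0))
  expect_equal(unname(ispline_basis(1, kn)[1, ]), c(1, 1, 1))
  xs <- seq(0, 1, length.out = 1001)
  b <- ispline_basis(xs, kn)
  expect_true(all(diff(b[, 1]) >= -1e-12))
  expect_true(all(diff(b[, 2]) >= -1e-12))
  expect_true(all(diff(b[, 3]) >= -1e-12))
  expect_lt(max(abs(diff(b[, 2]))), 0.01)  # continuity at the knot
  expect_warning(ispline_basis(c(-0.5, 2), kn), "clamped")
  expect_error(ispline_basis(0.5, c(0, 0, 1)))
})

test_that("a zero response yields a null GDM with bounded predictions", {
  n <- 12
  ids <- paste0("s", seq_len(n))
  y0 <- dist_matrix(matrix(0, n, n), ids, "genetic", "zero")
  set.seed(1)
  env <- cbind(temp = rnorm(n))
  rownames(env) <- ids
  fit <- gdm_fit(y0, env = env, n_perm = 2)
  expect_equal(unname(unlist(fit$coefficients)), rep(0, 3))
  expect_equal(fit$intercept, 0)
  expect_equal(fit$deviance_explained, 100)
  expect_true(all(fit$fitted >= 0 & fit$fitted < 1))
})

test_that("gdm recovers a known single-predictor monotone relationship", {
  dev <- numeric(5); imp_ok <- logical(5)
  for (s in 1:5) {
    set.seed(s)
    n <- 25
    ids <- paste0("s", seq_len(n))
    env <- cbind(active = runif(n), inert = runif(n))
    rownames(env) <- ids
    f <- function(x) 1.5 * x^2          # monotone transform on [0,1]
    eta <- abs(outer(f(env[, 1]), f(env[, 1]), "-"))
    d <- 1 - exp(-(0.1 + eta))
    y <- dist_matrix(d - diag(diag(d)), ids, "genetic", "gdmsim")
    fit <- gdm_fit(y, env = env, n_perm = 5, seed = s)
    dev[s] <- fit$deviance_explained
    imp_ok[s] <- fit$importance["active"] > fit$importance["inert"]
    expect_true(all(unlist(fit$coefficients) >= 0))
    expect_true(all(fit$fitted >= 0 & fit$fitted < 1))
  }
  expect_gte(median(dev), 80)
  expect_gte(sum(imp_ok), 4)
})

test_that("gdm rejects unscaled dissimilarities and clamps exact ones", {
  n <- 10
  ids <- paste0("s", seq_len(n))
  set.seed(2)
  env <- cbind(v = rnorm(n)); rownames(env) <- ids
  big <- dist_matrix(matrix(5, n, n) - diag(5, n), ids, "genetic", "big")
  expect_error(gdm_fit(big, env = env), "rescale")
  ones <- matrix(1, n, n) - diag(1, n)
  y1 <- dist_matrix(ones, ids, "genetic", "ones")
  fit <- gdm_fit(y1, env = env, n_perm = 2)
  expect_true(all(is.finite(fit$fitted)))
})

test_that("gdm_map transforms monotonically and errors on degenerate models", {
  sim <- small_sim(seed = 31, n = 30, l = 150)
  env <- extract_env(sim$env_layers, sim$coords)
  y <- rescale_dist(genetic_distance(impute_median(sim$genotypes),
                                     "euclidean"))
  fit <- gdm_fit(y, env = env, coords = sim$coords, use_geo = TRUE,
                 n_perm = 2, seed = 1)
  maps <- gdm_map(fit, sim$env_layers)
  # monotone: cell ordering by raw value is preserved by the transform
  raw <- as.vector(sim$env_layers[[1]]$values)
  tr <- as.vector(maps$transformed[[1]]$values)
  ord <- order(raw)
  expect_true(all(diff(tr[ord]) >= -1e-9))
  expect_length(maps$rgb, 3)
  for (ch in maps$rgb) {
    v <- ch$values[!is.na(ch$values)]
    expect_gte(min(v), 0); expect_lte(max(v), 255)
  }
  # degenerate model: zero coefficients
  fit0 <- fit
  fit0$coefficients <- lapply(fit0$coefficients, function(x) x * 0)
  expect_error(gdm_map(fit0, sim$env_layers), "degenerate")
  expect_error(gdm_map(fit, sim$env_layers[1]), "missing predictor")
})
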