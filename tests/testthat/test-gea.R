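test_that("single-predictor RDA has one axis whose eigenvalue is the fitted variance", {
  sim <- small_sim(seed = 41, n = 25, l = 60)
  set.seed(1)
  env <- cbind(temp = rnorm(25))
  m <- rda_fit(sim$genotypes, env)
  expect_length(m$eigenvalues, 1)
  y <- scale(sim$genotypes$values * 1.0, scale = FALSE)
  x <- scale(env)
  fitted <- x %*% solve(crossprod(x), crossprod(x, y))
  expect_equal(m$eigenvalues[1], sum(fitted^2) / (25 - 1), tolerance = 1e-10)
})

test_that("RDA eigenstructure matches an independent constrained-ordination oracle", {
  skip_if_not_installed("vegan")
  sim <- small_sim(seed = 42, n = 30, l = 100)
  env <- extract_env(sim$env_layers, sim$coords)
  m <- rda_fit(sim$genotypes, env)
  v <- vegan::rda(X = sim$genotypes$values * 1.0, Y = scale(env))
  expect_equal(unname(m$eigenvalues), unname(v$CCA$eig), tolerance = 1e-8)
  expect_equal(m$adj_r_squared, vegan::RsquareAdj(v)$adj.r.squared,
               tolerance = 1e-8)
  # locus loadings agree up to per-axis sign
  or <- v$CCA$v
  for (ax in seq_along(m$eigenvalues)) {
    agree <- min(max(abs(m$loadings[, ax] - or[, ax])),
                 max(abs(m$loadings[, ax] + or[, ax])))
    expect_lt(agree / max(abs(or[, ax])), 1e-6)
  }
})

test_that("partial RDA with empty conditioning equals plain RDA", {
  sim <- small_sim(seed = 43, n = 20, l = 50)
  env <- extract_env(sim$env_layers, sim$coords)
  a <- rda_fit(sim$genotypes, env, covariates = NULL)
  b <- rda_fit(sim$genotypes, env, covariates = matrix(nrow = 20, ncol = 0))
  expect_equal(a$eigenvalues, b$eigenvalues, tolerance = 1e-10)
  expect_equal(a$loadings, b$loadings, tolerance = 1e-10)
  # constrained variance never exceeds total genotype variance
  expect_lte(sum(a$eigenvalues), a$total_variance + 1e-10)
})

test_that("partial RDA removes covariate-aligned structure", {
  sim <- small_sim(seed = 44, n = 30, l = 120, demes = 2, div = 0.5)
  env <- extract_env(sim$env_layers, sim$coords)
  deme_cov <- matrix(as.numeric(sim$truth$deme == 1), ncol = 1)
  full <- rda_fit(sim$genotypes, env)
  part <- rda_fit(sim$genotypes, env, covariates = deme_cov)
  expect_equal(part$call_type, "pRDA")
  expect_lt(sum(part$eigenvalues), sum(full$eigenvalues))
})

test_that("z-score outliers flag a planted extreme locus and respect thresholds", {
  sim <- small_sim(seed = 45, n = 25, l = 80)
  env <- extract_env(sim$env_layers, sim$coords)
  m <- rda_fit(sim$genotypes, env)
  m$loadings[7, 1] <- median(m$loadings[, 1]) +
    10 * sd(m$loadings[, 1])           # constructed outlier
  res <- rda_outliers_z(m, n_axes = 1, z_threshold = 3)
  expect_true(res$outlier[7])
  expect_lte(sum(res$outlier), 3)
  expect_false(any(rda_outliers_z(m, 1, z_threshold = Inf)$outlier))
  # constant loadings cannot be outliers
  m$loadings[, 1] <- 1
  expect_warning(res0 <- rda_outliers_z(m, 1, 3), "zero spread")
  expect_false(any(res0$outlier))
})

test_that("Mahalanobis p-values are calibrated on chi-squared distances", {
  set.seed(7)
  m <- structure(list(
    loadings = matrix(rnorm(2000), 1000, 2,
                      dimnames = list(paste0("l", 1:1000), NULL)),
    eigenvalues = c(2, 1)), class = "rda_model")
  res <- rda_outliers_p(m, n_axes = 2, fdr = 0.05)
  expect_lt(abs(res$gif - 1), 0.1)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  # q-values are monotone in p-values
  ord <- order(res$p_value)
  expect_true(all(diff(res$q_value[ord]) >= -1e-12))
  expect_error(rda_outliers_p(
    structure(list(loadings = matrix(rnorm(4), 2, 2),
                   eigenvalues = c(1, 1)), class = "rda_model"), 2), "axes")
})

test_that("BH q-values match the direct step-up formula", {
  set.seed(8)
  for (p in list(runif(50), c(0.001, 0.5, 0.04, 0.04, 1), runif(1)^2)) {
    expect_equal(bh_qvalues(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_equal(bh_qvalues(0.37), 0.37)  # single test: q = p
})

test_that("variance partitioning separates orthogonal blocks and detects confounding", {
  sim <- small_sim(seed = 46, n = 40, l = 200, demes = 2, div = 0.4)
  set.seed(3)
  env <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("e1", "e2")))
  struct <- matrix(as.numeric(sim$truth$deme == 1), ncol = 1,
                   dimnames = list(NULL, "deme"))
  # orthogonalize env against structure so confounding is ~0 by construction
  env <- env - struct %*% solve(crossprod(struct), crossprod(struct, env))
  vp <- variance_partition(sim$genotypes, list(env = env, struct = struct))
  full <- vp$adj_r_squared[vp$fraction == "full"]
  conf <- vp$adj_r_squared[vp$fraction == "confounded"]
  indep <- vp$adj_r_squared[grepl("independent", vp$fraction)]
  expect_equal(sum(indep) + conf, full, tolerance = 1e-6)
  expect_lt(abs(conf), 0.02)
  # duplicated block: everything confounded
  vp2 <- variance_partition(sim$genotypes,
                            list(a = struct, b = struct + 0.01 *
                                   matrix(rnorm(40), 40, 1)))
  indep2 <- vp2$adj_r_squared[grepl("independent", vp2$fraction)]
  conf2 <- vp2$adj_r_squared[vp2$fraction == "confounded"]
  full2 <- vp2$adj_r_squared[vp2$fraction == "full"]
  expect_lt(max(abs(indep2)), 0.02)
  expect_equal(conf2, full2, tolerance = 0.05)
  # single block degenerates to the full-model fit
  vp3 <- variance_partition(sim$genotypes, list(env = env))
  expect_equal(nrow(vp3), 1L)
  expect_equal(vp3$adj_r_squared, rda_fit(sim$genotypes, env)$adj_r_squared)
})

test_that("lfmm with k = 0 reduces to per-locus OLS", {
  sim <- small_sim(seed = 47, n = 30, l = 40)
  env <- extract_env(sim$env_layers, sim$coords)
  lf <- lfmm_ridge(sim$genotypes, env, k = 0)
  for (j in c(3, 17, 40)) {
    o <- summary(lm(sim$genotypes$values[, j] ~ scale(env)))$coefficients
    expect_equal(unname(lf$p_raw[j, 1]), o[2, 4], tolerance = 1e-8)
    expect_equal(unname(lf$p_raw[j, 2]), o[3, 4], tolerance = 1e-8)
  }
  expect_error(lfmm_ridge(sim$genotypes, env, k = 30), "below")
})

test_that("lfmm tests are invariant to rescaling the environment", {
  sim <- small_sim(seed = 48, n = 25, l = 60)
  env <- extract_env(sim$env_layers, sim$coords)
  a <- lfmm_ridge(sim$genotypes, env, k = 2)
  b <- lfmm_ridge(sim$genotypes, env * 100 + 5, k = 2)
  expect_equal(a$zscores, b$zscores, tolerance = 1e-8)
})

test_that("latent-factor selection behaves on structured and unstructured data", {
  set.seed(9)
  noise <- dosage_matrix(matrix(rbinom(50 * 300, 2, 0.5), 50, 300))
  expect_equal(select_latent_k(noise, "tracy_widom", alpha = 0.01)$k, 0)
  sim <- small_sim(seed = 49, n = 60, l = 400, demes = 3, div = 0.4,
                   ibd_strength = 0)
  g <- sim$genotypes
  co <- sim$coords
  ks <- c(tw = select_latent_k(g, "tracy_widom")$k,
          elbow = select_latent_k(g, "quick_elbow")$k,
          cv = select_latent_k(g, "cluster_cv", k_range = 1:5, seed = 2,
                               coords = co)$k,
          km = select_latent_k(g, "kmeans", k_range = 1:5, seed = 2)$k)
  # demes or demes-1 both accepted: K in {2, 3}
  expect_true(all(ks >= 2 & ks <= 3))
  expect_equal(select_latent_k(g, "kmeans", k_range = 1)$k, 1)
  expect_error(select_latent_k(g, "cluster_cv"), "coordinates")
})

test_that("GEA TSV export round-trips the outlier table", {
  sim <- small_sim(seed = 50, n = 20, l = 30)
  env <- extract_env(sim$env_layers, sim$coords)
  lf <- lfmm_ridge(sim$genotypes, env, k = 1)
  res <- lfmm_outliers(lf, 1, fdr = 0.1)
  path <- tempfile(fileext = ".tsv")
  write_gea_tsv(res, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 30)
  expect_equal(tab$p, unname(res$p_value), tolerance = 1e-6)
})
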