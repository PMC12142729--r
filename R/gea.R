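# Genotype-environment association: redundancy analysis (RDA / partial RDA)
# with Z-score and Mahalanobis outlier detection, ridge latent factor mixed
# models (LFMM), variance partitioning and latent-factor (K) selection.

residualize <- function(m, covariates) {
  # residuals of each column of m on covariates (with intercept)
  cv <- cbind(1, as.matrix(covariates))
  m - cv %*% solve(crossprod(cv), crossprod(cv, m))
}

#' Fit a (partial) redundancy analysis of genotypes on environment
#'
#' Centers the genotype columns and standardizes the predictors; with
#' covariates, both genotypes and predictors are first residualized on the
#' covariates (partial RDA). Fitted values are the projection of the genotype
#' matrix onto the predictor column space, and the constrained axes are the
#' principal components of those fitted values. Adjusted R-squared uses the
#' Ezekiel correction.
#'
#' @param g a complete (imputed) `dosage_matrix`.
#' @param env individuals x variables environment matrix.
#' @param covariates optional matrix of conditioning covariates (pRDA).
#' @return An `rda_model`: `eigenvalues`, `loadings` (loci x axes),
#'   `site_scores`, `biplot` (predictor scores), `r_squared`,
#'   `adj_r_squared`, `call_type`.
#' @export
rda_fit <- function(g, env, covariates = NULL) {
  stopifnot(inherits(g, "dosage_matrix"))
  if (anyNA(g$values)) stop("missing genotypes present: impute first")
  y <- scale(g$values * 1.0, center = TRUE, scale = FALSE)
  env <- as.matrix(env)
  if (is.null(colnames(env))) colnames(env) <- paste0("env", seq_len(ncol(env)))
  x <- scale(env)
  partial <- !is.null(covariates) && NCOL(covariates) > 0 &&
    length(covariates) > 0
  if (partial) {
    cv <- scale(as.matrix(covariates))
    y <- residualize(y, cv)
    x <- residualize(x, cv)
  }
  kp <- kappa(crossprod(x), exact = TRUE)
  if (!is.finite(kp) || kp > 1e10) stop("collinear predictors in RDA")
  n <- nrow(y)
  fitted <- x %*% solve(crossprod(x), crossprod(x, y))
  sv <- svd(fitted)
  pos <- sv$d^2 / (n - 1) > 1e-12 * max(sv$d^2 / (n - 1), 1e-300)
  n_axes <- min(sum(pos), ncol(x))
  eig <- (sv$d^2 / (n - 1))[seq_len(n_axes)]
  loadings <- sv$v[, seq_len(n_axes), drop = FALSE]
  rownames(loadings) <- g$locus_ids
  site_scores <- sv$u[, seq_len(n_axes), drop = FALSE] %*%
    diag(sv$d[seq_len(n_axes)], n_axes)
  biplot <- stats::cor(x, site_scores)
  tot_var <- sum(y^2) / (n - 1)
  r2 <- sum(eig) / tot_var
  p <- ncol(x)
  adj <- 1 - (1 - r2) * (n - 1) / (n - 1 - p)
  structure(list(eigenvalues = eig, loadings = loadings,
                 site_scores = site_scores, biplot = biplot,
                 r_squared = r2, adj_r_squared = adj,
                 total_variance = tot_var,
                 n = n, n_predictors = p,
                 condition_names = if (partial) colnames(as.matrix(covariates))
                                   else NULL,
                 call_type = if (partial) "pRDA" else "RDA"),
            class = "rda_model")
}

#' @export
print.rda_model <- function(x, ...) {
  cat(sprintf("<rda_model> %s: %d constrained axes, adj R2 = %.4f\n",
              x$call_type, length(x$eigenvalues), x$adj_r_squared))
  invisible(x)
}

gea_result <- function(locus_ids, statistic, p_value, q_value, outlier,
                       method, gif = NA_real_) {
  structure(list(locus_ids = locus_ids, statistic = statistic,
                 p_value = p_value, q_value = q_value, outlier = outlier,
                 method = method, gif = gif),
            class = "gea_result")
}

#' @export
print.gea_result <- function(x, ...) {
  cat(sprintf("<gea_result> %s: %d loci, %d outliers (gif = %.3g)\n",
              x$method, length(x$locus_ids), sum(x$outlier), x$gif))
  invisible(x)
}

#' RDA outlier loci by Z-scores of axis loadings
#'
#' Standardizes the locus loadings on each retained axis; a locus is an
#' outlier if its |z| exceeds `z_threshold` on any axis. A flag-based method:
#' no p-values are produced.
#'
#' @param model an `rda_model`.
#' @param n_axes number of leading constrained axes to scan.
#' @param z_threshold outlier threshold in standard-deviation units.
#' @return A `gea_result` with the max |z| over axes as statistic.
#' @export
rda_outliers_z <- function(model, n_axes = length(model$eigenvalues),
                           z_threshold = 3) {
  stopifnot(n_axes >= 1, n_axes <= ncol(model$loadings))
  l <- model$loadings[, seq_len(n_axes), drop = FALSE]
  sds <- apply(l, 2, stats::sd)
  if (any(sds == 0)) {
    warning("axis loadings with zero spread: no outliers on those axes")
    sds[sds == 0] <- Inf
  }
  z <- abs(scale(l, center = TRUE, scale = sds))
  zmax <- apply(z, 1, max)
  gea_result(rownames(model$loadings), zmax,
             p_value = rep(NA_real_, nrow(l)),
             q_value = rep(NA_real_, nrow(l)),
             outlier = zmax > z_threshold,
             method = "rda_z")
}

#' Benjamini-Hochberg q-values
#' @param p vector of p-values.
#' @return BH-adjusted q-values (monotone step-up).
#' @export
bh_qvalues <- function(p) stats::p.adjust(p, method = "BH")

#' RDA outlier loci by Mahalanobis distance p-values
#'
#' Computes a robust Mahalanobis distance of each locus in the space of the
#' leading `n_axes` loadings (median/MAD standardization per axis), calibrates
#' it by the genomic inflation factor `gif = median(D2) / median(chi2_k)`, and
#' converts to upper-tail chi-squared p-values with `n_axes` degrees of
#' freedom. q-values are Benjamini-Hochberg; outliers have `q < fdr`.
#'
#' @param model an `rda_model`.
#' @param n_axes number of leading axes used.
#' @param fdr false-discovery-rate threshold.
#' @return A `gea_result` with D-squared statistics, p, q and gif.
#' @export
rda_outliers_p <- function(model, n_axes = length(model$eigenvalues),
                           fdr = 0.05) {
  stopifnot(n_axes >= 1, n_axes <= ncol(model$loadings))
  l <- model$loadings[, seq_len(n_axes), drop = FALSE]
  if (nrow(l) <= n_axes)
    stop("more axes than loci: Mahalanobis distance undefined")
  med <- apply(l, 2, stats::median)
  madv <- apply(l, 2, stats::mad)
  if (any(madv == 0)) stop("degenerate loadings: zero MAD on some axis")
  z <- sweep(sweep(l, 2, med), 2, madv, "/")
  d2 <- rowSums(z^2)
  gif <- stats::median(d2) / stats::qchisq(0.5, df = n_axes)
  p <- stats::pchisq(d2 / gif, df = n_axes, lower.tail = FALSE)
  q <- bh_qvalues(p)
  gea_result(rownames(model$loadings), d2, p, q, outlier = q < fdr,
             method = "rda_p", gif = gif)
}

#' Variance partitioning across explanatory blocks with (p)RDA
#'
#' For named blocks of predictors (e.g. environment, population structure,
#' geography), reports the full-model adjusted R-squared, each block's
#' independent contribution (the adjusted R-squared of the pRDA of the
#' genotypes on that block conditioned on all other blocks), and the
#' confounded remainder (full minus the sum of independent fractions). Small
#' negative adjusted fractions are reported as computed.
#'
#' @param g a complete `dosage_matrix`.
#' @param blocks named list of individuals x variables matrices.
#' @return data.frame with one row per fraction.
#' @export
variance_partition <- function(g, blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  if (is.null(names(blocks))) names(blocks) <- paste0("block", seq_along(blocks))
  blocks <- lapply(blocks, as.matrix)
  full_x <- do.call(cbind, blocks)
  full <- rda_fit(g, full_x)
  rows <- data.frame(fraction = "full", adj_r_squared = full$adj_r_squared)
  if (length(blocks) == 1) return(rows)
  indep <- vapply(seq_along(blocks), function(i) {
    others <- do.call(cbind, blocks[-i])
    rda_fit(g, blocks[[i]], covariates = others)$adj_r_squared
  }, numeric(1))
  rows <- rbind(rows,
                data.frame(fraction = paste0("independent_", names(blocks)),
                           adj_r_squared = indep),
                data.frame(fraction = "confounded",
                           adj_r_squared = full$adj_r_squared - sum(indep)))
  rows
}

#' Ridge latent factor mixed model for genotype-environment association
#'
#' Estimates `K` latent factors alongside per-locus environmental effects by
#' alternating between (1) extracting the top-K singular structure of the
#' genotype matrix after removing the current environmental component and
#' (2) ridge-regressing the genotypes on the environment given the latent
#' factors, iterated to convergence. Genotype columns are standardized to
#' unit variance so the ridge penalty `lambda` is comparable across
#' datasets; the penalty shifts variance that is confounded between
#' environment and population structure onto the latent factors, which keeps
#' the per-locus tests calibrated. Per-locus significance comes from OLS
#' z-statistics of each environmental variable with the latent factors as
#' covariates; z-squared statistics are calibrated by the genomic inflation
#' factor (median rule) and converted to chi-squared p-values. Raw
#' t-distribution p-values are kept in `p_raw` (with `k = 0` these equal
#' plain per-locus OLS p-values).
#'
#' @param g a complete `dosage_matrix`.
#' @param env individuals x variables environment matrix.
#' @param k number of latent factors (>= 0).
#' @param lambda ridge penalty on the environmental effects.
#' @param max_iter,tol alternation controls.
#' @return An `lfmm_model`: `effects` (loci x variables), `zscores`,
#'   `p_value` (gif-calibrated), `p_raw`, `gif` (per variable), `K`, `U`
#'   (latent factors).
#' @export
lfmm_ridge <- function(g, env, k = 2, lambda = 5, max_iter = 50,
                       tol = 1e-8) {
  stopifnot(inherits(g, "dosage_matrix"), k >= 0)
  if (anyNA(g$values)) stop("missing genotypes present: impute first")
  y <- scale(g$values * 1.0)  # unit-variance loci: lambda is scale-free
  y[, attr(y, "scaled:scale") == 0] <- 0
  x <- scale(as.matrix(env))
  if (is.null(colnames(x))) colnames(x) <- paste0("env", seq_len(ncol(x)))
  n <- nrow(y); l <- ncol(y); d <- ncol(x)
  if (k >= min(n, l)) stop("k must be below min(n_individuals, n_loci)")
  ridge_b <- function(resid) {
    solve(crossprod(x) + diag(lambda, d), crossprod(x, resid))
  }
  b <- ridge_b(y)
  w <- matrix(0, n, l)
  if (k > 0) {
    loss_old <- Inf
    for (it in seq_len(max_iter)) {
      sv <- svd(y - x %*% b, nu = k, nv = k)
      w <- sv$u %*% diag(sv$d[seq_len(k)], k) %*% t(sv$v)
      b <- ridge_b(y - w)
      loss <- sum((y - w - x %*% b)^2) + lambda * sum(b^2)
      if (is.finite(loss_old) && abs(loss_old - loss) <= tol * loss_old) break
      loss_old <- loss
    }
  }
  # association testing: per-locus OLS with latent factors as covariates
  u <- if (k > 0) svd(w, nu = k, nv = 0)$u else NULL
  design <- cbind(1, x, u)
  q_r <- qr(design)
  coefs <- qr.coef(q_r, y)
  res <- y - design %*% coefs
  df <- n - ncol(design)
  sigma2 <- colSums(res^2) / df
  xtx_inv_diag <- diag(chol2inv(qr.R(q_r)))
  env_idx <- 1 + seq_len(d)
  z <- matrix(0, l, d, dimnames = list(g$locus_ids, colnames(x)))
  p_raw <- z
  for (j in seq_len(d)) {
    se <- sqrt(sigma2 * xtx_inv_diag[env_idx[j]])
    zj <- coefs[env_idx[j], ] / se
    zj[se == 0] <- 0  # monomorphic / perfectly fitted loci carry no signal
    z[, j] <- zj
    p_raw[, j] <- 2 * stats::pt(abs(zj), df = df, lower.tail = FALSE)
  }
  gif <- apply(z, 2, function(zz)
    stats::median(zz^2) / stats::qchisq(0.5, df = 1))
  p_cal <- sapply(seq_len(d), function(j)
    stats::pchisq(z[, j]^2 / gif[j], df = 1, lower.tail = FALSE))
  p_cal <- matrix(p_cal, nrow = l, dimnames = dimnames(z))
  structure(list(K = k, effects = t(coefs[env_idx, , drop = FALSE]),
                 zscores = z, p_value = p_cal, p_raw = p_raw,
                 gif = gif, U = u, locus_ids = g$locus_ids),
            class = "lfmm_model")
}

#' @export
print.lfmm_model <- function(x, ...) {
  cat(sprintf("<lfmm_model> K=%d, %d loci x %d variables, gif = %s\n",
              x$K, nrow(x$zscores), ncol(x$zscores),
              paste(sprintf("%.3g", x$gif), collapse = ", ")))
  invisible(x)
}

#' Flag LFMM outlier loci at a false-discovery-rate threshold
#' @param model an `lfmm_model`.
#' @param variable environment variable (name or index).
#' @param fdr Benjamini-Hochberg threshold.
#' @param calibrated use gif-calibrated p-values?
#' @return A `gea_result`.
#' @export
lfmm_outliers <- function(model, variable = 1, fdr = 0.1,
                          calibrated = TRUE) {
  p <- if (calibrated) model$p_value[, variable] else model$p_raw[, variable]
  q <- bh_qvalues(p)
  gea_result(model$locus_ids, model$zscores[, variable]^2, p, q,
             outlier = q < fdr, method = "lfmm_ridge",
             gif = model$gif[[variable]])
}

# 90th/95th/99th/99.9th percentiles of the Tracy-Widom TW1 distribution
tw1_critical <- c("0.1" = 0.4501, "0.05" = 0.9793, "0.01" = 2.0234,
                  "0.001" = 3.2724)

tracy_widom_k <- function(x, alpha = 0.01, k_max = NULL) {
  # sequential test of leading eigenvalues of the normalized genotype
  # covariance (Patterson-style): stop at the first non-significant one
  crit <- tw1_critical[as.character(alpha)]
  if (is.na(crit)) stop("alpha must be one of 0.1, 0.05, 0.01, 0.001")
  p <- colMeans(x) / 2
  keep <- p > 0 & p < 1
  xs <- sweep(x[, keep, drop = FALSE], 2, 2 * p[keep])
  xs <- sweep(xs, 2, sqrt(p[keep] * (1 - p[keep])), "/")
  n_ind <- nrow(xs); n_loci <- ncol(xs)
  ev <- svd(xs, nu = 0, nv = 0)$d^2 / n_loci
  ev <- ev[ev > 1e-12]
  if (is.null(k_max)) k_max <- length(ev) - 1
  k <- 0
  for (i in seq_len(min(k_max, length(ev) - 1))) {
    m <- n_ind - i + 1          # samples remaining after stripping i-1 axes
    lam <- ev[i:length(ev)]
    nn <- n_loci
    ll <- (m * lam[1]) / sum(lam)
    mu <- (sqrt(nn - 1) + sqrt(m))^2 / nn
    sg <- ((sqrt(nn - 1) + sqrt(m)) / nn) *
      (1 / sqrt(nn - 1) + 1 / sqrt(m))^(1 / 3)
    tw <- (ll - mu) / sg
    if (tw > crit) k <- i else break
  }
  k
}

quick_elbow_k <- function(ev, low_fraction = 0.08) {
  ratios <- ev / ev[1]
  below <- which(ratios < low_fraction)
  if (length(below) == 0) return(length(ev))
  max(below[1] - 1, 1)
}

kmeans_bic_k <- function(scores, k_range, seed) {
  set.seed(seed)
  n <- nrow(scores); d <- ncol(scores)
  bics <- vapply(k_range, function(k) {
    km <- if (k == 1)
      list(tot.withinss = sum(scale(scores, scale = FALSE)^2))
    else stats::kmeans(scores, centers = k, nstart = 10)
    n * log(km$tot.withinss / n) + log(n) * k * d
  }, numeric(1))
  k_range[which.min(bics)]
}

#' Choose the number of latent factors / genetic clusters
#'
#' Four selection rules over the imputed genotype matrix:
#' \describe{
#'   \item{tracy_widom}{sequential Tracy-Widom tests of the leading
#'     eigenvalues of the normalized genotype covariance at `alpha`.}
#'   \item{quick_elbow}{smallest K whose next eigenvalue falls below a fixed
#'     fraction (0.08) of the leading eigenvalue.}
#'   \item{cluster_cv}{masked-entry cross-validation of the spatial
#'     clustering model (see [select_k()]); requires `coords`.}
#'   \item{kmeans}{K minimizing the BIC of k-means on principal-component
#'     scores over `k_range`.}
#' }
#'
#' @param g a complete `dosage_matrix`.
#' @param method selection rule.
#' @param alpha Tracy-Widom significance level (0.1, 0.05, 0.01 or 0.001).
#' @param k_range candidate K values (cluster_cv, kmeans).
#' @param seed integer seed.
#' @param coords a [sample_coords()] table (cluster_cv only).
#' @return list with `k` and method diagnostics.
#' @export
select_latent_k <- function(g, method = c("tracy_widom", "quick_elbow",
                                          "cluster_cv", "kmeans"),
                            alpha = 0.01, k_range = 1:5, seed = 1,
                            coords = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(g, "dosage_matrix"))
  if (anyNA(g$values)) stop("missing genotypes present: impute first")
  x <- g$values * 1.0
  if (method == "tracy_widom")
    return(list(k = tracy_widom_k(x, alpha = alpha), method = method))
  if (method == "cluster_cv") {
    if (is.null(coords)) stop("cluster_cv requires coordinates")
    sk <- select_k(g, coords, k_range = k_range, mode = "auto", seed = seed)
    return(list(k = sk$chosen_k, method = method, table = sk$table))
  }
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc, nu = min(10, nrow(x) - 1), nv = 0)
  ev <- sv$d^2 / (nrow(x) - 1)
  if (method == "quick_elbow")
    return(list(k = quick_elbow_k(ev[ev > 1e-12]), method = method,
                eigenvalues = ev))
  scores <- sv$u %*% diag(sv$d[seq_len(ncol(sv$u))], ncol(sv$u))
  list(k = kmeans_bic_k(scores, k_range, seed), method = method)
}

#' Write per-locus GEA results as TSV
#' @param result a `gea_result`.
#' @param path output path.
#' @export
write_gea_tsv <- function(result, path) {
  df <- data.frame(locus = result$locus_ids, statistic = result$statistic,
                   p = result$p_value, q = result$q_value,
                   outlier = result$outlier, method = result$method)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
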