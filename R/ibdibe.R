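# Isolation by distance / environment / resistance: multiple matrix
# regression with randomization (MMRR) and generalized dissimilarity
# modelling (GDM) on pairwise distance matrices.

#' Unfold the strict lower triangle of a square matrix to a vector
#' @param m square matrix.
#' @return numeric vector of the n(n-1)/2 pairwise entries.
#' @export
unfold <- function(m) {
  if (inherits(m, "dist_matrix")) m <- m$values
  m[lower.tri(m)]
}

check_same_ids <- function(y, xs) {
  for (x in xs)
    if (!identical(y$ids, x$ids))
      stop("all distance matrices must share the same ids and order")
}

mmrr_fit_core <- function(yv, xmat) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, xmat), yv)
  coefs <- fit$coefficients
  res <- fit$residuals
  n <- length(yv)
  p <- ncol(xmat)
  rss <- sum(res^2)
  tss <- sum((yv - mean(yv))^2)
  sigma2 <- rss / (n - p - 1)
  xtx_inv <- chol2inv(chol(crossprod(cbind(1, xmat))))
  se <- sqrt(diag(xtx_inv) * sigma2)
  tstat <- coefs / se
  r2 <- 1 - rss / tss
  fstat <- (tss - rss) / p / (rss / (n - p - 1))
  list(coef = coefs[-1], tstat = tstat[-1], r2 = r2, f = fstat)
}

#' Multiple matrix regression with randomization (MMRR)
#'
#' Regresses the unfolded, standardized lower triangle of a genetic distance
#' matrix on those of one or more predictor distance matrices by OLS.
#' Significance is assessed by jointly permuting the rows and columns of the
#' response matrix, refitting, and comparing |t| statistics (per coefficient)
#' and the F statistic (whole model) against their permutation distributions:
#' `p = (count(perm >= observed) + 1) / (n_perm + 1)`.
#'
#' @param y response `dist_matrix` (genetic distances).
#' @param xs named list of predictor `dist_matrix` objects.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutations.
#' @return An `mmrr_result`: standardized coefficients (`beta`), per-predictor
#'   permutation p-values (`beta_p`), `r_squared`, `f_statistic`, `f_p`,
#'   `n_perm` and `kept_predictors`.
#' @export
mmrr <- function(y, xs, n_perm = 999, seed = 1) {
  stopifnot(inherits(y, "dist_matrix"), n_perm >= 99)
  if (inherits(xs, "dist_matrix")) xs <- list(x1 = xs)
  if (is.null(names(xs)) || any(names(xs) == ""))
    names(xs) <- paste0("x", seq_along(xs))
  check_same_ids(y, xs)
  n <- length(y$ids)
  yv <- as.vector(scale(unfold(y)))
  xmat <- sapply(xs, function(x) as.vector(scale(unfold(x))))
  xmat <- matrix(xmat, ncol = length(xs),
                 dimnames = list(NULL, names(xs)))
  if (ncol(xmat) > 1) {
    kp <- kappa(cbind(1, xmat), exact = TRUE)
    if (kp > 1e10) {
      cc <- stats::cor(xmat)
      diag(cc) <- 0
      worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
      stop("collinear predictors: ", colnames(xmat)[worst[1]], " and ",
           colnames(xmat)[worst[2]])
    }
  }
  obs <- mmrr_fit_core(yv, xmat)
  set.seed(seed)
  ge_t <- rep(0L, ncol(xmat))
  ge_f <- 0L
  ymat <- y$values
  for (b in seq_len(n_perm)) {
    perm <- sample(n)
    ypv <- as.vector(scale(unfold(ymat[perm, perm])))
    pf <- mmrr_fit_core(ypv, xmat)
    ge_t <- ge_t + (abs(pf$tstat) >= abs(obs$tstat))
    ge_f <- ge_f + (pf$f >= obs$f)
  }
  structure(list(beta = obs$coef,
                 beta_p = (ge_t + 1) / (n_perm + 1),
                 r_squared = obs$r2,
                 f_statistic = obs$f,
                 f_p = (ge_f + 1) / (n_perm + 1),
                 n_perm = n_perm,
                 kept_predictors = names(xs),
                 eliminated = character(0)),
            class = "mmrr_result")
}

#' @export
print.mmrr_result <- function(x, ...) {
  cat("<mmrr_result>\n")
  print(data.frame(beta = x$beta, p = x$beta_p))
  cat(sprintf("R2 = %.4f, F = %.3f (p = %.4g), %d permutations\n",
              x$r_squared, x$f_statistic, x$f_p, x$n_perm))
  invisible(x)
}

#' MMRR with backwards elimination of non-significant predictors
#'
#' Repeatedly drops the predictor with the largest permutation p-value above
#' `alpha` and refits, until every remaining predictor is significant or none
#' remain (the model is then declared null).
#'
#' @inheritParams mmrr
#' @param alpha significance threshold for retention.
#' @return An `mmrr_result` for the final model (with `eliminated` recording
#'   the drop order), or a null-model result with zero predictors.
#' @export
mmrr_backward <- function(y, xs, alpha = 0.05, n_perm = 999, seed = 1) {
  if (inherits(xs, "dist_matrix")) xs <- list(x1 = xs)
  if (is.null(names(xs)) || any(names(xs) == ""))
    names(xs) <- paste0("x", seq_along(xs))
  eliminated <- character(0)
  current <- xs
  repeat {
    if (length(current) == 0) {
      return(structure(list(beta = numeric(0), beta_p = numeric(0),
                            r_squared = NA_real_, f_statistic = NA_real_,
                            f_p = NA_real_, n_perm = n_perm,
                            kept_predictors = character(0),
                            eliminated = eliminated, null_model = TRUE),
                       class = "mmrr_result"))
    }
    fit <- mmrr(y, current, n_perm = n_perm, seed = seed)
    if (all(fit$beta_p <= alpha)) {
      fit$eliminated <- eliminated
      return(fit)
    }
    worst <- names(current)[which.max(fit$beta_p)]
    eliminated <- c(eliminated, worst)
    current <- current[names(current) != worst]
  }
}

#' Monotone I-spline basis (3 functions, quadratic)
#'
#' Integrated M-splines of order 2 on knots `(min, mid, max)`: three monotone
#' non-decreasing basis functions, each 0 at the minimum knot and 1 at the
#' maximum knot. Values outside the knot range are clamped with a warning.
#'
#' @param x numeric values.
#' @param knots length-3 strictly increasing vector (min, mid, max).
#' @return matrix with 3 columns (one per basis function).
#' @export
ispline_basis <- function(x, knots) {
  stopifnot(length(knots) == 3, all(diff(knots) > 0))
  a <- knots[1]; b <- knots[2]; c <- knots[3]
  if (any(x < a - 1e-12) || any(x > c + 1e-12))
    warning("values outside knot range clamped")
  x <- pmin(pmax(x, a), c)
  i1 <- ifelse(x <= b, 1 - ((b - x) / (b - a))^2, 1)
  i2 <- ifelse(x <= b,
               (x - a)^2 / ((c - a) * (b - a)),
               (b - a) / (c - a) +
                 ((c - b)^2 - (c - x)^2) / ((c - a) * (c - b)))
  i3 <- ifelse(x <= b, 0, ((x - b) / (c - b))^2)
  cbind(i1, i2, i3)
}

ispline_knots <- function(v) {
  k <- c(min(v), stats::median(v), max(v))
  if (k[1] >= k[3]) stop("constant predictor: I-spline knots undefined")
  if (k[2] <= k[1] || k[2] >= k[3]) k[2] <- (k[1] + k[3]) / 2
  k
}

#' Rescale a genetic distance matrix to [0, 1]
#'
#' Divides by the observed maximum; the scale is kept as an attribute so
#' fitted dissimilarities can be back-transformed.
#' @param d a `dist_matrix`.
#' @return the rescaled `dist_matrix` with attribute `"scale"`.
#' @export
rescale_dist <- function(d) {
  mx <- max(d$values)
  if (mx > 0) d$values <- d$values / mx
  attr(d, "scale") <- mx
  d
}

gdm_design <- function(env, coords, use_geo, knots = NULL) {
  # pair features: |I_j(x_i) - I_j(x_j)| per predictor and basis function;
  # geographic distance enters through I-splines on the pair distance itself
  preds <- list()
  if (!is.null(env)) {
    env <- as.matrix(env)
    if (is.null(colnames(env))) colnames(env) <- paste0("env", seq_len(ncol(env)))
    for (j in seq_len(ncol(env))) {
      nm <- colnames(env)[j]
      kn <- if (!is.null(knots)) knots[[nm]] else ispline_knots(env[, j])
      basis <- ispline_basis(env[, j], kn)     # sites x 3
      preds[[nm]] <- list(knots = kn, type = "site",
                          cols = sapply(1:3, function(bb) {
                            m <- abs(outer(basis[, bb], basis[, bb], "-"))
                            m[lower.tri(m)]
                          }))
    }
  }
  if (use_geo) {
    gd <- geo_distance(coords, "linear")$values
    gv <- gd[lower.tri(gd)]
    kn <- if (!is.null(knots)) knots[["geographic"]] else ispline_knots(gv)
    basis <- ispline_basis(gv, kn)
    preds[["geographic"]] <- list(knots = kn, type = "pair", cols = basis)
  }
  preds
}

gdm_dev_explained <- function(eta, fitted) {
  sstot <- sum((eta - mean(eta))^2)
  if (sstot == 0) return(100)
  100 * (1 - sum((eta - fitted)^2) / sstot)
}

gdm_nnls <- function(eta, design) {
  a <- cbind(1, design)
  fit <- pracma::lsqnonneg(a, eta)
  coefs <- fit$x
  list(intercept = coefs[1], beta = coefs[-1], fitted = as.vector(a %*% coefs))
}

#' Fit a generalized dissimilarity model
#'
#' Models pairwise genetic dissimilarity `d_ij` in [0, 1) as
#' `1 - exp(-(a0 + sum_p |f_p(x_i) - f_p(x_j)|))` where each `f_p` is a
#' non-negative combination of three monotone I-spline basis functions (knots
#' at the minimum, median and maximum of the predictor). The model is fitted
#' by non-negative least squares on the link scale `eta = -log(1 - d)`, which
#' guarantees monotone, non-negative fitted relationships. Geographic
#' distance, when requested, enters through I-splines on the pairwise
#' great-circle distance. Predictor importance is the percent drop in
#' deviance explained when that predictor's site values are permuted.
#'
#' @param y genetic `dist_matrix` with values in [0, 1] (values of exactly 1
#'   are clamped to 1 - 1e-6); see [rescale_dist()].
#' @param env individuals x variables environment matrix (or NULL).
#' @param coords a [sample_coords()] table (needed when `use_geo`).
#' @param use_geo include geographic distance as a predictor?
#' @param n_perm permutations per predictor for importance.
#' @param seed integer seed for the importance permutations.
#' @return A `gdm_model`: intercept, per-predictor spline coefficients and
#'   knots, `deviance_explained` (%), and `importance` (%).
#' @export
gdm_fit <- function(y, env = NULL, coords = NULL, use_geo = FALSE,
                    n_perm = 10, seed = 1) {
  stopifnot(inherits(y, "dist_matrix"))
  if (is.null(env) && !use_geo) stop("no predictors: give env and/or use_geo")
  if (use_geo && is.null(coords)) stop("use_geo requires coordinates")
  yv <- unfold(y)
  if (any(yv < 0) || any(yv > 1))
    stop("dissimilarities outside [0, 1]: rescale first (rescale_dist)")
  yv <- pmin(yv, 1 - 1e-6)
  eta <- -log(1 - yv)
  preds <- gdm_design(env, coords, use_geo)
  design <- do.call(cbind, lapply(preds, function(p) p$cols))
  fit <- gdm_nnls(eta, design)
  dev_full <- gdm_dev_explained(eta, fit$fitted)
  coef_list <- split(fit$beta, rep(seq_along(preds), each = 3))
  names(coef_list) <- names(preds)
  # permutation importance: permute one predictor's site values, refit
  set.seed(seed)
  n_sites <- length(y$ids)
  importance <- vapply(seq_along(preds), function(pi) {
    devs <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      perm <- sample(n_sites)
      preds_p <- preds
      if (preds[[pi]]$type == "site") {
        xcol <- as.matrix(env)[, names(preds)[pi], drop = FALSE][perm, ,
                                                                 drop = FALSE]
        basis <- ispline_basis(xcol[, 1], preds[[pi]]$knots)
        preds_p[[pi]]$cols <- sapply(1:3, function(bb) {
          m <- abs(outer(basis[, bb], basis[, bb], "-"))
          m[lower.tri(m)]
        })
      } else {
        cp <- coords[perm, ]
        gd <- geo_distance(sample_coords(paste0("s", seq_len(n_sites)),
                                         cp$lon, cp$lat), "linear")$values
        gv0 <- pmin(pmax(gd[lower.tri(gd)], preds[[pi]]$knots[1]),
                    preds[[pi]]$knots[3])
        preds_p[[pi]]$cols <- ispline_basis(gv0, preds[[pi]]$knots)
      }
      dsn <- do.call(cbind, lapply(preds_p, function(p) p$cols))
      fp <- gdm_nnls(eta, dsn)
      devs[b] <- gdm_dev_explained(eta, fp$fitted)
    }
    dev_full - mean(devs)
  }, numeric(1))
  names(importance) <- names(preds)
  structure(list(intercept = fit$intercept,
                 coefficients = coef_list,
                 knots = lapply(preds, function(p) p$knots),
                 predictor_type = vapply(preds, function(p) p$type,
                                         character(1)),
                 fitted = 1 - exp(-fit$fitted),
                 deviance_explained = dev_full,
                 importance = importance),
            class = "gdm_model")
}

#' @export
print.gdm_model <- function(x, ...) {
  cat(sprintf("<gdm_model> %d predictors, deviance explained %.1f%%\n",
              length(x$coefficients), x$deviance_explained))
  invisible(x)
}

#' Evaluate a fitted GDM predictor transform
#' @param model a `gdm_model`.
#' @param predictor predictor name.
#' @param x values to transform.
#' @return `f_p(x)`, the fitted monotone transform.
#' @export
gdm_transform <- function(model, predictor, x) {
  if (!predictor %in% names(model$coefficients))
    stop("unknown predictor: ", predictor)
  kn <- model$knots[[predictor]]
  basis <- ispline_basis(pmin(pmax(x, kn[1]), kn[3]), kn)
  as.vector(basis %*% model$coefficients[[predictor]])
}

#' Map genetic compositional dissimilarity from a fitted GDM
#'
#' Passes each predictor raster through its fitted I-spline transform, runs a
#' PCA over the transformed cell values, and rescales the first three
#' components to [0, 255] as an RGB triplet visualizing genetic turnover.
#' With fewer than three available components, channels repeat (a message is
#' issued).
#'
#' @param model a `gdm_model`.
#' @param layers named list of `grid_surface` layers matching the model's
#'   site-level predictors.
#' @return list with `transformed` (list of layers) and `rgb` (list of three
#'   layers scaled 0-255).
#' @export
gdm_map <- function(model, layers) {
  site_preds <- names(model$predictor_type)[model$predictor_type == "site"]
  if (length(site_preds) == 0) stop("model has no site-level predictors to map")
  lay_names <- vapply(layers, function(l) l$name, character(1))
  missing_p <- setdiff(site_preds, lay_names)
  if (length(missing_p))
    stop("missing predictor layer(s): ", paste(missing_p, collapse = ", "))
  if (all(unlist(model$coefficients[site_preds]) == 0))
    stop("degenerate model: all spline coefficients are zero")
  tmpl <- layers[[1]]
  transformed <- lapply(site_preds, function(p) {
    l <- layers[[match(p, lay_names)]]
    v <- gdm_transform(model, p, as.vector(l$values))
    v[is.na(as.vector(l$values))] <- NA_real_
    grid_surface(matrix(v, nrow(l$values), ncol(l$values)),
                 l$xmin, l$ymax, l$xres, l$yres, name = paste0("f_", p))
  })
  names(transformed) <- site_preds
  tv <- sapply(transformed, function(l) as.vector(l$values))
  tv <- matrix(tv, ncol = length(transformed))
  valid <- stats::complete.cases(tv)
  keep <- apply(tv[valid, , drop = FALSE], 2, stats::sd) > 0
  if (!any(keep)) stop("degenerate model: transformed layers are constant")
  pc <- stats::prcomp(tv[valid, keep, drop = FALSE], center = TRUE,
                      scale. = FALSE)
  n_pc <- ncol(pc$x)
  if (n_pc < 3) message("fewer than 3 components: RGB channels repeat")
  rgb_layers <- lapply(1:3, function(ch) {
    comp <- pc$x[, min(ch, n_pc)]
    rng <- range(comp)
    scaled <- if (diff(rng) > 0) 255 * (comp - rng[1]) / diff(rng)
              else rep(127.5, length(comp))
    v <- rep(NA_real_, nrow(tv))
    v[valid] <- scaled
    grid_surface(matrix(v, nrow(tmpl$values), ncol(tmpl$values)),
                 tmpl$xmin, tmpl$ymax, tmpl$xres, tmpl$yres,
                 name = c("R", "G", "B")[ch])
  })
  list(transformed = transformed, rgb = rgb_layers)
}
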