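# Spatially regularized ancestry estimation. Individuals x loci dosages are
# scaled to [0,1] (divide by 2) and factorized as X ~ Q G with Q rows on the
# probability simplex (ancestry coefficients) and G in [0,1] (cluster allele
# frequencies), penalized by a graph-Laplacian smoothness term so nearby
# individuals receive similar ancestry, in the spirit of spatially explicit
# clustering methods such as TESS.

project_simplex <- function(v) {
  # euclidean projection onto {x >= 0, sum x = 1} (sort-based)
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

spatial_laplacian <- function(coords, bandwidth = NULL) {
  n <- nrow(coords)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d[i, j] <- d[j, i] <- haversine_km(coords$lon[i], coords$lat[i],
                                       coords$lon[j], coords$lat[j])
  }
  if (is.null(bandwidth)) {
    nn <- apply(d + diag(Inf, n), 1, min)
    bandwidth <- mean(nn[is.finite(nn)])
    if (!is.finite(bandwidth) || bandwidth == 0) bandwidth <- 1
  }
  w <- exp(-d^2 / (2 * bandwidth^2))
  diag(w) <- 0
  diag(rowSums(w)) - w
}

cluster_loss <- function(x, q, g, lambda, lap) {
  sum((x - q %*% g)^2) + lambda * sum(diag(t(q) %*% lap %*% q))
}

#' Fit spatially regularized genetic clusters
#'
#' Minimizes `||X - QG||^2_F + lambda * tr(Q' L Q)` by projected alternating
#' least squares (monotone proximal-gradient block updates), where `X` is the
#' dosage matrix scaled to [0,1], `Q` holds per-individual ancestry
#' coefficients on the probability simplex, `G` holds cluster allele
#' frequencies in [0,1], and `L` is the graph Laplacian of a Gaussian spatial
#' kernel on great-circle distances (bandwidth = mean nearest-neighbour
#' distance). `Q` is initialized from k-means on principal-component scores.
#'
#' @param g a complete (imputed) `dosage_matrix`.
#' @param coords a [sample_coords()] table, rows matching `g`.
#' @param k number of clusters (>= 1).
#' @param lambda spatial regularization weight (0 disables regularization).
#' @param seed integer seed (initialization).
#' @param max_iter,tol outer-iteration cap and relative-loss tolerance.
#' @return An `ancestry_model`: list with `Q`, `G`, `K`, `lambda`, `loss`
#'   (trajectory) and `cv_error` (NA; filled by [select_k()]).
#' @export
fit_clusters <- function(g, coords, k, lambda = 1.0, seed = 1,
                         max_iter = 200, tol = 1e-6) {
  stopifnot(inherits(g, "dosage_matrix"), k >= 1)
  if (anyNA(g$values)) stop("missing genotypes present: impute first")
  n <- nrow(g$values)
  if (k > n) stop("k cannot exceed the number of individuals")
  x <- g$values / 2
  set.seed(seed)
  lap <- spatial_laplacian(coords)
  lap_lmax <- if (lambda > 0) max(eigen(lap, symmetric = TRUE,
                                        only.values = TRUE)$values) else 0
  # init: k-means on PC scores with deterministic farthest-point seeding
  # (permutation-equivariant: depends on the data only through distances)
  q <- matrix(1, n, k)
  if (k > 1) {
    xc <- scale(x, center = TRUE, scale = FALSE)
    npc <- min(max(k, 2), n - 1, ncol(x))
    sv <- svd(xc, nu = npc, nv = 0)
    scores <- sv$u %*% diag(sv$d[seq_len(npc)], npc)
    chosen <- which.max(rowSums(scores^2))
    while (length(chosen) < k) {
      dmin <- apply(as.matrix(stats::dist(scores))[, chosen, drop = FALSE],
                    1, min)
      chosen <- c(chosen, which.max(dmin))
    }
    km <- stats::kmeans(scores, centers = scores[chosen, , drop = FALSE],
                        iter.max = 50)
    q <- matrix(0.1 / (k - 1), n, k)
    q[cbind(seq_len(n), km$cluster)] <- 0.9
  }
  gmat <- matrix(stats::runif(k * ncol(x)), k, ncol(x))
  loss_tr <- cluster_loss(x, q, gmat, lambda, lap)
  for (it in seq_len(max_iter)) {
    # G block: prox-grad steps on box [0,1], step 1/L guarantees descent
    lg <- 2 * max(eigen(crossprod(q), symmetric = TRUE,
                        only.values = TRUE)$values)
    for (s in 1:5) {
      grad <- -2 * t(q) %*% (x - q %*% gmat)
      gmat <- pmin(pmax(gmat - grad / lg, 0), 1)
    }
    # Q block: prox-grad steps with row-wise simplex projection
    lq <- 2 * (max(eigen(tcrossprod(gmat), symmetric = TRUE,
                         only.values = TRUE)$values) + lambda * lap_lmax)
    for (s in 1:5) {
      grad <- -2 * (x - q %*% gmat) %*% t(gmat) + 2 * lambda * lap %*% q
      q <- q - grad / lq
      q <- t(apply(q, 1, project_simplex))
      if (k == 1) q <- matrix(q, n, 1)
    }
    loss <- cluster_loss(x, q, gmat, lambda, lap)
    loss_tr <- c(loss_tr, loss)
    prev <- loss_tr[length(loss_tr) - 1]
    if (abs(prev - loss) <= tol * max(prev, 1e-12)) break
  }
  structure(list(Q = q, G = gmat, K = k, lambda = lambda,
                 loss = loss_tr, cv_error = NA_real_,
                 sample_ids = g$sample_ids),
            class = "ancestry_model")
}

#' @export
print.ancestry_model <- function(x, ...) {
  cat(sprintf("<ancestry_model> K=%d, %d individuals, final loss %.4g\n",
              x$K, nrow(x$Q), x$loss[length(x$loss)]))
  invisible(x)
}

#' Cross-validation over K for genetic clustering
#'
#' For each candidate K, hides a fraction of genotype cells (replacing them by
#' the per-locus median of the visible cells), fits the clustering model and
#' scores the root-mean-square error between reconstructed (`2 * QG`) and true
#' dosages on the hidden cells, averaged over replicates. In `auto` mode the
#' chosen K is the elbow: the smallest K whose relative error improvement to
#' K+1 falls below 5%.
#'
#' @param g a complete `dosage_matrix`.
#' @param coords a [sample_coords()] table.
#' @param k_range integer vector of candidate K values.
#' @param mode "manual" (table only) or "auto" (table + chosen K).
#' @param seed integer seed.
#' @param lambda spatial regularization weight passed to [fit_clusters()].
#' @param mask_fraction fraction of cells hidden per replicate.
#' @param n_replicates replicates per K.
#' @return list with `table` (K, cv_error) and `chosen_k` (NA in manual mode).
#' @export
select_k <- function(g, coords, k_range = 1:5, mode = c("manual", "auto"),
                     seed = 1, lambda = 1.0, mask_fraction = 0.05,
                     n_replicates = 3) {
  mode <- match.arg(mode)
  stopifnot(length(k_range) >= 1)
  k_range <- sort(unique(as.integer(k_range)))
  x <- g$values
  n_cells <- length(x)
  errs <- sapply(k_range, function(k) {
    rep_err <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      set.seed(seed * 1000 + r)
      hide <- sample(n_cells, max(1, round(mask_fraction * n_cells)))
      xm <- x
      xm[hide] <- NA
      gm <- tryCatch(impute_median(dosage_matrix(xm, g$sample_ids,
                                                 g$locus_ids)),
                     error = function(e) NULL)
      if (is.null(gm)) { # loci fully hidden: fall back to global median
        xm[is.na(xm)] <- as.integer(stats::median(x[!is.na(x)]))
        gm <- dosage_matrix(xm, g$sample_ids, g$locus_ids)
      }
      fit <- fit_clusters(gm, coords, k, lambda = lambda,
                          seed = seed * 1000 + r)
      recon <- 2 * fit$Q %*% fit$G
      rep_err[r] <- sqrt(mean((recon[hide] - x[hide])^2))
    }
    mean(rep_err)
  })
  tab <- data.frame(K = k_range, cv_error = errs)
  chosen <- NA_integer_
  if (mode == "auto") {
    chosen <- k_range[length(k_range)]
    if (length(k_range) == 1) {
      chosen <- k_range[1]
    } else {
      for (i in seq_len(length(k_range) - 1)) {
        improvement <- (errs[i] - errs[i + 1]) / errs[i]
        if (improvement < 0.05) { chosen <- k_range[i]; break }
      }
    }
  }
  list(table = tab, chosen_k = chosen)
}

#' Kriged maps of ancestry coefficients
#'
#' Interpolates each ancestry-coefficient column of `Q` onto the grid by
#' ordinary kriging (IDW fallback on variogram failure, with a message),
#' clamps cell values to [0,1] and renormalizes across the K layers so they
#' sum to one in every cell, and derives a dominant-cluster layer (arg-max,
#' ties to the lowest cluster index).
#'
#' @param model an `ancestry_model` from [fit_clusters()].
#' @param coords a [sample_coords()] table (>= 5 points).
#' @param grid a `grid_surface` covering all points.
#' @return list with `ancestry` (list of K `grid_surface`s) and `dominant`.
#' @export
krige_ancestry <- function(model, coords, grid) {
  if (nrow(coords) < 5)
    stop("need at least 5 points to fit a variogram for kriging")
  cells <- cell_of_point(grid, coords)
  if (anyNA(cells$row)) stop("grid does not cover all sample points")
  centers <- cell_centers(grid)
  k <- model$K
  layers <- vector("list", k)
  preds <- matrix(0, nrow(centers), k)
  for (ki in seq_len(k)) {
    kr <- krige_points(coords$lon, coords$lat, model$Q[, ki],
                       centers$lon, centers$lat)
    preds[, ki] <- pmin(pmax(kr$pred, 0), 1)
  }
  tot <- rowSums(preds)
  zero <- tot < 1e-12
  preds[zero, ] <- 1 / k
  preds[!zero, ] <- preds[!zero, , drop = FALSE] / tot[!zero]
  for (ki in seq_len(k)) {
    m <- matrix(NA_real_, nrow(grid$values), ncol(grid$values))
    m[cbind(centers$row, centers$col)] <- preds[, ki]
    layers[[ki]] <- grid_surface(m, grid$xmin, grid$ymax, grid$xres,
                                 grid$yres, name = paste0("ancestry_", ki))
  }
  dom <- apply(preds, 1, which.max)  # which.max takes the lowest index on ties
  dm <- matrix(NA_real_, nrow(grid$values), ncol(grid$values))
  dm[cbind(centers$row, centers$col)] <- dom
  dominant <- grid_surface(dm, grid$xmin, grid$ymax, grid$xres, grid$yres,
                           name = "dominant_cluster")
  list(ancestry = layers, dominant = dominant)
}

#' Write ancestry coefficients as CSV (id, q1..qK)
#' @param model an `ancestry_model`.
#' @param path output path.
#' @export
write_qmatrix_csv <- function(model, path) {
  df <- data.frame(id = model$sample_ids, model$Q)
  names(df) <- c("id", paste0("q", seq_len(model$K)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
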