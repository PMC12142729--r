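# Ordinary kriging with least-squares variogram fitting, plus inverse-distance
# weighting. Shared by ancestry mapping and diversity-surface interpolation.
# Distances here are planar in degree units: interpolation operates on local
# study extents where the planar approximation is adequate.

vgm_model <- function(h, nugget, psill, range, model) {
  h <- pmax(h, 0)
  g <- switch(model,
    exponential = psill * (1 - exp(-h / range)),
    spherical = ifelse(h >= range, psill,
                       psill * (1.5 * h / range - 0.5 * (h / range)^3)),
    gaussian = psill * (1 - exp(-(h / range)^2)),
    stop("unknown variogram model: ", model))
  nugget + g
}

empirical_variogram <- function(x, y, z, n_bins = 12) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  dv <- d[lower.tri(d)]
  gv <- 0.5 * outer(z, z, "-")^2
  gv <- gv[lower.tri(gv)]
  cutoff <- max(dv) / 2
  sel <- dv > 0 & dv <= cutoff
  if (sum(sel) < 3) {
    sel <- dv > 0
    cutoff <- max(dv)
  }
  breaks <- seq(0, cutoff, length.out = n_bins + 1)
  bin <- cut(dv[sel], breaks, include.lowest = TRUE)
  out <- data.frame(
    dist = as.vector(tapply(dv[sel], bin, mean)),
    gamma = as.vector(tapply(gv[sel], bin, mean)),
    n = as.vector(table(bin)))
  out[stats::complete.cases(out), ]
}

fit_variogram <- function(emp) {
  emp <- emp[emp$n > 0 & is.finite(emp$gamma), ]
  if (nrow(emp) < 3 || all(emp$gamma == 0)) return(NULL)
  best <- NULL
  sill0 <- max(emp$gamma)
  range0 <- max(emp$dist) / 2
  for (model in c("exponential", "spherical", "gaussian")) {
    obj <- function(par) {
      p <- exp(par)  # positivity via log parametrization
      sum(emp$n * (vgm_model(emp$dist, p[1], p[2], p[3], model) - emp$gamma)^2)
    }
    fit <- tryCatch(
      stats::optim(log(c(sill0 * 0.05 + 1e-10, sill0, range0)), obj,
                   method = "Nelder-Mead",
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$sse) {
      p <- exp(fit$par)
      best <- list(model = model, nugget = p[1], psill = p[2],
                   range = p[3], sse = fit$value)
    }
  }
  best
}

#' Inverse-distance-weighted interpolation
#' @param x,y,z known point coordinates and values.
#' @param x0,y0 target coordinates.
#' @param power IDW exponent.
#' @return interpolated values at the targets.
#' @keywords internal
idw_interpolate <- function(x, y, z, x0, y0, power = 2) {
  vapply(seq_along(x0), function(i) {
    d <- sqrt((x - x0[i])^2 + (y - y0[i])^2)
    if (any(d < 1e-12)) return(mean(z[d < 1e-12]))
    w <- 1 / d^power
    sum(w * z) / sum(w)
  }, numeric(1))
}

#' Ordinary kriging of scattered point values onto target locations
#'
#' Fits a variogram (exponential, spherical or gaussian, chosen by weighted
#' least squares on the empirical variogram) and solves the ordinary-kriging
#' system for each target. Falls back to inverse-distance weighting when the
#' variogram cannot be fitted (fewer than 5 points, degenerate geometry or
#' optimizer failure), with a message.
#'
#' @param x,y,z known point coordinates and values.
#' @param x0,y0 target coordinates.
#' @return list with `pred` (values at targets) and `method` ("krige"/"idw").
#' @keywords internal
krige_points <- function(x, y, z, x0, y0) {
  n <- length(x)
  fallback <- function(why) {
    message("kriging fallback to IDW: ", why)
    list(pred = idw_interpolate(x, y, z, x0, y0), method = "idw")
  }
  if (n < 5) return(fallback("fewer than 5 points"))
  if (stats::sd(z) == 0)
    return(list(pred = rep(z[1], length(x0)), method = "krige"))
  emp <- tryCatch(empirical_variogram(x, y, z), error = function(e) NULL)
  vg <- if (is.null(emp)) NULL else fit_variogram(emp)
  if (is.null(vg)) return(fallback("variogram fit failed"))
  d <- as.matrix(stats::dist(cbind(x, y)))
  gamma <- vgm_model(d, vg$nugget, vg$psill, vg$range, vg$model)
  diag(gamma) <- 0
  a <- rbind(cbind(gamma, 1), c(rep(1, n), 0))
  a_inv <- tryCatch(solve(a), error = function(e) NULL)
  if (is.null(a_inv)) return(fallback("singular kriging system"))
  d0 <- sqrt(outer(x0, x, "-")^2 + outer(y0, y, "-")^2)
  g0 <- vgm_model(d0, vg$nugget, vg$psill, vg$range, vg$model)
  g0[d0 < 1e-12] <- 0
  rhs <- cbind(g0, 1)            # targets x (n+1)
  w <- rhs %*% t(a_inv)          # targets x (n+1); last col = Lagrange mult.
  pred <- as.vector(w[, seq_len(n), drop = FALSE] %*% z)
  list(pred = pred, method = "krige", variogram = vg)
}
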