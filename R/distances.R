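#' Construct a pairwise distance matrix
#'
#' Symmetric non-negative dissimilarity over individuals with a zero diagonal.
#'
#' @param values n x n numeric matrix.
#' @param ids individual identifiers.
#' @param kind one of "genetic", "geographic", "environmental", "resistance".
#' @param metric name of the metric that produced the values.
#' @return An object of class `dist_matrix`.
#' @export
dist_matrix <- function(values, ids, kind, metric) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values), length(ids) == nrow(values))
  kind <- match.arg(kind, c("genetic", "geographic", "environmental",
                            "resistance"))
  finite <- is.finite(values)
  if (max(abs(values - t(values))[finite & t(finite)]) > 1e-10)
    stop("distance matrix is not symmetric")
  if (any(abs(diag(values)) > 1e-10)) stop("diagonal must be zero")
  if (any(values[finite] < 0)) stop("distances must be non-negative")
  diag(values) <- 0
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, ids = as.character(ids),
                 kind = kind, metric = metric),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d x %d, kind=%s, metric=%s\n",
              nrow(x$values), ncol(x$values), x$kind, x$metric))
  invisible(x)
}

#' Pairwise genetic distances between individuals
#'
#' Three individual-valid metrics:
#' \describe{
#'   \item{euclidean}{L2 distance over dosages.}
#'   \item{pc}{L2 distance in the space of the top `n_pcs` principal
#'     components of the column-centered dosage matrix.}
#'   \item{dps}{1 minus the proportion of shared alleles, averaged over loci.}
#' }
#'
#' @param g a complete (imputed) `dosage_matrix`.
#' @param metric "euclidean", "pc" or "dps".
#' @param n_pcs number of principal components for `metric = "pc"`.
#' @return A `dist_matrix` of kind "genetic".
#' @export
genetic_distance <- function(g, metric = c("euclidean", "pc", "dps"),
                             n_pcs = 10) {
  stopifnot(inherits(g, "dosage_matrix"))
  metric <- match.arg(metric)
  x <- g$values
  if (anyNA(x))
    stop("missing genotypes present: impute first (impute_median or impute_structure)")
  storage.mode(x) <- "double"
  n <- nrow(x)
  d <- switch(metric,
    euclidean = as.matrix(stats::dist(x)),
    pc = {
      stopifnot(n_pcs >= 1, n_pcs < n)
      xc <- scale(x, center = TRUE, scale = FALSE)
      sv <- svd(xc, nu = n_pcs, nv = 0)
      scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
      as.matrix(stats::dist(scores))
    },
    dps = {
      # shared-allele proportion from dosages: per locus
      # ps = (min(ref_i, ref_j) + min(alt_i, alt_j)) / 2, averaged over loci
      out <- matrix(0, n, n)
      for (i in seq_len(n - 1)) {
        ai <- x[i, ]
        for (j in (i + 1):n) {
          aj <- x[j, ]
          ps <- (pmin(2 - ai, 2 - aj) + pmin(ai, aj)) / 2
          out[i, j] <- out[j, i] <- 1 - mean(ps)
        }
      }
      out
    })
  dist_matrix(d, g$sample_ids, "genetic", metric)
}

#' Great-circle distance in kilometres (haversine)
#'
#' Uses the IUGG mean Earth radius 6371.0088 km.
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @return distance in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Pairwise geographic distances between sample points
#'
#' `type = "linear"` gives great-circle (haversine) distances in km;
#' `type = "resistance"` gives commute distances on the resistance surface
#' (see [commute_distance()]).
#'
#' @param coords a [sample_coords()] table.
#' @param type "linear" or "resistance".
#' @param surface resistance `grid_surface` (required for resistance).
#' @return A `dist_matrix`.
#' @export
geo_distance <- function(coords, type = c("linear", "resistance"),
                         surface = NULL) {
  type <- match.arg(type)
  if (type == "resistance") {
    if (is.null(surface)) stop("resistance distances need a resistance surface")
    return(commute_distance(surface, coords))
  }
  n <- nrow(coords)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d[i, j] <- d[j, i] <- haversine_km(coords$lon[i], coords$lat[i],
                                       coords$lon[j], coords$lat[j])
  }
  dist_matrix(d, coords$id, "geographic", "haversine_km")
}

resistance_graph <- function(surface) {
  # nodes = non-nodata cells; edge conductance between neighbours =
  # mean of cell conductances, scaled by 1/sqrt(2) for diagonal moves
  v <- surface$values
  nr <- nrow(v); nc <- ncol(v)
  node <- matrix(NA_integer_, nr, nc)
  valid <- which(!is.na(v))
  node[valid] <- seq_along(valid)
  cond <- 1 / v
  edges_i <- integer(0); edges_j <- integer(0); edges_w <- numeric(0)
  offsets <- rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 1 / sqrt(2)),
                   c(1, -1, 1 / sqrt(2)))
  for (o in seq_len(nrow(offsets))) {
    dr <- offsets[o, 1]; dc <- offsets[o, 2]; sc <- offsets[o, 3]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    for (r in r1) for (cl in c1) {
      a <- node[r, cl]; b <- node[r + dr, cl + dc]
      if (is.na(a) || is.na(b)) next
      edges_i <- c(edges_i, a); edges_j <- c(edges_j, b)
      edges_w <- c(edges_w, sc * (cond[r, cl] + cond[r + dr, cl + dc]) / 2)
    }
  }
  list(n = length(valid), node = node,
       edges = data.frame(i = edges_i, j = edges_j, w = edges_w))
}

graph_components <- function(n, edges) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    m <- pmin(comp[edges$i], comp[edges$j])
    if (any(comp[edges$i] != m)) { comp[edges$i] <- m; changed <- TRUE }
    if (any(comp[edges$j] != m)) { comp[edges$j] <- m; changed <- TRUE }
    if (!changed) break
  }
  match(comp, unique(comp))
}

#' Commute distances between sample points on a resistance surface
#'
#' Builds a node-per-cell graph (8-connected; diagonal edges scaled by
#' 1/sqrt(2)); edge conductance is the mean of the two cell conductances
#' (conductance = 1/resistance). The commute distance is
#' `C(i,j) = vol(G) * R_eff(i,j)` with `vol(G)` twice the total edge
#' conductance and `R_eff` the effective resistance from the graph Laplacian.
#' Sample points are snapped to their containing cells. Pairs of samples in
#' disconnected components receive `Inf` with a warning.
#'
#' @param surface a strictly positive resistance `grid_surface`.
#' @param coords a [sample_coords()] table inside the surface extent.
#' @return A `dist_matrix` of kind "resistance".
#' @export
commute_distance <- function(surface, coords) {
  if (any(surface$values[!is.na(surface$values)] <= 0))
    stop("resistance values must be strictly positive")
  cells <- cell_of_point(surface, coords)
  if (anyNA(cells$row))
    stop("sample(s) outside resistance surface: ",
         paste(coords$id[is.na(cells$row)], collapse = ", "))
  gr <- resistance_graph(surface)
  snode <- gr$node[cbind(cells$row, cells$col)]
  if (anyNA(snode))
    stop("sample(s) on nodata resistance cell: ",
         paste(coords$id[is.na(snode)], collapse = ", "))
  n <- gr$n
  lap <- matrix(0, n, n)
  for (e in seq_len(nrow(gr$edges))) {
    i <- gr$edges$i[e]; j <- gr$edges$j[e]; w <- gr$edges$w[e]
    lap[i, j] <- lap[i, j] - w
    lap[j, i] <- lap[j, i] - w
    lap[i, i] <- lap[i, i] + w
    lap[j, j] <- lap[j, j] + w
  }
  vol <- 2 * sum(gr$edges$w)
  comp <- graph_components(n, gr$edges)
  lplus <- MASS::ginv(lap)
  ns <- nrow(coords)
  d <- matrix(0, ns, ns)
  disconnected <- FALSE
  for (a in seq_len(ns - 1)) for (b in (a + 1):ns) {
    i <- snode[a]; j <- snode[b]
    if (i == j) { d[a, b] <- d[b, a] <- 0; next }
    if (comp[i] != comp[j]) {
      d[a, b] <- d[b, a] <- Inf
      disconnected <- TRUE
      next
    }
    reff <- lplus[i, i] + lplus[j, j] - 2 * lplus[i, j]
    d[a, b] <- d[b, a] <- vol * reff
  }
  if (disconnected)
    warning("disconnected resistance surface: some distances are infinite")
  dist_matrix(d, coords$id, "resistance", "commute")
}

#' Environmental distance matrices
#'
#' Each variable is standardized (zero mean, unit variance over individuals);
#' per-variable distances are absolute differences of the standardized values
#' and the combined distance is the euclidean distance over all standardized
#' variables.
#'
#' @param env individuals x variables matrix (no missing values) with row
#'   names as ids.
#' @return list with `per_variable` (list of `dist_matrix`) and `combined`.
#' @export
env_distance <- function(env) {
  env <- as.matrix(env)
  if (anyNA(env)) stop("missing environmental values")
  ids <- rownames(env)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(env)))
  if (is.null(colnames(env))) colnames(env) <- paste0("env", seq_len(ncol(env)))
  sds <- apply(env, 2, stats::sd)
  if (any(sds == 0))
    stop("constant variable(s), standardization undefined: ",
         paste(colnames(env)[sds == 0], collapse = ", "))
  z <- scale(env)
  per_var <- lapply(seq_len(ncol(z)), function(j)
    dist_matrix(abs(outer(z[, j], z[, j], "-")), ids, "environmental",
                colnames(env)[j]))
  names(per_var) <- colnames(env)
  combined <- dist_matrix(as.matrix(stats::dist(z)), ids, "environmental",
                          "combined_euclidean")
  list(per_variable = per_var, combined = combined)
}

#' Write a distance matrix as square CSV (ids as header row and column)
#' @param d a `dist_matrix`.
#' @param path output path.
#' @export
write_dist_csv <- function(d, path) {
  df <- data.frame(id = d$ids, d$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a distance matrix from square CSV written by [write_dist_csv()]
#' @param path input path.
#' @param kind,metric matrix annotations (see [dist_matrix()]).
#' @export
read_dist_csv <- function(path, kind = "genetic", metric = "unknown") {
  df <- utils::read.csv(path, check.names = FALSE)
  dist_matrix(as.matrix(df[, -1, drop = FALSE]), df$id, kind, metric)
}
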