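#' Configuration for moving-window genetic diversity mapping
#'
#' @param statistic "het" (observed heterozygosity), "pi" (nucleotide
#'   diversity, unbiased pairwise-difference form) or "allelic_richness".
#' @param wdim odd window edge length in grid cells.
#' @param min_n minimum individuals pooled per window; windows below it are
#'   nodata.
#' @param rarefy rarefy allelic richness to `g` gene copies?
#' @param g rarefaction size in gene copies (2 per diploid individual);
#'   defaults to `2 * min_n`.
#' @return A `diversity_config` list.
#' @export
diversity_config <- function(statistic = c("het", "pi", "allelic_richness"),
                             wdim = 3, min_n = 2, rarefy = FALSE,
                             g = 2 * min_n) {
  statistic <- match.arg(statistic)
  stopifnot(wdim >= 1, wdim %% 2 == 1, min_n >= 1)
  if (rarefy && g < 2) stop("rarefaction size g must be >= 2")
  structure(list(statistic = statistic, wdim = wdim, min_n = min_n,
                 rarefy = rarefy, g = g), class = "diversity_config")
}

#' Expected allele count under rarefaction
#'
#' Hypergeometric expectation of the number of alleles observed when `g` gene
#' copies are drawn without replacement from `c0` copies of one allele and
#' `c1` of the other: `sum_a [1 - choose(N - N_a, g) / choose(N, g)]`.
#'
#' @param c0,c1 allele counts (gene copies) at a biallelic locus.
#' @param g number of gene copies drawn (1 <= g <= c0 + c1).
#' @return Expected number of distinct alleles (between 1 and 2).
#' @export
rarefied_richness <- function(c0, c1, g) {
  n <- c0 + c1
  if (g > n) stop("rarefaction size g exceeds available gene copies")
  stopifnot(g >= 1)
  counts <- c(c0, c1)
  counts <- counts[counts > 0]
  sum(1 - exp(lchoose(n - counts, g) - lchoose(n, g)))
}

window_statistic <- function(x, cfg) {
  # x: pooled individuals x loci dosage sub-matrix (NA = missing)
  switch(cfg$statistic,
    het = {
      obs <- !is.na(x)
      if (!any(obs)) return(NA_real_)
      sum(x == 1, na.rm = TRUE) / sum(obs)
    },
    pi = {
      vals <- apply(x, 2, function(col) {
        col <- col[!is.na(col)]
        m <- 2 * length(col)
        if (m < 2) return(NA_real_)
        c1 <- sum(col)
        c0 <- m - c1
        2 * c0 * c1 / (m * (m - 1))
      })
      if (all(is.na(vals))) return(NA_real_)
      mean(vals, na.rm = TRUE)
    },
    allelic_richness = {
      vals <- apply(x, 2, function(col) {
        col <- col[!is.na(col)]
        m <- 2 * length(col)
        if (m < 1) return(NA_real_)
        c1 <- sum(col)
        c0 <- m - c1
        if (cfg$rarefy) {
          if (m < cfg$g) return(NA_real_)
          rarefied_richness(c0, c1, cfg$g)
        } else {
          sum(c(c0, c1) > 0)
        }
      })
      if (all(is.na(vals))) return(NA_real_)
      mean(vals, na.rm = TRUE)
    })
}

#' Moving-window genetic diversity surface
#'
#' Assigns each individual to its grid cell, then for every cell pools the
#' individuals whose cells fall within the `wdim` x `wdim` window centred on
#' it and computes the configured statistic over the pooled genotypes.
#' Windows pooling fewer than `min_n` individuals are nodata. A companion
#' raster reports the per-window sample count.
#'
#' @param g a `dosage_matrix` (missing genotypes allowed; excluded per locus).
#' @param coords a [sample_coords()] table.
#' @param grid a `grid_surface` defining the output geometry.
#' @param cfg a [diversity_config()].
#' @return list with `surface` (statistic raster) and `counts`.
#' @export
window_diversity <- function(g, coords, grid, cfg = diversity_config()) {
  stopifnot(inherits(g, "dosage_matrix"), inherits(cfg, "diversity_config"))
  cells <- cell_of_point(grid, coords)
  if (anyNA(cells$row)) stop("grid does not cover all sample points")
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  half <- (cfg$wdim - 1) / 2
  stat <- matrix(NA_real_, nr, nc)
  counts <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    inside <- abs(cells$row - r) <= half & abs(cells$col - cl) <= half
    counts[r, cl] <- sum(inside)
    if (sum(inside) < cfg$min_n) next
    stat[r, cl] <- window_statistic(g$values[inside, , drop = FALSE], cfg)
  }
  if (all(is.na(stat)))
    stop("no window reaches min_n individuals; consider a larger wdim")
  list(surface = grid_surface(stat, grid$xmin, grid$ymax, grid$xres,
                              grid$yres, name = cfg$statistic),
       counts = grid_surface(counts, grid$xmin, grid$ymax, grid$xres,
                             grid$yres, name = "n_individuals"))
}

#' Interpolate the nodata cells of a surface
#'
#' Fills nodata cells from the defined cells by ordinary kriging or IDW.
#' With fewer than 5 defined cells kriging falls back to IDW with a warning.
#' Optionally masks cells whose centers fall outside the convex hull of the
#' sample points (or of the defined cells when no coordinates are given).
#'
#' @param raw a `grid_surface` with some defined cells.
#' @param method "krige" or "idw".
#' @param mask_to "extent" (no mask) or "convex_hull".
#' @param coords optional [sample_coords()] used for the convex hull.
#' @return An interpolated `grid_surface`.
#' @export
interpolate_surface <- function(raw, method = c("krige", "idw"),
                                mask_to = c("extent", "convex_hull"),
                                coords = NULL) {
  method <- match.arg(method)
  mask_to <- match.arg(mask_to)
  centers <- cell_centers(raw)
  vals <- raw$values[cbind(centers$row, centers$col)]
  defined <- !is.na(vals)
  out <- raw$values
  if (any(!defined)) {
    if (method == "krige" && sum(defined) < 5) {
      warning("fewer than 5 defined cells: falling back to IDW")
      method <- "idw"
    }
    pred <- if (method == "krige") {
      krige_points(centers$lon[defined], centers$lat[defined], vals[defined],
                   centers$lon[!defined], centers$lat[!defined])$pred
    } else {
      idw_interpolate(centers$lon[defined], centers$lat[defined],
                      vals[defined], centers$lon[!defined],
                      centers$lat[!defined])
    }
    out[cbind(centers$row[!defined], centers$col[!defined])] <- pred
  }
  if (mask_to == "convex_hull") {
    px <- if (!is.null(coords)) coords$lon else centers$lon[defined]
    py <- if (!is.null(coords)) coords$lat else centers$lat[defined]
    hull <- grDevices::chull(px, py)
    bnd <- cbind(px[hull], py[hull])
    inside <- mgcv::in.out(rbind(bnd, bnd[1, ]),
                           cbind(centers$lon, centers$lat))
    out[cbind(centers$row[!inside], centers$col[!inside])] <- NA_real_
  }
  grid_surface(out, raw$xmin, raw$ymax, raw$xres, raw$yres, name = raw$name)
}
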