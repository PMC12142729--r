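#' Construct a sampling-coordinates table
#'
#' One row per individual, longitude/latitude in decimal degrees (WGS84).
#' Row order must match the rows of the dosage matrix.
#'
#' @param sample_ids unique identifiers.
#' @param lon,lat numeric vectors of coordinates.
#' @return An object of class `sample_coords`.
#' @export
sample_coords <- function(sample_ids, lon, lat) {
  sample_ids <- as.character(sample_ids)
  stopifnot(length(sample_ids) == length(lon), length(lon) == length(lat))
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
  if (any(lon < -180 | lon > 180)) stop("longitude outside [-180, 180]")
  structure(data.frame(id = sample_ids, lon = as.numeric(lon),
                       lat = as.numeric(lat), stringsAsFactors = FALSE),
            class = c("sample_coords", "data.frame"))
}

#' Read sampling coordinates from CSV (columns id, lon, lat)
#' @param path CSV file path.
#' @return A [sample_coords()] table.
#' @export
read_coords <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("coordinates CSV needs columns: id, lon, lat")
  sample_coords(df$id, df$lon, df$lat)
}

#' Construct a georeferenced grid surface
#'
#' A raster layer with cell-center registration, stored row-major from the
#' north-west corner (row 1 is the northernmost row). `NA` marks nodata.
#'
#' @param values numeric matrix (rows x cols).
#' @param xmin,ymax coordinates of the outer corner of the top-left cell.
#' @param xres,yres cell sizes in degrees (both > 0).
#' @param name layer name.
#' @return An object of class `grid_surface`.
#' @export
grid_surface <- function(values, xmin, ymax, xres, yres = xres,
                         name = "layer") {
  values <- as.matrix(values)
  stopifnot(xres > 0, yres > 0)
  structure(list(values = values, xmin = xmin, ymax = ymax,
                 xres = xres, yres = yres, name = name),
            class = "grid_surface")
}

#' @export
print.grid_surface <- function(x, ...) {
  cat(sprintf("<grid_surface '%s'> %d x %d cells, res (%g, %g), origin (%g, %g)\n",
              x$name, nrow(x$values), ncol(x$values), x$xres, x$yres,
              x$xmin, x$ymax))
  invisible(x)
}

#' @export
dim.grid_surface <- function(x) dim(x$values)

#' Cell-center coordinates of every cell of a grid surface
#' @param surface a `grid_surface`.
#' @return data.frame with columns row, col, lon, lat.
#' @export
cell_centers <- function(surface) {
  nr <- nrow(surface$values); nc <- ncol(surface$values)
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  data.frame(row = rows, col = cols,
             lon = surface$xmin + (cols - 0.5) * surface$xres,
             lat = surface$ymax - (rows - 0.5) * surface$yres)
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$xres - b$xres) < tol && abs(a$yres - b$yres) < tol
}

#' Locate the grid cell containing each point
#' @param surface a `grid_surface`.
#' @param coords a [sample_coords()] table.
#' @return data.frame with columns row, col (NA when outside the extent).
#' @export
cell_of_point <- function(surface, coords) {
  col <- floor((coords$lon - surface$xmin) / surface$xres) + 1
  row <- floor((surface$ymax - coords$lat) / surface$yres) + 1
  # points exactly on the max edge belong to the last cell
  col[coords$lon == surface$xmin + ncol(surface$values) * surface$xres] <-
    ncol(surface$values)
  row[coords$lat == surface$ymax - nrow(surface$values) * surface$yres] <-
    nrow(surface$values)
  outside <- col < 1 | col > ncol(surface$values) |
    row < 1 | row > nrow(surface$values)
  row[outside] <- NA_integer_
  col[outside] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Extract environmental values at sample points
#'
#' Exact cell lookup (no interpolation): each sample receives the stored value
#' of the cell containing it, for each layer. Samples on nodata cells get `NA`
#' with a warning naming them; samples outside the raster extent are an error.
#'
#' @param layers a list of co-registered `grid_surface` layers.
#' @param coords a [sample_coords()] table.
#' @return numeric matrix, individuals x layers, with layer names as columns.
#' @export
extract_env <- function(layers, coords) {
  if (inherits(layers, "grid_surface")) layers <- list(layers)
  stopifnot(length(layers) >= 1)
  for (l in layers[-1])
    if (!same_geometry(layers[[1]], l))
      stop("environmental layers are not co-registered")
  cells <- cell_of_point(layers[[1]], coords)
  if (anyNA(cells$row))
    stop("sample(s) outside raster extent: ",
         paste(coords$id[is.na(cells$row)], collapse = ", "))
  out <- sapply(layers, function(l)
    l$values[cbind(cells$row, cells$col)])
  out <- matrix(out, nrow = nrow(coords))
  colnames(out) <- vapply(layers, function(l) l$name, character(1))
  rownames(out) <- coords$id
  if (anyNA(out)) {
    bad <- coords$id[apply(is.na(out), 1, any)]
    warning("sample(s) on nodata cells: ", paste(bad, collapse = ", "))
  }
  out
}

#' Principal components of a set of environmental layers
#'
#' Each layer is standardized to zero mean and unit variance over its valid
#' (non-nodata) cells, then a PCA over cells decomposes the layer stack into
#' orthogonal component layers. Useful for collapsing collinear environmental
#' predictors before regression-style analyses.
#'
#' @param layers list of co-registered `grid_surface` layers (>= 2).
#' @param n_components number of components to return.
#' @return list with `layers` (component `grid_surface`s), `loadings`
#'   (variables x components) and `explained` (variance fractions).
#' @export
env_pca <- function(layers, n_components = length(layers)) {
  stopifnot(length(layers) >= 2, n_components <= length(layers),
            n_components >= 1)
  for (l in layers[-1])
    if (!same_geometry(layers[[1]], l)) stop("layers are not co-registered")
  vals <- sapply(layers, function(l) as.vector(l$values))
  colnames(vals) <- vapply(layers, function(l) l$name, character(1))
  valid <- stats::complete.cases(vals)
  sds <- apply(vals[valid, , drop = FALSE], 2, stats::sd)
  if (any(sds == 0))
    stop("constant layer(s): ", paste(colnames(vals)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(vals[valid, , drop = FALSE], center = TRUE, scale. = TRUE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  out_layers <- lapply(seq_len(n_components), function(i) {
    v <- rep(NA_real_, nrow(vals))
    v[valid] <- pc$x[, i]
    tmpl <- layers[[1]]
    grid_surface(matrix(v, nrow(tmpl$values), ncol(tmpl$values)),
                 tmpl$xmin, tmpl$ymax, tmpl$xres, tmpl$yres,
                 name = paste0("PC", i))
  })
  list(layers = out_layers,
       loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
       explained = explained)
}

#' Build an empty grid covering a set of points
#'
#' The grid covers the bounding box of the coordinates, expanded by `buffer`
#' (a fraction of each axis span, per side), at the requested resolution.
#' Grid dimensions are `ceiling(span / resolution)` per axis.
#'
#' @param coords a [sample_coords()] table with >= 2 distinct points.
#' @param resolution cell size in degrees.
#' @param buffer fraction of the axis span added on each side.
#' @return An empty (all-NA) `grid_surface`.
#' @export
make_grid <- function(coords, resolution, buffer = 0.1) {
  pts <- unique(cbind(coords$lon, coords$lat))
  if (nrow(pts) < 2) stop("need at least 2 distinct points to build a grid")
  span_x <- diff(range(coords$lon))
  span_y <- diff(range(coords$lat))
  if (resolution > max(span_x + 2 * buffer * span_x,
                       span_y + 2 * buffer * span_y))
    stop("resolution larger than the buffered bounding box extent")
  xmin <- min(coords$lon) - buffer * span_x
  xmax <- max(coords$lon) + buffer * span_x
  ymin <- min(coords$lat) - buffer * span_y
  ymax <- max(coords$lat) + buffer * span_y
  ncols <- max(1L, ceiling((xmax - xmin) / resolution))
  nrows <- max(1L, ceiling((ymax - ymin) / resolution))
  grid_surface(matrix(NA_real_, nrows, ncols), xmin = xmin, ymax = ymax,
               xres = resolution, yres = resolution, name = "grid")
}

#' Write a grid surface as an ESRI ASCII grid (.asc)
#'
#' Plain-text georeferenced raster format readable by common GIS software.
#' Nodata is written as -9999.
#'
#' @param surface a `grid_surface`.
#' @param path output path.
#' @export
write_gridsurface <- function(surface, path) {
  v <- surface$values
  if (abs(surface$xres - surface$yres) > 1e-12)
    stop("ESRI ASCII grids require square cells")
  yllcorner <- surface$ymax - nrow(v) * surface$yres
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", surface$xmin),
    sprintf("yllcorner %.10g", yllcorner),
    sprintf("cellsize %.10g", surface$xres),
    "NODATA_value -9999")
  v[is.na(v)] <- -9999
  body <- apply(v, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid (.asc) into a grid surface
#' @param path input path.
#' @param name layer name (defaults to the file stem).
#' @return A `grid_surface`.
#' @export
read_gridsurface <- function(path, name = NULL) {
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  vals <- do.call(rbind, lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals[vals == nodata] <- NA_real_
  grid_surface(vals,
               xmin = hdr$xllcorner,
               ymax = hdr$yllcorner + hdr$nrows * hdr$cellsize,
               xres = hdr$cellsize, yres = hdr$cellsize, name = name)
}
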