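#' Regular raster grid
#'
#' A grid in planar coordinates following the ESRI ASCII convention: lower
#' left corner `(x0, y0)`, square cells of size `cellsize`, and a values
#' matrix whose first row is the NORTHERNMOST row (rows are written top to
#' bottom in the `.asc` format).
#'
#' @param x0,y0 lower-left corner coordinates.
#' @param cellsize cell edge length, `> 0`.
#' @param ncols,nrows grid dimensions.
#' @param values `nrows x ncols` matrix (or `NULL` for an empty grid).
#' @param nodata marker for missing cells (default -9999).
#' @export
raster_grid <- function(x0, y0, cellsize, ncols, nrows, values = NULL,
                        nodata = -9999) {
  stopifnot(cellsize > 0, ncols >= 1, nrows >= 1)
  if (is.null(values)) values <- matrix(nodata, nrows, ncols)
  values <- as.matrix(values)
  if (!all(dim(values) == c(nrows, ncols)))
    stop("values must be an nrows x ncols matrix", call. = FALSE)
  structure(list(x0 = x0, y0 = y0, cellsize = cellsize, ncols = ncols,
                 nrows = nrows, values = values, nodata = nodata),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid %d x %d, cellsize %g, origin (%g, %g)>\n",
              x$nrows, x$ncols, x$cellsize, x$x0, x$y0))
  invisible(x)
}

## cell-center coordinates; matrix row 1 = top (northernmost) row
.grid_centers <- function(grid) {
  xs <- grid$x0 + (seq_len(grid$ncols) - 0.5) * grid$cellsize
  ys <- grid$y0 + (grid$nrows - seq_len(grid$nrows) + 0.5) * grid$cellsize
  list(x = xs, y = ys)
}

#' Inverse-distance-weighted value at arbitrary query points
#'
#' `sum(w_i v_i) / sum(w_i)` with `w_i = d_i^(-power)` over the `neighbors`
#' nearest data points (all points by default). A query within `eps` of a
#' data point takes that point's value exactly. Being a convex combination,
#' the interpolant can never leave the range of the input values.
#'
#' @param points data frame with columns `x`, `y`, `value`.
#' @param xout,yout query coordinates (equal length).
#' @param power distance-decay exponent, `> 0` (default 2).
#' @param neighbors number of nearest points to use, or `Inf` for all.
#' @param eps coincidence tolerance.
#' @export
idw_at <- function(points, xout, yout, power = 2, neighbors = Inf,
                   eps = 1e-12) {
  stopifnot(power > 0, length(xout) == length(yout))
  points <- as.data.frame(points)
  if (!all(c("x", "y", "value") %in% names(points)))
    stop("points must have columns x, y, value", call. = FALSE)
  if (nrow(points) == 0) stop("empty point set", call. = FALSE)
  key <- paste(points$x, points$y)
  if (anyDuplicated(key)) {
    dup <- split(points$value, key)
    if (any(vapply(dup, function(v) length(unique(v)) > 1, logical(1))))
      stop("duplicate coordinates with conflicting values", call. = FALSE)
    points <- points[!duplicated(key), , drop = FALSE]
  }
  k <- min(neighbors, nrow(points))
  vapply(seq_along(xout), function(i) {
    d <- sqrt((points$x - xout[i])^2 + (points$y - yout[i])^2)
    hit <- which(d < eps)
    if (length(hit)) return(points$value[hit[1]])
    if (k < nrow(points)) {
      sel <- order(d)[seq_len(k)]
      d <- d[sel]; v <- points$value[sel]
    } else v <- points$value
    w <- d^(-power)
    sum(w * v) / sum(w)
  }, numeric(1))
}

#' Interpolate scattered points onto a raster grid by IDW
#'
#' Evaluates [idw_at()] at every cell center of the grid specification.
#' The coincidence tolerance is `1e-9 * cellsize`.
#'
#' @param points data frame with columns `x`, `y`, `value`.
#' @param grid a [raster_grid()] (its values are replaced).
#' @param power distance-decay exponent (default 2, the common GIS default).
#' @param neighbors nearest-neighbor count, or `Inf` for all points.
#' @return the grid with interpolated values.
#' @export
idw_interpolate <- function(points, grid, power = 2, neighbors = Inf) {
  stopifnot(inherits(grid, "raster_grid"))
  ctr <- .grid_centers(grid)
  xy <- expand.grid(col = seq_len(grid$ncols), row = seq_len(grid$nrows))
  vals <- idw_at(points, ctr$x[xy$col], ctr$y[xy$row], power = power,
                 neighbors = neighbors, eps = 1e-9 * grid$cellsize)
  grid$values <- matrix(vals, nrow = grid$nrows, ncol = grid$ncols,
                        byrow = TRUE)
  grid
}

#' Write a raster grid in ESRI ASCII format
#'
#' Six header lines (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by one line per row, northernmost first. Output
#' is bit-stable for fixed inputs.
#'
#' @param grid a [raster_grid()].
#' @param path output path (`.asc`).
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  fmt <- function(v) format(v, digits = 15, trim = TRUE, scientific = FALSE)
  header <- c(paste("ncols", grid$ncols), paste("nrows", grid$nrows),
              paste("xllcorner", fmt(grid$x0)), paste("yllcorner", fmt(grid$y0)),
              paste("cellsize", fmt(grid$cellsize)),
              paste("NODATA_value", fmt(grid$nodata)))
  vals <- grid$values
  vals[!is.finite(vals)] <- grid$nodata
  rows <- apply(vals, 1, function(r) paste(fmt(r), collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path path to a `.asc` file written by [write_ascii_grid()] or a
#'   GIS tool.
#' @return a [raster_grid()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  val <- function(key) {
    i <- which(vapply(hdr, function(h) h[1] == key, logical(1)))
    if (!length(i)) stop("missing header field: ", key, call. = FALSE)
    as.numeric(hdr[[i]][2])
  }
  ncols <- val("ncols"); nrows <- val("nrows")
  vals <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  raster_grid(val("xllcorner"), val("yllcorner"), val("cellsize"),
              ncols, nrows, values = vals, nodata = val("nodata_value"))
}
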