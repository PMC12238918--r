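# Planar gridded rasters: the common spatial currency for elevation, NDVI
# scenes and lake/catchment masks.  Deliberately minimal -- planar metric
# coordinates only, no CRS handling.

#' Create a grid raster
#'
#' A `grid_raster` is a rectangular grid of cells in planar (metric)
#' coordinates. The value matrix is stored with row 1 as the *southernmost*
#' row and column 1 as the westernmost column, so `values[r, c]` sits at
#' coordinates `x_origin + (c - 0.5) * cell_size`,
#' `y_origin + (r - 0.5) * cell_size` (cell centers; the origin is the
#' lower-left corner of the grid).
#'
#' @param values Numeric matrix of cell values (row 1 = south).
#' @param x_origin,y_origin Coordinates (meters) of the lower-left corner.
#' @param cell_size Cell edge length in meters (> 0).
#' @param nodata Sentinel value marking invalid cells; must not occur as a
#'   valid value.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, x_origin = 0, y_origin = 0, cell_size = 1,
                        nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0,
            nrow(values) >= 1L, ncol(values) >= 1L)
  structure(
    list(values = values, x_origin = as.numeric(x_origin),
         y_origin = as.numeric(y_origin), cell_size = as.numeric(cell_size),
         nodata = as.numeric(nodata)),
    class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- valid_values(x)
  cat(sprintf("<grid_raster> %d x %d cells, cell_size %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$x_origin, x$y_origin))
  if (length(v)) {
    cat(sprintf("  values: [%g, %g], %d nodata cells\n", min(v), max(v),
                sum(is_nodata(x))))
  } else cat("  all cells nodata\n")
  invisible(x)
}

is_grid_raster <- function(x) inherits(x, "grid_raster")

#' @rdname grid_raster
#' @param x A `grid_raster`.
#' @export
is_nodata <- function(x) {
  stopifnot(is_grid_raster(x))
  is.na(x$values) | x$values == x$nodata
}

valid_values <- function(x) x$values[!is_nodata(x)]

#' Check two rasters share grid geometry
#' @param a,b `grid_raster` objects.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
stopifnot_same_geometry <- function(a, b) {
  stopifnot(is_grid_raster(a), is_grid_raster(b))
  if (!identical(dim(a$values), dim(b$values)) ||
      !isTRUE(all.equal(c(a$x_origin, a$y_origin, a$cell_size),
                        c(b$x_origin, b$y_origin, b$cell_size)))) {
    stop("rasters do not share grid geometry", call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert between coordinates and cell indices
#'
#' `cell_at()` maps a planar coordinate to the (row, col) of the containing
#' cell; `cell_xy()` returns the center coordinates of a cell.
#'
#' @param grid A `grid_raster`.
#' @param x,y Planar coordinates (meters).
#' @return `cell_at()`: integer vector `c(row, col)` or `NULL` when outside
#'   the grid. `cell_xy()`: numeric `c(x, y)`.
#' @export
cell_at <- function(grid, x, y) {
  r <- floor((y - grid$y_origin) / grid$cell_size) + 1
  c <- floor((x - grid$x_origin) / grid$cell_size) + 1
  if (r < 1 || r > nrow(grid$values) || c < 1 || c > ncol(grid$values)) {
    return(NULL)
  }
  c(row = as.integer(r), col = as.integer(c))
}

#' @rdname cell_at
#' @param row,col Cell indices (row 1 = southernmost).
#' @export
cell_xy <- function(grid, row, col) {
  c(x = grid$x_origin + (col - 0.5) * grid$cell_size,
    y = grid$y_origin + (row - 0.5) * grid$cell_size)
}

#' Read / write ESRI ASCII grid files
#'
#' The baseline raster interchange format: a 6-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by rows of numbers listed north to south. Masks are written as
#' 0/1 grids.
#'
#' @param path File path.
#' @return `read_esri_ascii()` returns a `grid_raster`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ESRI ASCII header in ", path, call. = FALSE)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("ESRI ASCII body has ", length(vals), " values, expected ", nr * nc,
         call. = FALSE)
  }
  # file rows run north->south; flip so row 1 = south
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)[nr:1, , drop = FALSE]
  grid_raster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nodata)
}

#' @rdname read_esri_ascii
#' @param grid A `grid_raster` to write.
#' @export
write_esri_ascii <- function(grid, path) {
  stopifnot(is_grid_raster(grid))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", nc), paste("nrows", nr),
    paste("xllcorner", format(grid$x_origin, scientific = FALSE)),
    paste("yllcorner", format(grid$y_origin, scientific = FALSE)),
    paste("cellsize", format(grid$cell_size, scientific = FALSE)),
    paste("NODATA_value", format(grid$nodata, scientific = FALSE))), con)
  for (r in nr:1) {
    writeLines(paste(format(m[r, ], trim = TRUE, scientific = FALSE,
                            digits = 10), collapse = " "), con)
  }
  invisible(path)
}
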