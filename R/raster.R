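#' Lightweight single-band raster
#'
#' A minimal in-memory raster on a regular grid of square cells: a numeric
#' matrix stored row-major north-up (row 1 is the northernmost row), plus the
#' coordinates of the lower-left corner and the cell size in km. `NA` cells
#' are nodata.
#'
#' @param values Numeric matrix, `nrow = ny`, `ncol = nx`, row 1 = north.
#' @param xll,yll Coordinates (km) of the lower-left corner of the grid.
#' @param cellsize Cell edge length in km (cells are area-true squares).
#' @return An `epi_raster` object.
#' @export
epi_raster <- function(values, xll = 0, yll = 0, cellsize = 1) {
  stopifnot(is.matrix(values), is.numeric(values) || all(is.na(values)))
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize),
            class = "epi_raster")
}

#' @export
print.epi_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<epi_raster> %d x %d cells, %.3g km cells, origin (%.1f, %.1f)\n",
              ncol(v), nrow(v), x$cellsize, x$xll, x$yll))
  cat(sprintf("  values: min %.4g, max %.4g, nodata %d\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' Cell-centre coordinates of a raster
#'
#' @param r An `epi_raster`.
#' @return A data.frame with `x`, `y` (km) and `value`, one row per cell in
#'   row-major north-up order.
#' @export
raster_cells <- function(r) {
  stopifnot(inherits(r, "epi_raster"))
  ny <- nrow(r$values); nx <- ncol(r$values)
  col <- rep(seq_len(nx), times = ny)
  row <- rep(seq_len(ny), each = nx)
  data.frame(
    x = r$xll + (col - 0.5) * r$cellsize,
    y = r$yll + (ny - row + 0.5) * r$cellsize,
    value = as.vector(t(r$values)))
}

same_geometry <- function(a, b) {
  isTRUE(all.equal(dim(a$values), dim(b$values))) &&
    isTRUE(all.equal(c(a$xll, a$yll, a$cellsize), c(b$xll, b$yll, b$cellsize)))
}

#' Read and write single-band rasters as ESRI ASCII grids
#'
#' Grids are serialized as ESRI ASCII grid (`.asc`): a six-line plain-text
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of cell values from north to south. The
#' round trip preserves values to full double precision and the geotransform
#' exactly.
#'
#' @param r An `epi_raster`.
#' @param path File path (conventionally `.asc`).
#' @param nodata Sentinel written for `NA` cells.
#' @return `write_raster` returns `path` invisibly; `read_raster` returns an
#'   `epi_raster`.
#' @export
write_raster <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "epi_raster"))
  v <- r$values
  if (any(v[!is.na(v)] == nodata))
    stop("raster error: data contain the nodata sentinel ", nodata, call. = FALSE)
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.17g", r$xll),
    sprintf("yllcorner %.17g", r$yll),
    sprintf("cellsize %.17g", r$cellsize),
    sprintf("NODATA_value %.17g", nodata))
  rows <- apply(v, 1, function(z) paste(sprintf("%.17g", z), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7)
    stop("I/O error: not an ASCII grid: ", path, call. = FALSE)
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% keys))
    stop("I/O error: ASCII grid header missing ",
         paste(setdiff(need, keys), collapse = ", "), call. = FALSE)
  nx <- as.integer(vals["ncols"]); ny <- as.integer(vals["nrows"])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nx * ny)
    stop("I/O error: ASCII grid body has ", length(body),
         " values, expected ", nx * ny, call. = FALSE)
  m <- matrix(body, nrow = ny, ncol = nx, byrow = TRUE)
  m[m == vals["nodata_value"]] <- NA_real_
  epi_raster(m, xll = vals[["xllcorner"]], yll = vals[["yllcorner"]],
             cellsize = vals[["cellsize"]])
}
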