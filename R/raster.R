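#' Georeferenced raster grid
#'
#' Lightweight container for a single-band raster: a numeric matrix plus
#' cell size and the coordinate of the centre of the top-left (northernmost,
#' westernmost) cell. Row 1 is the northernmost row; column 1 the westernmost
#' column. Coordinates are projected metres. `NA` marks nodata and is excluded
#' from every statistic computed downstream.
#'
#' Depth layers are stored positive-down in metres, so "shallow" means a
#' smaller value.
#'
#' @param values numeric matrix (rows north to south, columns west to east).
#' @param cell_size cell edge length in metres (> 0).
#' @param origin_x,origin_y coordinates (m) of the centre of cell `[1, 1]`.
#'   `origin_y` defaults to `(nrow - 1) * cell_size` so the southernmost row
#'   of cell centres sits at y = 0.
#' @param code layer code carried by the raster (e.g. `"DTH"`).
#' @return An object of class `benthoscape_raster`.
#' @export
raster_grid <- function(values, cell_size, origin_x = 0, origin_y = NULL,
                        code = "DTH") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  if (is.null(origin_y)) origin_y <- (nrow(values) - 1L) * cell_size
  structure(
    list(values = values, cell_size = cell_size,
         origin_x = origin_x, origin_y = origin_y, code = code),
    class = "benthoscape_raster"
  )
}

#' @export
print.benthoscape_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<benthoscape_raster> %s: %d x %d cells @ %g m\n",
              x$code, nrow(v), ncol(v), x$cell_size))
  cat(sprintf("  origin (cell centre): x = %g, y = %g; %d nodata cells\n",
              x$origin_x, x$origin_y, sum(is.na(v))))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  if (is.finite(rng[1])) cat(sprintf("  value range: [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.benthoscape_raster <- function(x) dim(x$values)

#' Cell-centre coordinates of a raster
#'
#' @param r a [raster_grid()].
#' @return list with `x` (length ncol, west to east) and `y` (length nrow,
#'   north to south).
#' @export
cell_centers <- function(r) {
  list(x = r$origin_x + (seq_len(ncol(r$values)) - 1L) * r$cell_size,
       y = r$origin_y - (seq_len(nrow(r$values)) - 1L) * r$cell_size)
}

#' Map points to raster cells
#'
#' Uses the half-open cell convention: cell `[i, j]` covers
#' `[x_centre - c/2, x_centre + c/2)` in x and `(y_centre - c/2, y_centre + c/2]`
#' in y, i.e. `floor((coord - edge) / cell_size)`. Points outside the raster
#' footprint get `NA` indices.
#'
#' @param r a [raster_grid()].
#' @param x,y point coordinates (m).
#' @return data.frame with integer columns `row`, `col`.
#' @export
point_to_cell <- function(r, x, y) {
  cs <- r$cell_size
  col <- floor((x - (r$origin_x - cs / 2)) / cs) + 1L
  row <- floor(((r$origin_y + cs / 2) - y) / cs) + 1L
  bad <- col < 1L | col > ncol(r$values) | row < 1L | row > nrow(r$values)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at point locations
#'
#' Nearest-cell rule: each point takes the value of the cell containing it
#' (no interpolation).
#'
#' @inheritParams point_to_cell
#' @return numeric vector, `NA` for points outside the raster.
#' @export
extract_at <- function(r, x, y) {
  idx <- point_to_cell(r, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- r$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) < tol &&
    abs(a$origin_x - b$origin_x) < tol &&
    abs(a$origin_y - b$origin_y) < tol
}

#' Read a raster from an ESRI ASCII grid file
#'
#' Supports the standard six-line header (`ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' `nodata_value`; the nodata line optional). GeoTIFF is not supported;
#' `.tif` paths produce an informative error.
#'
#' @param path file path.
#' @param code layer code to attach (defaults to the file base name).
#' @return a [raster_grid()].
#' @export
read_raster <- function(path, code = NULL) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stop("GeoTIFF is not supported; supply an ESRI ASCII grid (.asc)",
         call. = FALSE)
  }
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  body_start <- 1L
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2])
      body_start <- i + 1L
    } else break
  }
  for (k in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[k]])) {
      stop(sprintf("malformed ESRI ASCII header: missing '%s' (line %d)",
                   k, body_start), call. = FALSE)
    }
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[body_start:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf(
      "ESRI ASCII body has %d values but header declares %d x %d = %d (body starts line %d)",
      length(vals), nr, nc, nr * nc, body_start), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  cs <- hdr$cellsize
  ox <- if (!is.null(hdr$xllcenter)) hdr$xllcenter else hdr$xllcorner + cs / 2
  oy_ll <- if (!is.null(hdr$yllcenter)) hdr$yllcenter else hdr$yllcorner + cs / 2
  origin_y <- oy_ll + (nr - 1L) * cs
  if (is.null(code)) code <- sub("\\.[^.]*$", "", basename(path))
  raster_grid(m, cs, origin_x = ox, origin_y = origin_y, code = code)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Values are written with 17 significant digits so a write/read cycle
#' round-trips doubles bit-exactly. nodata cells are written as `-9999`.
#'
#' @param r a [raster_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stop("GeoTIFF output is not supported; use an .asc path", call. = FALSE)
  }
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  cs <- r$cell_size
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.17g", r$origin_x - cs / 2),
    sprintf("yllcorner %.17g", r$origin_y + cs / 2 - nr * cs),
    sprintf("cellsize %.17g", cs),
    "nodata_value -9999"
  )
  body <- apply(v, 1L, function(row) {
    row[is.na(row)] <- -9999
    paste(sprintf("%.17g", row), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}
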