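#' @title Terrain derivatives from bathymetry
#' @description Computes the twenty predictor layers used by the habitat
#'   models: raw and detrended bathymetry, Horn slope and aspect,
#'   Zevenbergen-Thorne curvatures, Jenness surface area, focal statistics of
#'   surface area, and hypsometric index / local relief range / standard
#'   deviation of depth over circular neighbourhoods.
#' @name terrain
NULL

# Layer codes of the full predictor stack, in declared (model) order.
#' Predictor codes of the full terrain stack
#' @return character vector of the twenty layer codes.
#' @export
terrain_codes <- function() {
  c("DTH", "DETRND", "ASP", "SLP", "PROFCURV", "PLANCURV", "CURV", "SURFA",
    "F7S", "F21S", "F21M", "HYP5", "HYP10", "HYP25",
    "RNG5", "RNG10", "RNG25", "STD5", "STD10", "STD25")
}

# ---- internal matrix helpers -------------------------------------------------

# out[i, j] = m[i + di, j + dj] where defined, else `fill`
shift_mat <- function(m, di, dj, fill = NA_real_) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r0 <- max(1L, 1L - di); r1 <- min(nr, nr - di)
  c0 <- max(1L, 1L - dj); c1 <- min(nc, nc - dj)
  if (r0 <= r1 && c0 <= c1) {
    out[r0:r1, c0:c1] <- m[(r0 + di):(r1 + di), (c0 + dj):(c1 + dj)]
  }
  out
}

# replicate-pad a matrix by one cell on every side (edge policy for 3x3 ops)
pad_replicate <- function(m) {
  m2 <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  cbind(m2[, 1, drop = FALSE], m2, m2[, ncol(m2), drop = FALSE])
}

# circular-kernel offsets: cell-centre distance <= radius (metres)
disc_offsets <- function(radius, cell_size) {
  k <- floor(radius / cell_size + 1e-9)
  g <- expand.grid(di = -k:k, dj = -k:k)
  keep <- cell_size * sqrt(g$di^2 + g$dj^2) <= radius + 1e-9
  g[keep, , drop = FALSE]
}

# shift-accumulate scan of a circular kernel: sums, counts and (optionally)
# running max/min over valid (non-NA) in-kernel cells
focal_scan <- function(values, cell_size, radius, minmax = FALSE) {
  off <- disc_offsets(radius, cell_size)
  w <- !is.na(values)
  # centre on the global mean: avoids catastrophic cancellation in the
  # sum-of-squares variance update (a constant layer then gives exactly 0)
  mu <- mean(values[w])
  if (!is.finite(mu)) mu <- 0
  v0 <- values - mu; v0[!w] <- 0
  wm <- matrix(as.numeric(w), nrow(values), ncol(values))
  s <- ss <- n <- matrix(0, nrow(values), ncol(values))
  if (minmax) {
    vmax <- matrix(-Inf, nrow(values), ncol(values))
    vmin <- matrix(Inf, nrow(values), ncol(values))
    vhi <- values; vhi[!w] <- -Inf
    vlo <- values; vlo[!w] <- Inf
  }
  for (i in seq_len(nrow(off))) {
    di <- off$di[i]; dj <- off$dj[i]
    s <- s + shift_mat(v0, di, dj, 0)
    ss <- ss + shift_mat(v0 * v0, di, dj, 0)
    n <- n + shift_mat(wm, di, dj, 0)
    if (minmax) {
      vmax <- pmax(vmax, shift_mat(vhi, di, dj, -Inf))
      vmin <- pmin(vmin, shift_mat(vlo, di, dj, Inf))
    }
  }
  out <- list(sum = s, sumsq = ss, n = n, mu = mu)
  if (minmax) {
    vmax[n == 0] <- NA_real_
    vmin[n == 0] <- NA_real_
    out$max <- vmax
    out$min <- vmin
  }
  out
}

scan_mean <- function(sc) {
  m <- sc$sum / sc$n + sc$mu
  m[sc$n == 0] <- NA_real_
  m
}

scan_sd <- function(sc) {
  # population standard deviation; nodata when fewer than 3 valid cells
  m <- sc$sum / sc$n
  v <- pmax(sc$sumsq / sc$n - m * m, 0)
  s <- sqrt(v)
  s[sc$n < 3] <- NA_real_
  s
}

# ---- operations --------------------------------------------------------------

#' Grid soundings by moving-window averaging
#'
#' Each output cell takes the mean of all soundings whose location lies within
#' `window_radius` of the cell centre; cells with no sounding in range become
#' nodata. Output geometry is anchored at the bounding box of the points.
#'
#' @param points data.frame with columns `x`, `y`, `depth` (m, positive-down).
#' @param cell_size output cell size (m).
#' @param window_radius averaging window radius (m), at least `cell_size / 2`.
#' @return a [raster_grid()] with code `"DTH"`.
#' @export
grid_soundings <- function(points, cell_size, window_radius) {
  if (!all(c("x", "y", "depth") %in% names(points)) || nrow(points) < 1L) {
    stop("`points` must be a non-empty data.frame with x, y, depth",
         call. = FALSE)
  }
  if (window_radius < cell_size / 2) {
    stop("`window_radius` must be at least cell_size / 2", call. = FALSE)
  }
  ox <- min(points$x); oymax <- max(points$y)
  nc <- floor((max(points$x) - ox) / cell_size + 1e-9) + 1L
  nr <- floor((oymax - min(points$y)) / cell_size + 1e-9) + 1L
  s <- matrix(0, nr, nc)
  n <- matrix(0, nr, nc)
  k <- ceiling(window_radius / cell_size) + 1L
  for (p in seq_len(nrow(points))) {
    px <- points$x[p]; py <- points$y[p]; pz <- points$depth[p]
    j0 <- floor((px - ox) / cell_size) + 1L
    i0 <- floor((oymax - py) / cell_size) + 1L
    ii <- max(1L, i0 - k):min(nr, i0 + k)
    jj <- max(1L, j0 - k):min(nc, j0 + k)
    cx <- ox + (jj - 1L) * cell_size
    cy <- oymax - (ii - 1L) * cell_size
    d2 <- outer(cy, cx, function(a, b) (a - py)^2 + (b - px)^2)
    hit <- d2 <= window_radius^2 + 1e-12
    s[ii, jj] <- s[ii, jj] + hit * pz
    n[ii, jj] <- n[ii, jj] + hit
  }
  out <- s / n
  out[n == 0] <- NA_real_
  raster_grid(out, cell_size, origin_x = ox, origin_y = oymax, code = "DTH")
}

#' Detrend a bathymetry raster
#'
#' Fits a linear polynomial `z = a + b x + c y` to all valid cells by least
#' squares and subtracts it, exposing local relief independent of the
#' regional depth gradient. The residual surface has mean zero (to within
#' 1e-9 of the depth range) and the operation is idempotent.
#'
#' @param grid a depth [raster_grid()].
#' @return a [raster_grid()] with code `"DETRND"`.
#' @export
detrend <- function(grid) {
  v <- grid$values
  cc <- cell_centers(grid)
  X <- cbind(1, rep(cc$x, each = nrow(v)), rep(cc$y, times = ncol(v)))
  z <- as.vector(v)
  ok <- !is.na(z)
  if (sum(ok) < 3L) stop("detrend needs at least 3 valid cells", call. = FALSE)
  fit <- tryCatch(stats::.lm.fit(X[ok, , drop = FALSE], z[ok]),
                  error = function(e) NULL)
  if (is.null(fit) || fit$rank < 3L) {
    # collinear cell layout (e.g. a single row/column of valid cells)
    stop("degenerate trend fit: valid cells are collinear", call. = FALSE)
  }
  res <- rep(NA_real_, length(z))
  res[ok] <- z[ok] - X[ok, , drop = FALSE] %*% fit$coefficients
  raster_grid(matrix(res, nrow(v), ncol(v)), grid$cell_size,
              origin_x = grid$origin_x, origin_y = grid$origin_y,
              code = "DETRND")
}

# 3x3 neighbourhood planes of a padded matrix, named by compass position
neighbourhoods3 <- function(m) {
  p <- pad_replicate(m)
  nr <- nrow(m); nc <- ncol(m)
  sub <- function(di, dj) p[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  list(nw = sub(-1, -1), n = sub(-1, 0), ne = sub(-1, 1),
       w = sub(0, -1),  c = sub(0, 0),  e = sub(0, 1),
       sw = sub(1, -1),  s = sub(1, 0),  se = sub(1, 1))
}

#' Slope and aspect (Horn 3x3)
#'
#' Horn's third-order finite differences on the 3x3 neighbourhood. Slope is
#' returned in degrees. Aspect is the compass direction of the steepest
#' descent (downslope), degrees clockwise from north in `[0, 360)`; cells with
#' gradient magnitude below 1e-12 are flat and get nodata aspect (0 would
#' alias a north-facing slope). Edges use replicate padding.
#'
#' @param grid a depth [raster_grid()] of at least 3x3 cells.
#' @return list with elements `SLP` and `ASP` (rasters).
#' @export
slope_aspect <- function(grid) {
  v <- grid$values
  if (nrow(v) < 3L || ncol(v) < 3L) stop("grid must be at least 3x3", call. = FALSE)
  nb <- neighbourhoods3(v)
  cs <- grid$cell_size
  # depth is positive-down: downslope is the direction of increasing depth
  ddx <- ((nb$ne + 2 * nb$e + nb$se) - (nb$nw + 2 * nb$w + nb$sw)) / (8 * cs)
  ddy <- ((nb$nw + 2 * nb$n + nb$ne) - (nb$sw + 2 * nb$s + nb$se)) / (8 * cs)
  mag <- sqrt(ddx^2 + ddy^2)
  slp <- atan(mag) * 180 / pi
  asp <- (atan2(ddx, ddy) * 180 / pi) %% 360
  asp[mag < 1e-12] <- NA_real_
  bad <- is.na(v)
  slp[bad] <- NA_real_; asp[bad] <- NA_real_
  mk <- function(m, code) raster_grid(m, cs, grid$origin_x, grid$origin_y, code)
  list(SLP = mk(slp, "SLP"), ASP = mk(asp, "ASP"))
}

#' Profile, plan and combined curvature (Zevenbergen-Thorne)
#'
#' Quadratic fit on the 3x3 window of the (negated, i.e. elevation-sense)
#' surface. Sign convention: convex-up relief (a bump or ridge crest) has
#' positive profile curvature. The combined index is
#' `CURV = PROFCURV - PLANCURV`. Cells with near-zero gradient have undefined
#' slope-line directions; profile and plan curvature are set to 0 there.
#' Edges use replicate padding. Units are 1/m.
#'
#' @param grid a [raster_grid()] (typically the detrended surface) >= 3x3.
#' @return list with elements `PROFCURV`, `PLANCURV`, `CURV` (rasters).
#' @export
curvatures <- function(grid) {
  v <- grid$values
  if (nrow(v) < 3L || ncol(v) < 3L) stop("grid must be at least 3x3", call. = FALSE)
  nb <- neighbourhoods3(-v)   # work in elevation sense (positive-up)
  L <- grid$cell_size
  D <- ((nb$w + nb$e) / 2 - nb$c) / L^2
  E <- ((nb$n + nb$s) / 2 - nb$c) / L^2
  FF <- (-nb$nw + nb$ne + nb$sw - nb$se) / (4 * L^2)
  G <- (-nb$w + nb$e) / (2 * L)
  H <- (nb$n - nb$s) / (2 * L)
  g2 <- G^2 + H^2
  prof <- -2 * (D * G^2 + E * H^2 + FF * G * H) / g2
  plan <- 2 * (D * H^2 + E * G^2 - FF * G * H) / g2
  flat <- g2 < 1e-18
  prof[flat] <- 0; plan[flat] <- 0
  bad <- is.na(v)
  prof[bad] <- NA_real_; plan[bad] <- NA_real_
  mk <- function(m, code) raster_grid(m, L, grid$origin_x, grid$origin_y, code)
  list(PROFCURV = mk(prof, "PROFCURV"), PLANCURV = mk(plan, "PLANCURV"),
       CURV = mk(prof - plan, "CURV"))
}

#' True surface area of the local neighbourhood (Jenness)
#'
#' Eight-triangle construction on the 3x3 neighbourhood: the surface area of
#' each triangle formed by the focal cell centre and two adjacent neighbour
#' centres is computed from its 3-D side lengths (Heron), halved in each
#' dimension so the eight triangles tile exactly one cell footprint. The
#' result is always at least the planar cell area, with equality iff the
#' neighbourhood is flat. Edges use replicate padding. Units m^2.
#'
#' @param grid a depth [raster_grid()] of at least 3x3 cells.
#' @return a [raster_grid()] with code `"SURFA"`.
#' @export
surface_area <- function(grid) {
  v <- grid$values
  if (nrow(v) < 3L || ncol(v) < 3L) stop("grid must be at least 3x3", call. = FALSE)
  nb <- neighbourhoods3(v)
  cs <- grid$cell_size
  # neighbours in cyclic order with their horizontal offsets from the centre
  ring <- list(
    list(z = nb$n, dx = 0, dy = cs),  list(z = nb$ne, dx = cs, dy = cs),
    list(z = nb$e, dx = cs, dy = 0),  list(z = nb$se, dx = cs, dy = -cs),
    list(z = nb$s, dx = 0, dy = -cs), list(z = nb$sw, dx = -cs, dy = -cs),
    list(z = nb$w, dx = -cs, dy = 0), list(z = nb$nw, dx = -cs, dy = cs)
  )
  heron <- function(a, b, c) {
    s <- (a + b + c) / 2
    sqrt(pmax(s * (s - a) * (s - b) * (s - c), 0))
  }
  area <- matrix(0, nrow(v), ncol(v))
  for (k in 1:8) {
    p1 <- ring[[k]]
    p2 <- ring[[if (k == 8) 1 else k + 1]]
    a <- sqrt(p1$dx^2 + p1$dy^2 + (p1$z - nb$c)^2) / 2
    b <- sqrt(p2$dx^2 + p2$dy^2 + (p2$z - nb$c)^2) / 2
    dd <- sqrt((p1$dx - p2$dx)^2 + (p1$dy - p2$dy)^2 + (p1$z - p2$z)^2) / 2
    area <- area + heron(a, b, dd)
  }
  area[is.na(v)] <- NA_real_
  raster_grid(area, cs, grid$origin_x, grid$origin_y, code = "SURFA")
}

#' Focal statistic over a circular kernel
#'
#' Per-cell mean or population standard deviation of a layer over the cells
#' whose centres lie within `radius` of the focal cell centre (the focal cell
#' included). Statistics are taken over valid in-kernel cells; the standard
#' deviation is nodata when fewer than 3 valid cells fall in the kernel, the
#' mean when none do.
#'
#' @param layer a [raster_grid()].
#' @param radius kernel radius in metres, at least `cell_size / 2`.
#' @param stat `"mean"` or `"stdev"`.
#' @param code layer code to attach to the result.
#' @return a [raster_grid()].
#' @export
focal_stat <- function(layer, radius, stat = c("mean", "stdev"), code = NULL) {
  stat <- match.arg(stat)
  if (radius < layer$cell_size / 2) {
    stop("`radius` must be at least cell_size / 2", call. = FALSE)
  }
  sc <- focal_scan(layer$values, layer$cell_size, radius)
  out <- if (stat == "mean") scan_mean(sc) else scan_sd(sc)
  if (is.null(code)) code <- sprintf("F%d%s", round(radius),
                                     if (stat == "mean") "M" else "S")
  raster_grid(out, layer$cell_size, layer$origin_x, layer$origin_y, code)
}

#' Hypsometric index over a circular kernel
#'
#' Relief-normalised position of the focal cell:
#' `HI = (z_max - z_focal) / (z_max - z_min)` over the kernel, with depth
#' positive-down, so `HI -> 1` marks a local high (shallow) point and
#' `HI -> 0` a local low. A flat kernel (max = min) yields 0.5 by convention.
#'
#' @param grid a depth [raster_grid()].
#' @param radius kernel radius (m), at least `cell_size`.
#' @param code layer code for the result (default derived from radius).
#' @return a [raster_grid()] with values in `[0, 1]`.
#' @export
hypsometric_index <- function(grid, radius, code = NULL) {
  if (radius < grid$cell_size) stop("`radius` must be at least cell_size", call. = FALSE)
  sc <- focal_scan(grid$values, grid$cell_size, radius, minmax = TRUE)
  rel <- sc$max - sc$min
  hi <- (sc$max - grid$values) / rel
  hi[rel < 1e-12] <- 0.5
  hi[is.na(grid$values)] <- NA_real_
  if (is.null(code)) code <- sprintf("HYP%g", radius)
  raster_grid(hi, grid$cell_size, grid$origin_x, grid$origin_y, code)
}

#' Local relief range over a circular kernel
#'
#' Maximum minus minimum depth among valid cells whose centres lie within
#' `radius` of the focal cell centre.
#'
#' @inheritParams hypsometric_index
#' @return a [raster_grid()].
#' @export
local_range <- function(grid, radius, code = NULL) {
  if (radius < grid$cell_size) stop("`radius` must be at least cell_size", call. = FALSE)
  sc <- focal_scan(grid$values, grid$cell_size, radius, minmax = TRUE)
  out <- sc$max - sc$min
  out[is.na(grid$values)] <- NA_real_
  if (is.null(code)) code <- sprintf("RNG%g", radius)
  raster_grid(out, grid$cell_size, grid$origin_x, grid$origin_y, code)
}

#' Local standard deviation of depth over a circular kernel
#'
#' Population standard deviation of valid in-kernel depths; nodata when fewer
#' than 3 valid cells fall in the kernel.
#'
#' @inheritParams hypsometric_index
#' @return a [raster_grid()].
#' @export
local_std <- function(grid, radius, code = NULL) {
  if (radius < grid$cell_size) stop("`radius` must be at least cell_size", call. = FALSE)
  sc <- focal_scan(grid$values, grid$cell_size, radius)
  out <- scan_sd(sc)
  out[is.na(grid$values)] <- NA_real_
  if (is.null(code)) code <- sprintf("STD%g", radius)
  raster_grid(out, grid$cell_size, grid$origin_x, grid$origin_y, code)
}

# ---- terrain stack -----------------------------------------------------------

#' Construct a terrain stack from co-registered layers
#'
#' @param layers named list of [raster_grid()] objects sharing one geometry.
#' @return an object of class `terrain_stack`.
#' @export
terrain_stack <- function(layers) {
  if (length(layers) == 0L || is.null(names(layers)) || any(names(layers) == "")) {
    stop("`layers` must be a non-empty named list", call. = FALSE)
  }
  ref <- layers[[1]]
  for (nm in names(layers)) {
    if (!inherits(layers[[nm]], "benthoscape_raster")) {
      stop("layer '", nm, "' is not a raster", call. = FALSE)
    }
    if (!same_geometry(layers[[nm]], ref)) {
      stop("layer '", nm, "' is not co-registered with the stack", call. = FALSE)
    }
    layers[[nm]]$code <- nm
  }
  structure(list(layers = layers, cell_size = ref$cell_size,
                 origin_x = ref$origin_x, origin_y = ref$origin_y,
                 dim = dim(ref$values)),
            class = "terrain_stack")
}

#' @export
print.terrain_stack <- function(x, ...) {
  cat(sprintf("<terrain_stack> %d layers, %d x %d cells @ %g m\n",
              length(x$layers), x$dim[1], x$dim[2], x$cell_size))
  cat("  ", paste(names(x$layers), collapse = " "), "\n")
  invisible(x)
}

#' Build the full twenty-layer predictor stack
#'
#' Derives every predictor layer from one bathymetry raster. Curvatures are
#' computed on the detrended surface (their purpose is local shape free of
#' the regional depth gradient); slope, aspect, surface area and the
#' depth-neighbourhood statistics are computed on raw bathymetry; the focal
#' statistics F7S / F21S / F21M are the standard deviation (7 m, 21 m) and
#' mean (21 m) of the surface-area layer.
#'
#' @param grid a depth [raster_grid()].
#' @return a [terrain_stack()] holding exactly the codes in [terrain_codes()].
#' @export
build_stack <- function(grid) {
  cs <- grid$cell_size
  dtr <- detrend(grid)
  sa <- slope_aspect(grid)
  cv <- curvatures(dtr)
  surfa <- surface_area(grid)
  radii <- c(`5` = 12.5, `10` = 25, `25` = 62.5)
  layers <- list(DTH = grid, DETRND = dtr, ASP = sa$ASP, SLP = sa$SLP,
                 PROFCURV = cv$PROFCURV, PLANCURV = cv$PLANCURV,
                 CURV = cv$CURV, SURFA = surfa,
                 F7S = focal_stat(surfa, 7, "stdev", code = "F7S"),
                 F21S = focal_stat(surfa, 21, "stdev", code = "F21S"),
                 F21M = focal_stat(surfa, 21, "mean", code = "F21M"))
  for (suf in names(radii)) {
    r <- radii[[suf]]
    sc <- focal_scan(grid$values, cs, r, minmax = TRUE)
    rel <- sc$max - sc$min
    hi <- (sc$max - grid$values) / rel
    hi[rel < 1e-12] <- 0.5
    std <- scan_sd(sc)
    bad <- is.na(grid$values)
    hi[bad] <- NA_real_; rel[bad] <- NA_real_; std[bad] <- NA_real_
    mk <- function(m, code) raster_grid(m, cs, grid$origin_x, grid$origin_y, code)
    layers[[paste0("HYP", suf)]] <- mk(hi, paste0("HYP", suf))
    layers[[paste0("RNG", suf)]] <- mk(rel, paste0("RNG", suf))
    layers[[paste0("STD", suf)]] <- mk(std, paste0("STD", suf))
  }
  layers <- layers[terrain_codes()]
  terrain_stack(layers)
}

#' Extract stack values at point locations
#'
#' @param stack a [terrain_stack()].
#' @param x,y point coordinates (m).
#' @param layers optional subset of layer codes.
#' @return data.frame, one column per layer, one row per point.
#' @export
stack_extract <- function(stack, x, y, layers = NULL) {
  if (is.null(layers)) layers <- names(stack$layers)
  missing <- setdiff(layers, names(stack$layers))
  if (length(missing)) {
    stop("stack is missing required layer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(stack$layers[layers], extract_at, x = x, y = y)
  as.data.frame(out, optional = TRUE)
}

# all cells of the stack as a predictor data.frame (column-major cell order)
stack_as_df <- function(stack, layers = NULL) {
  if (is.null(layers)) layers <- names(stack$layers)
  as.data.frame(lapply(stack$layers[layers], function(r) as.vector(r$values)),
                optional = TRUE)
}
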