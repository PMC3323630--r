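#' @title Synthetic seascape and survey generator
#' @description Seeded generators for every input the analysis consumes: a
#'   bathymetry raster with a regional depth gradient, a Gaussian reef ridge,
#'   smoothed rugose patches and optional acquisition striping; towed-video
#'   transect frames with rule-based substrate and biota labels; and a
#'   pot-line survey with Poisson catches planted on terrain predictors.
#'   Every generator is a pure function of its parameters and seed.
#' @name synthetic_data
NULL

#' Substrate class vocabulary
#' @return character vector of the seven primary substrate classes.
#' @export
substrate_classes <- function() {
  c("sand", "rhodolith", "obscured_reef", "flat_reef",
    "low_reef", "medium_reef", "high_reef")
}

#' Biota class vocabulary
#' @return character vector of dominant-biota classes.
#' @export
biota_classes <- function() {
  c("ecklonia", "other_macroalgae", "sessile_invertebrates", "hard_coral",
    "none")
}

#' Default substrate class proportions
#'
#' Target class frequencies for the rule-based substrate generator,
#' configured from the frame-classification tally of the motivating towed
#' video survey (normalised over classified substrate frames).
#'
#' @return named numeric vector summing to 1.
#' @export
substrate_targets <- function() {
  counts <- c(sand = 442, rhodolith = 992, high_reef = 55, medium_reef = 147,
              low_reef = 478, flat_reef = 620, obscured_reef = 412)
  counts / sum(counts)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

#' Seascape generator parameters
#'
#' Defaults describe the study conditions the generator emulates at its
#' working scale: a 1 km-square domain gridded at 3 m with a 45-80 m
#' depth gradient running offshore (+x), a 5 m-amplitude reef ridge striking
#' north-south, scattered rugose patches, and metre-scale sounding noise.
#' Depth is positive-down.
#'
#' @param extent_x,extent_y domain size (m).
#' @param cell_size raster cell size (m, default 3).
#' @param depth_min,depth_max depth at the inshore (x = 0) and offshore
#'   (x = extent_x) edges (m, positive-down; defaults 45 and 80).
#' @param ridge_amplitude height of the reef ridge above the regional trend
#'   (m; the ridge is shallower than its surroundings).
#' @param ridge_width Gaussian cross-section standard deviation of the ridge
#'   (m).
#' @param ridge_strike ridge strike, degrees clockwise from north (0 = a
#'   north-south ridge, parallel to the coast).
#' @param rugose_patch_density rugose patches per square kilometre.
#' @param patch_radius Gaussian envelope scale of each rugose patch (m).
#' @param patch_relief_sd relief standard deviation inside patches (m).
#' @param noise_sd white sounding noise standard deviation (m).
#' @param striping_amplitude optional boat-motion striping artifact amplitude
#'   (m; 0 disables).
#' @param striping_wavelength striping wavelength (m).
#' @param seed integer seed.
#' @return list of class `seascape_params`.
#' @export
seascape_params <- function(extent_x = 1000, extent_y = 1000, cell_size = 3,
                            depth_min = 45, depth_max = 80,
                            ridge_amplitude = 5, ridge_width = 120,
                            ridge_strike = 0, rugose_patch_density = 40,
                            patch_radius = 25, patch_relief_sd = 1,
                            noise_sd = 0.15, striping_amplitude = 0,
                            striping_wavelength = 50, seed = 1) {
  if (extent_x <= 0 || extent_y <= 0 || cell_size <= 0) {
    stop("extents and cell size must be positive", call. = FALSE)
  }
  if (!(depth_max > depth_min && depth_min > 0)) {
    stop("need depth_max > depth_min > 0 (positive-down metres)", call. = FALSE)
  }
  if (ridge_amplitude < 0 || noise_sd < 0 || striping_amplitude < 0 ||
      patch_relief_sd < 0) {
    stop("amplitudes must be non-negative", call. = FALSE)
  }
  structure(as.list(environment()), class = "seascape_params")
}

# light smoothing for the rugose-patch relief field (two 3x3 mean passes)
smooth33 <- function(m, passes = 2) {
  for (p in seq_len(passes)) {
    s <- matrix(0, nrow(m), ncol(m))
    n <- matrix(0, nrow(m), ncol(m))
    for (di in -1:1) for (dj in -1:1) {
      s <- s + shift_mat(m, di, dj, 0)
      n <- n + shift_mat(matrix(1, nrow(m), ncol(m)), di, dj, 0)
    }
    m <- s / n
  }
  m
}

#' Generate a synthetic bathymetry raster
#'
#' Depth is the sum of a linear inshore-offshore gradient, a Gaussian-profile
#' reef ridge through the domain centre (shallower than the trend), smoothed
#' random relief inside randomly placed rugose patches, white sounding noise,
#' and an optional sinusoidal striping artifact. Identical parameters and
#' seed give a bit-identical raster.
#'
#' @param params a [seascape_params()].
#' @return a depth [raster_grid()] (code `"DTH"`).
#' @export
make_bathymetry <- function(params) {
  stopifnot(inherits(params, "seascape_params"))
  cs <- params$cell_size
  nc <- max(3L, floor(params$extent_x / cs))
  nr <- max(3L, floor(params$extent_y / cs))
  xc <- (seq_len(nc) - 0.5) * cs
  yc <- (nr - seq_len(nr) + 0.5) * cs        # row 1 is northernmost
  X <- matrix(xc, nr, nc, byrow = TRUE)
  Y <- matrix(yc, nr, nc)
  depth <- params$depth_min +
    (params$depth_max - params$depth_min) * X / params$extent_x
  if (params$ridge_amplitude > 0) {
    th <- params$ridge_strike * pi / 180
    dperp <- (X - params$extent_x / 2) * cos(th) -
      (Y - params$extent_y / 2) * sin(th)
    depth <- depth -
      params$ridge_amplitude * exp(-dperp^2 / (2 * params$ridge_width^2))
  }
  with_seed(params$seed, {
    n_patch <- round(params$rugose_patch_density *
                       params$extent_x * params$extent_y / 1e6)
    if (n_patch > 0 && params$patch_relief_sd > 0) {
      px <- stats::runif(n_patch, 0, params$extent_x)
      py <- stats::runif(n_patch, 0, params$extent_y)
      env <- matrix(0, nr, nc)
      for (p in seq_len(n_patch)) {
        r2 <- (X - px[p])^2 + (Y - py[p])^2
        env <- env + exp(-r2 / (2 * params$patch_radius^2))
      }
      env <- pmin(env, 1)
      field <- smooth33(matrix(stats::rnorm(nr * nc), nr, nc))
      field <- field / stats::sd(field)
      depth <- depth + params$patch_relief_sd * env * field
    }
    if (params$noise_sd > 0) {
      depth <- depth + matrix(stats::rnorm(nr * nc, 0, params$noise_sd), nr, nc)
    }
  })
  if (params$striping_amplitude > 0) {
    depth <- depth +
      params$striping_amplitude * sin(2 * pi * Y / params$striping_wavelength)
  }
  raster_grid(depth, cs, origin_x = cs / 2, origin_y = (nr - 0.5) * cs,
              code = "DTH")
}

#' Place towed-video frames along transects
#'
#' Frames are placed at fixed along-track spacing on alternating
#' shore-perpendicular (east-west, the coastline runs north-south) and
#' shore-parallel (north-south) lines. Line positions follow a deterministic
#' low-discrepancy sequence so coverage is even at any frame count. All
#' frames lie inside the raster footprint.
#'
#' @param grid a [raster_grid()] supplying the footprint.
#' @param n_frames number of frames to place (>= 1).
#' @param spacing along-track frame spacing (m), at least the cell size.
#' @return data.frame `x`, `y`, `line`, `orientation`, with attributes
#'   `track_length_m` (sum of along-line gaps) and `n_lines`.
#' @export
sample_transects <- function(grid, n_frames, spacing) {
  if (n_frames < 1L) stop("`n_frames` must be at least 1", call. = FALSE)
  if (spacing < grid$cell_size) {
    stop("`spacing` must be at least the raster cell size", call. = FALSE)
  }
  W <- ncol(grid$values) * grid$cell_size
  H <- nrow(grid$values) * grid$cell_size
  x0 <- grid$origin_x - grid$cell_size / 2
  y0 <- grid$origin_y + grid$cell_size / 2 - H
  phi <- (sqrt(5) - 1) / 2
  xs <- ys <- numeric(0)
  line_id <- integer(0)
  orient <- character(0)
  k <- 0L
  while (length(xs) < n_frames) {
    k <- k + 1L
    t <- (k * phi) %% 1
    if (k %% 2L == 1L) {             # shore-perpendicular: runs along x
      yline <- y0 + min(t * H, H - 1e-9)
      np <- max(1L, floor((W - spacing / 2) / spacing - 1e-9) + 1L)
      px <- x0 + spacing / 2 + (seq_len(np) - 1L) * spacing
      py <- rep(yline, np)
      o <- "perpendicular"
    } else {                         # shore-parallel: runs along y
      xline <- x0 + min(t * W, W - 1e-9)
      np <- max(1L, floor((H - spacing / 2) / spacing - 1e-9) + 1L)
      py <- y0 + spacing / 2 + (seq_len(np) - 1L) * spacing
      px <- rep(xline, np)
      o <- "parallel"
    }
    take <- min(np, n_frames - length(xs))
    xs <- c(xs, px[seq_len(take)])
    ys <- c(ys, py[seq_len(take)])
    line_id <- c(line_id, rep(k, take))
    orient <- c(orient, rep(o, take))
  }
  out <- data.frame(x = xs, y = ys, line = line_id, orientation = orient,
                    stringsAsFactors = FALSE)
  per_line <- table(line_id)
  attr(out, "track_length_m") <- sum(pmax(per_line - 1L, 0L)) * spacing
  attr(out, "n_lines") <- length(per_line)
  out
}

derive_substrate_thresholds <- function(d, f, h, targets) {
  mu_d <- mean(d); sd_d <- stats::sd(d)
  mu_f <- mean(f); sd_f <- stats::sd(f)
  if (sd_d < 1e-12) sd_d <- 1
  if (sd_f < 1e-12) sd_f <- 1
  score <- -(d - mu_d) / sd_d + (f - mu_f) / sd_f
  hard_classes <- c("obscured_reef", "flat_reef", "low_reef", "medium_reef",
                    "high_reef")
  p_hard <- sum(targets[hard_classes])
  hard_cut <- unname(stats::quantile(score, 1 - p_hard, type = 7))
  hard <- score >= hard_cut
  cum <- cumsum(targets[c("obscured_reef", "flat_reef", "low_reef",
                          "medium_reef")]) / p_hard
  f_cuts <- if (any(hard)) {
    stats::setNames(unname(stats::quantile(f[hard], cum, type = 7)),
                    c("obscured", "flat", "low", "medium"))
  } else {
    stats::setNames(rep(Inf, 4), c("obscured", "flat", "low", "medium"))
  }
  p_rho <- unname(targets["rhodolith"] /
                    (targets["rhodolith"] + targets["sand"]))
  rho_cut <- if (any(!hard)) {
    unname(stats::quantile(h[!hard], p_rho, type = 7))
  } else 0
  list(mu_d = mu_d, sd_d = sd_d, mu_f = mu_f, sd_f = sd_f,
       hard_cut = hard_cut, f_cuts = f_cuts, rho_cut = rho_cut)
}

apply_substrate_rules <- function(d, f, h, th) {
  score <- -(d - th$mu_d) / th$sd_d + (f - th$mu_f) / th$sd_f
  hard <- score >= th$hard_cut
  lab <- character(length(d))
  lab[!hard & h <= th$rho_cut] <- "rhodolith"
  lab[!hard & h > th$rho_cut] <- "sand"
  lab[hard & f <= th$f_cuts["obscured"]] <- "obscured_reef"
  lab[hard & f > th$f_cuts["obscured"] & f <= th$f_cuts["flat"]] <- "flat_reef"
  lab[hard & f > th$f_cuts["flat"] & f <= th$f_cuts["low"]] <- "low_reef"
  lab[hard & f > th$f_cuts["low"] & f <= th$f_cuts["medium"]] <- "medium_reef"
  lab[hard & f > th$f_cuts["medium"]] <- "high_reef"
  lab
}

#' Assign substrate labels at frame locations
#'
#' Deterministic-given-seed labels from a planted rule set: frames score high
#' on a hardness index (shallower than the local trend and locally rough) are
#' reef, graded from obscured through flat, low and medium to high-profile
#' reef by increasing surface-area roughness (F7S); soft frames at local low
#' points (low hypsometric index) are rhodolith beds, the rest sand. Rule
#' thresholds are derived as quantiles of the planted layers so that class
#' frequencies match `targets`; symmetric label noise (uniform reassignment
#' over all classes) is applied at `noise_rate`.
#'
#' @param stack a [terrain_stack()] containing `DETRND`, `F7S` and `HYP5`.
#' @param x,y frame coordinates.
#' @param targets named class proportions (default [substrate_targets()]).
#' @param noise_rate symmetric label-noise rate (default 0.1).
#' @param seed integer seed (noise draws only; the rules are deterministic).
#' @param thresholds optional precomputed rule thresholds (as returned in the
#'   result attribute); when supplied the rules are applied verbatim.
#' @return factor of substrate labels with attribute `thresholds`.
#' @export
assign_substrate <- function(stack, x, y, targets = substrate_targets(),
                             noise_rate = 0.1, seed = 1, thresholds = NULL) {
  need <- c("DETRND", "F7S", "HYP5")
  missing <- setdiff(need, names(stack$layers))
  if (length(missing)) {
    stop("stack is missing required layer(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  v <- stack_extract(stack, x, y, need)
  if (anyNA(v)) stop("frame locations hit nodata cells", call. = FALSE)
  targets <- targets / sum(targets)
  th <- thresholds %||%
    derive_substrate_thresholds(v$DETRND, v$F7S, v$HYP5, targets)
  lab <- apply_substrate_rules(v$DETRND, v$F7S, v$HYP5, th)
  if (noise_rate > 0) {
    lab <- with_seed(seed, {
      flip <- stats::runif(length(lab)) < noise_rate
      lab[flip] <- sample(substrate_classes(), sum(flip), replace = TRUE)
      lab
    })
  }
  out <- factor(lab, levels = substrate_classes())
  attr(out, "thresholds") <- th
  out
}

#' Assign dominant-biota labels at frame locations
#'
#' Deterministic depth- and substrate-driven rules: kelp (*Ecklonia*) grows
#' only on hard substrate shallower than `kelp_max_depth`; sessile
#' invertebrates dominate hard substrate deeper than `invert_min_depth`;
#' hard substrate between the cutoffs and rhodolith beds carry other
#' macroalgae; bare sand carries none. Symmetric label noise as in
#' [assign_substrate()].
#'
#' @param stack a [terrain_stack()] containing `DTH`.
#' @param x,y frame coordinates.
#' @param substrate substrate labels for the same frames.
#' @param noise_rate symmetric label-noise rate (default 0.1).
#' @param seed integer seed.
#' @param kelp_max_depth deepest kelp occurrence (m, default 60).
#' @param invert_min_depth shallowest invertebrate dominance (m, default 65).
#' @return factor of biota labels.
#' @export
assign_biota <- function(stack, x, y, substrate, noise_rate = 0.1, seed = 1,
                         kelp_max_depth = 60, invert_min_depth = 65) {
  if (!"DTH" %in% names(stack$layers)) {
    stop("stack is missing required layer(s): DTH", call. = FALSE)
  }
  depth <- extract_at(stack$layers$DTH, x, y)
  if (anyNA(depth)) stop("frame locations hit nodata cells", call. = FALSE)
  substrate <- as.character(substrate)
  hard <- substrate %in% c("obscured_reef", "flat_reef", "low_reef",
                           "medium_reef", "high_reef")
  lab <- rep("none", length(depth))
  lab[substrate == "rhodolith"] <- "other_macroalgae"
  lab[hard] <- "other_macroalgae"
  lab[hard & depth <= kelp_max_depth] <- "ecklonia"
  lab[hard & depth >= invert_min_depth] <- "sessile_invertebrates"
  if (noise_rate > 0) {
    noise_pool <- setdiff(biota_classes(), "hard_coral")
    lab <- with_seed(seed, {
      flip <- stats::runif(length(lab)) < noise_rate
      lab[flip] <- sample(noise_pool, sum(flip), replace = TRUE)
      lab
    })
  }
  factor(lab, levels = biota_classes())
}

#' Lay out the pot-line survey grid
#'
#' Parallel north-south pot lines with fixed along-line spacing; the default
#' design is 11 lines of 30 pots 400 m apart (330 pots). Pot coordinates are
#' fixed and reused across simulated years. When a raster is supplied the
#' grid is centred in its footprint and must fit inside it.
#'
#' @param lines number of pot lines (default 11).
#' @param pots_per_line pots per line (default 30).
#' @param spacing along-line pot spacing (m, default 400).
#' @param line_spacing distance between lines (m, defaults to `spacing`).
#' @param origin_x,origin_y coordinate of the first pot of the first line
#'   (defaults 0, 0; ignored when `raster` is given).
#' @param raster optional [raster_grid()] to centre the grid in.
#' @return data.frame `pot_id`, `x`, `y`.
#' @export
make_pot_grid <- function(lines = 11, pots_per_line = 30, spacing = 400,
                          line_spacing = spacing, origin_x = 0, origin_y = 0,
                          raster = NULL) {
  if (lines < 1L || pots_per_line < 1L) {
    stop("`lines` and `pots_per_line` must be at least 1", call. = FALSE)
  }
  width <- (lines - 1) * line_spacing
  height <- (pots_per_line - 1) * spacing
  if (!is.null(raster)) {
    W <- ncol(raster$values) * raster$cell_size
    H <- nrow(raster$values) * raster$cell_size
    if (width > W || height > H) {
      stop(sprintf(
        "pot grid (%g x %g m) exceeds the raster extent (%g x %g m)",
        width, height, W, H), call. = FALSE)
    }
    origin_x <- (raster$origin_x - raster$cell_size / 2) + (W - width) / 2
    origin_y <- (raster$origin_y + raster$cell_size / 2 - H) + (H - height) / 2
  }
  g <- expand.grid(pot = seq_len(pots_per_line), line = seq_len(lines))
  data.frame(pot_id = sprintf("L%02dP%02d", g$line, g$pot),
             x = origin_x + (g$line - 1) * line_spacing,
             y = origin_y + (g$pot - 1) * spacing,
             stringsAsFactors = FALSE)
}

#' Lobster occupancy rule
#'
#' Log-linear Poisson catch model used to plant a recoverable signal:
#' per pot-year, `count ~ Poisson(exp(log(mean_catch) + intercept + s))`
#' where `s = sum(beta_j * z_j)` is the planted signal over the named terrain
#' layers standardised across valid raster cells and clamped to the
#' asymmetric range `[-4, 1.5]`: catch in suitable habitat saturates (a pot
#' attracts at most a few lobsters per lift, keeping the count histogram
#' dominated by zeros and ones) while unsuitable habitat is effectively
#' empty. The clamp also guards against the heavy tails of terrain
#' derivatives such as F7S, which would otherwise drive a log-linear rate to
#' physically absurd catches inside rugose patches. Presence is `count > 0`.
#' The default plants a strong geophysical signal: lobsters concentrate
#' where the seafloor rises above the local trend (negative detrended depth)
#' and terrain is rough at fine scales. The default coefficients are large
#' relative to the clamp, making habitat quality effectively bimodal: good
#' ground catches `mean_catch * exp(1.5)` lobsters per lift (presence nearly
#' certain over a pooled survey) and poor ground `mean_catch * exp(-4)`
#' (presence rare).
#'
#' @param intercept additive log-scale offset (default 0).
#' @param coefficients named vector, terrain layer code -> log-rate units per
#'   standardised unit.
#' @param mean_catch expected lobsters per pot at a zero linear predictor
#'   (default 0.5).
#' @return list of class `occupancy_rule`.
#' @export
occupancy_rule <- function(intercept = 0,
                           coefficients = c(DETRND = -3, F7S = 3,
                                            RNG25 = 1.5, HYP5 = 1.5),
                           mean_catch = 0.5) {
  if (mean_catch <= 0) stop("`mean_catch` must be positive", call. = FALSE)
  if (length(coefficients) && is.null(names(coefficients))) {
    stop("`coefficients` must be named by predictor code", call. = FALSE)
  }
  structure(list(intercept = intercept, coefficients = coefficients,
                 mean_catch = mean_catch),
            class = "occupancy_rule")
}

#' Simulate pot catches
#'
#' Draws seeded Poisson lobster counts per pot and year from an
#' [occupancy_rule()] evaluated on the terrain stack at the pot coordinates.
#'
#' @param stack a [terrain_stack()].
#' @param pots a [make_pot_grid()] data.frame.
#' @param rule an [occupancy_rule()].
#' @param years number of survey years (default 3).
#' @param seed integer seed.
#' @return data.frame `pot_id`, `x`, `y`, `year`, `count`, `presence`.
#' @export
simulate_catch <- function(stack, pots, rule = occupancy_rule(), years = 3,
                           seed = 1) {
  codes <- names(rule$coefficients)
  unknown <- setdiff(codes, names(stack$layers))
  if (length(unknown)) {
    stop("unknown predictor code(s) in occupancy rule: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  signal <- 0
  if (length(codes)) {
    v <- stack_extract(stack, pots$x, pots$y, codes)
    if (anyNA(v)) stop("pot locations hit nodata cells", call. = FALSE)
    for (cd in codes) {
      cells <- stack$layers[[cd]]$values
      mu <- mean(cells, na.rm = TRUE)
      sg <- stats::sd(cells, na.rm = TRUE)
      if (sg < 1e-12) sg <- 1
      signal <- signal + rule$coefficients[[cd]] * (v[[cd]] - mu) / sg
    }
    signal <- pmin(pmax(signal, -4), 1.5)
  }
  lambda <- exp(log(rule$mean_catch) + rule$intercept + signal)
  n <- nrow(pots)
  counts <- with_seed(seed, {
    matrix(stats::rpois(n * years, rep(lambda, years)), n, years)
  })
  out <- data.frame(
    pot_id = rep(pots$pot_id, years),
    x = rep(pots$x, years), y = rep(pots$y, years),
    year = rep(seq_len(years), each = n),
    count = as.vector(counts), stringsAsFactors = FALSE)
  out$presence <- out$count > 0
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default synthetic study scenario
#'
#' The package's reference study conditions: a 1 km-square seascape at 3 m
#' resolution (depth 45-80 m, north-south reef ridge, rugose patches), 1000
#' video frames on alternating transects, the 330-pot 11 x 30 survey grid
#' scaled to fit the domain (30 m along-line, 90 m between lines), three
#' survey years, 10% label noise, and the default planted occupancy rule.
#'
#' @param seed integer scenario seed; per-stage substreams are derived from
#'   it by fixed offsets.
#' @param ... overrides for any scenario field (e.g. `substrate_noise = 0`).
#' @return list of class `benthoscape_scenario`.
#' @export
default_scenario <- function(seed = 1, ...) {
  sc <- list(
    seascape = seascape_params(seed = seed),
    n_frames = 1000,
    frame_spacing = 15,
    pot_lines = 11, pots_per_line = 30,
    pot_spacing = 30, pot_line_spacing = 90,
    years = 3,
    substrate_noise = 0.1, biota_noise = 0.1,
    kelp_max_depth = 60, invert_min_depth = 65,
    rule = occupancy_rule(),
    seed = seed)
  dots <- list(...)
  for (nm in names(dots)) sc[[nm]] <- dots[[nm]]
  sc$seascape$seed <- sc$seed
  class(sc) <- "benthoscape_scenario"
  sc
}

#' Generate every input of a scenario
#'
#' Runs the full generator chain: bathymetry, terrain stack, transect frames
#' with substrate and biota labels, pot grid and simulated catches. Each
#' stage draws from its own substream (scenario seed plus a fixed offset) so
#' stages are independently reproducible.
#'
#' @param scenario a [default_scenario()] list.
#' @return list with `params`, `bathymetry`, `stack`, `frames` (x, y,
#'   substrate, biota), `pots`, `catch`.
#' @export
simulate_scenario <- function(scenario = default_scenario()) {
  seed <- scenario$seed
  bathy <- make_bathymetry(scenario$seascape)
  stack <- build_stack(bathy)
  frames <- sample_transects(bathy, scenario$n_frames, scenario$frame_spacing)
  frames$substrate <- assign_substrate(stack, frames$x, frames$y,
                                       noise_rate = scenario$substrate_noise,
                                       seed = seed + 2L)
  frames$biota <- assign_biota(stack, frames$x, frames$y, frames$substrate,
                               noise_rate = scenario$biota_noise,
                               seed = seed + 3L,
                               kelp_max_depth = scenario$kelp_max_depth,
                               invert_min_depth = scenario$invert_min_depth)
  pots <- make_pot_grid(scenario$pot_lines, scenario$pots_per_line,
                        scenario$pot_spacing, scenario$pot_line_spacing,
                        raster = bathy)
  catch <- simulate_catch(stack, pots, scenario$rule, scenario$years,
                          seed = seed + 5L)
  list(params = scenario, bathymetry = bathy, stack = stack, frames = frames,
       pots = pots, catch = catch)
}
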