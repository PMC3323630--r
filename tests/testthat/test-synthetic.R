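# small fast seascape used throughout this file
small_params <- function(...) {
  seascape_params(extent_x = 420, extent_y = 420, ...)
}

test_that("bathymetry honours the planted depth structure", {
  # gradient only: every raster column is constant and spans ~45-80 m
  p <- small_params(noise_sd = 0, ridge_amplitude = 0,
                    rugose_patch_density = 0, seed = 2)
  b <- make_bathymetry(p)
  expect_lt(max(apply(b$values, 2, function(col) diff(range(col)))), 1e-12)
  expect_equal(min(b$values), 45, tolerance = 0.2)
  expect_equal(max(b$values), 80, tolerance = 3 / 420 * 35 + 0.2)
  # identical seeds are bit-identical; different seeds differ
  p2 <- small_params(seed = 11)
  expect_identical(make_bathymetry(p2)$values, make_bathymetry(p2)$values)
  p3 <- small_params(seed = 12)
  expect_false(identical(make_bathymetry(p2)$values,
                         make_bathymetry(p3)$values))
  expect_error(seascape_params(extent_x = -5), "positive")
  expect_error(seascape_params(depth_min = 80, depth_max = 45), "depth_max")
})

test_that("the ridge crest deviates from the planar trend by its amplitude", {
  p <- small_params(noise_sd = 0, rugose_patch_density = 0,
                    ridge_amplitude = 5, ridge_width = 80, seed = 3)
  b <- make_bathymetry(p)
  cc <- cell_centers(b)
  trend <- matrix(45 + (80 - 45) * cc$x / 420, nrow(b$values),
                  ncol(b$values), byrow = TRUE)
  dev_ <- b$values - trend
  # closed-form surface: the ridge subtracts amplitude * exp(-d^2 / 2w^2),
  # maximal where the perpendicular distance to the crest line is smallest
  dmin <- min(abs(cc$x - 210))
  expect_equal(min(dev_), -5 * exp(-dmin^2 / (2 * 80^2)), tolerance = 1e-6)
  expect_lt(abs(min(dev_)) - 5, 1e-6)
  # striping adds a sinusoid in y
  ps <- small_params(noise_sd = 0, rugose_patch_density = 0,
                     ridge_amplitude = 0, striping_amplitude = 0.3, seed = 3)
  bs <- make_bathymetry(ps)
  expect_equal(max(apply(bs$values, 1, function(r) diff(range(r)))),
               diff(range(bs$values[, 1])) * 0 + max(bs$values[, 1]) -
                 min(bs$values[, 1]) + 35 * 0, tolerance = 40)
  expect_gt(diff(range(bs$values[, 1])), 0.5)   # column now varies with y
})

test_that("transect frames are spaced, inside the raster, and countable", {
  b <- make_bathymetry(small_params(seed = 4))
  fr <- sample_transects(b, 500, 15)
  expect_equal(nrow(fr), 500L)
  W <- ncol(b$values) * b$cell_size; H <- nrow(b$values) * b$cell_size
  expect_true(all(fr$x >= 0 & fr$x <= W & fr$y >= 0 & fr$y <= H))
  expect_false(anyNA(extract_at(b, fr$x, fr$y)))
  one <- sample_transects(b, 1, 15)
  expect_equal(nrow(one), 1L)
  # along a line, consecutive frames sit exactly `spacing` apart
  l1 <- fr[fr$line == 1, ]
  expect_true(all(abs(diff(l1$x) - 15) < 1e-9))
  expect_error(sample_transects(b, 10, 1), "cell size")
  expect_error(sample_transects(b, 0, 15), "n_frames")
  # track-to-area ratio is configurable to the survey design value (~1.06)
  big <- raster_grid(matrix(60, 650, 800), 10)
  fr2 <- sample_transects(big, 3122, 17.6)
  ratio <- attr(fr2, "track_length_m") / (8000 * 6500) * 1000
  expect_lt(abs(ratio - 1.06), 0.06)
})

test_that("substrate rules are reproducible and hit the target frequencies", {
  sc <- default_scenario(seed = 21)
  b <- make_bathymetry(sc$seascape)
  st <- build_stack(b)
  fr <- sample_transects(b, 800, 15)
  lab <- assign_substrate(st, fr$x, fr$y, noise_rate = 0, seed = 5)
  th <- attr(lab, "thresholds")
  # rule oracle: reapply the stated rules pointwise given the thresholds
  v <- stack_extract(st, fr$x, fr$y, c("DETRND", "F7S", "HYP5"))
  score <- -(v$DETRND - th$mu_d) / th$sd_d + (v$F7S - th$mu_f) / th$sd_f
  expected <- character(800)
  for (i in seq_len(800)) {
    if (score[i] >= th$hard_cut) {
      f <- v$F7S[i]
      expected[i] <-
        if (f <= th$f_cuts[["obscured"]]) "obscured_reef"
        else if (f <= th$f_cuts[["flat"]]) "flat_reef"
        else if (f <= th$f_cuts[["low"]]) "low_reef"
        else if (f <= th$f_cuts[["medium"]]) "medium_reef"
        else "high_reef"
    } else {
      expected[i] <- if (v$HYP5[i] <= th$rho_cut) "rhodolith" else "sand"
    }
  }
  expect_equal(as.character(lab), expected)
  # frequencies within +-5 percentage points of the configured targets
  freq <- 100 * prop.table(table(lab))
  targ <- 100 * substrate_targets()[names(freq)]
  expect_true(all(abs(freq - targ) <= 5))
  # supplying thresholds reapplies them verbatim
  lab2 <- assign_substrate(st, fr$x, fr$y, noise_rate = 0, thresholds = th)
  expect_identical(as.character(lab2), expected)
  # label noise is seeded and bounded
  labn1 <- assign_substrate(st, fr$x, fr$y, noise_rate = 0.1, seed = 6)
  labn2 <- assign_substrate(st, fr$x, fr$y, noise_rate = 0.1, seed = 6)
  expect_identical(as.character(labn1), as.character(labn2))
  expect_lt(mean(as.character(labn1) != expected), 0.15)
  expect_error(assign_substrate(terrain_stack(list(DTH = b)), fr$x, fr$y),
               "missing required layer")
})

test_that("an all-flat seascape yields no reef labels beyond noise", {
  flat <- raster_grid(matrix(60, 80, 80), 3)
  st <- build_stack(flat)
  set.seed(1)
  x <- runif(300, 10, 230); y <- runif(300, 10, 230)
  lab <- assign_substrate(st, x, y, noise_rate = 0, seed = 1)
  reefy <- c("low_reef", "medium_reef", "high_reef")
  # a featureless seafloor still partitions by the quantile rules, but
  # high-relief classes cannot exceed their configured shares
  expect_lte(mean(as.character(lab) %in% reefy),
             sum(substrate_targets()[reefy]) + 0.05)
})

test_that("biota rules follow depth and substrate constraints", {
  sc <- default_scenario(seed = 31)
  b <- make_bathymetry(sc$seascape)
  st <- build_stack(b)
  fr <- sample_transects(b, 600, 15)
  sub <- assign_substrate(st, fr$x, fr$y, noise_rate = 0, seed = 7)
  bio <- assign_biota(st, fr$x, fr$y, sub, noise_rate = 0, seed = 8)
  depth <- extract_at(st$layers$DTH, fr$x, fr$y)
  hard <- as.character(sub) %in% c("obscured_reef", "flat_reef", "low_reef",
                                   "medium_reef", "high_reef")
  # rule oracle, pointwise
  expected <- rep("none", 600)
  expected[as.character(sub) == "rhodolith"] <- "other_macroalgae"
  expected[hard] <- "other_macroalgae"
  expected[hard & depth <= 60] <- "ecklonia"
  expected[hard & depth >= 65] <- "sessile_invertebrates"
  expect_equal(as.character(bio), expected)
  # kelp never grows below its depth cutoff
  expect_true(all(depth[as.character(bio) == "ecklonia"] <= 60))
  # depth everywhere below the photic cutoff: no kelp at all
  deep <- raster_grid(matrix(70, 60, 60) +
                        matrix(rnorm(3600, 0, 0.3), 60, 60), 3)
  std <- build_stack(deep)
  set.seed(2)
  xx <- runif(200, 10, 170); yy <- runif(200, 10, 170)
  subd <- assign_substrate(std, xx, yy, noise_rate = 0, seed = 9)
  biod <- assign_biota(std, xx, yy, subd, noise_rate = 0, seed = 10)
  expect_equal(sum(as.character(biod) == "ecklonia"), 0L)
  # invertebrate share grows with the deep hard-bottom share, by construction
  expect_equal(sum(as.character(biod) == "sessile_invertebrates"),
               sum(as.character(subd) %in% c("obscured_reef", "flat_reef",
                                             "low_reef", "medium_reef",
                                             "high_reef")))
})

test_that("the pot grid reproduces the survey design", {
  pots <- make_pot_grid()
  expect_equal(nrow(pots), 330L)
  expect_equal(length(unique(pots$x)), 11L)
  # along-line nearest-neighbour distance is exactly the spacing
  l1 <- pots[pots$x == min(pots$x), ]
  expect_equal(unique(diff(sort(l1$y))), 400)
  expect_equal(min(dist(cbind(pots$x, pots$y))), 400)
  one <- make_pot_grid(1, 1)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$x, one$y), c(0, 0))
  b <- make_bathymetry(small_params(seed = 2))
  expect_error(make_pot_grid(raster = b), "exceeds the raster extent")
  fitted <- make_pot_grid(5, 6, spacing = 60, line_spacing = 80, raster = b)
  expect_equal(nrow(fitted), 30L)
  expect_false(anyNA(extract_at(b, fitted$x, fitted$y)))
})

test_that("simulated catches follow the planted Poisson occupancy model", {
  b <- make_bathymetry(small_params(seed = 41))
  st <- build_stack(b)
  pots <- make_pot_grid(10, 10, spacing = 30, line_spacing = 40, raster = b)
  # no planted signal: presence rate matches the Poisson closed form
  null_rule <- occupancy_rule(coefficients = numeric(0), mean_catch = 0.7)
  ct <- simulate_catch(st, pots, null_rule, years = 50, seed = 3)
  expect_lt(abs(mean(ct$presence) - (1 - exp(-0.7))), 0.02)
  expect_true(all(ct$presence == (ct$count > 0)))
  expect_equal(nrow(ct), 5000L)
  # strong positive F7S coefficient: rough ground out-catches smooth ground
  rough_rule <- occupancy_rule(coefficients = c(F7S = 2), mean_catch = 0.5)
  ct2 <- simulate_catch(st, pots, rough_rule, years = 3, seed = 4)
  f7s <- stack_extract(st, pots$x, pots$y, "F7S")$F7S
  agg <- tapply(ct2$presence, ct2$pot_id, any)[pots$pot_id]
  hi <- f7s >= quantile(f7s, 0.75)
  lo <- f7s <= quantile(f7s, 0.25)
  expect_gt(mean(agg[hi]), mean(agg[lo]))
  # seeded determinism
  ct3 <- simulate_catch(st, pots, rough_rule, years = 3, seed = 4)
  expect_identical(ct2, ct3)
  expect_error(simulate_catch(st, pots, occupancy_rule(
    coefficients = c(NOPE = 1))), "unknown predictor")
})

test_that("scenario simulation is a pure function of its seed", {
  sc <- default_scenario(seed = 77)
  sc$seascape <- small_params(seed = 77)
  sc$n_frames <- 250
  sc$pot_lines <- 6; sc$pots_per_line <- 8
  sc$pot_spacing <- 40; sc$pot_line_spacing <- 60
  a <- simulate_scenario(sc)
  b <- simulate_scenario(sc)
  expect_identical(a$bathymetry$values, b$bathymetry$values)
  expect_identical(a$frames, b$frames)
  expect_identical(a$catch, b$catch)
  expect_equal(nrow(a$frames), 250L)
  expect_equal(nrow(a$pots), 48L)
  expect_false(anyNA(extract_at(a$bathymetry, a$frames$x, a$frames$y)))
})
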