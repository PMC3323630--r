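#' @title Observation readers, run configuration and manifests
#' @name io_cli
#' @description CSV readers for frame and pot observations with vocabulary
#'   checking and alias mapping, YAML run-configuration loading, and a
#'   machine-readable run manifest.
NULL

# documented alias table: survey shorthand -> canonical category
category_aliases <- function() {
  c(kelp = "ecklonia", ecklonia = "ecklonia",
    macroalgae = "other_macroalgae", other_algae = "other_macroalgae",
    inverts = "sessile_invertebrates",
    invertebrates = "sessile_invertebrates",
    sponges = "sessile_invertebrates",
    coral = "hard_coral", bare = "none")
}

normalise_category <- function(x, vocabulary, kind, rows) {
  raw <- tolower(trimws(as.character(x)))
  canon <- gsub("[ -]+", "_", raw)
  al <- category_aliases()
  mapped <- ifelse(canon %in% names(al), al[canon], canon)
  bad <- which(!mapped %in% vocabulary)
  if (length(bad)) {
    stop(sprintf("unknown %s category '%s' at row %d", kind, raw[bad[1]],
                 rows[bad[1]]), call. = FALSE)
  }
  factor(unname(mapped), levels = vocabulary)
}

check_bounds <- function(df, raster, what) {
  if (is.null(raster)) return(invisible(NULL))
  idx <- point_to_cell(raster, df$x, df$y)
  out <- which(is.na(idx$row))
  if (length(out)) {
    stop(sprintf("%s at row %d lies outside the raster footprint",
                 what, out[1]), call. = FALSE)
  }
  invisible(NULL)
}

#' Read frame or pot observations from CSV
#'
#' Frames need columns `x`, `y`, `substrate`, `biota`; pots need `pot_id`,
#' `x`, `y`, `year`, `count`. Categories are vocabulary-checked (with a
#' documented alias table, e.g. `kelp` maps to `ecklonia`); violations name
#' the offending row. Pot presence is derived as `count > 0`; negative
#' counts are rejected. When a raster is supplied, coordinates must fall
#' inside its footprint.
#'
#' @param path CSV file path.
#' @param kind `"frames"` or `"pots"`.
#' @param raster optional [raster_grid()] for coordinate bounds checking.
#' @return data.frame of validated records.
#' @export
read_observations <- function(path, kind = c("frames", "pots"),
                              raster = NULL) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (kind == "frames") {
    need <- c("x", "y", "substrate", "biota")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("frames CSV missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    df$substrate <- normalise_category(df$substrate, substrate_classes(),
                                       "substrate", seq_len(nrow(df)))
    df$biota <- normalise_category(df$biota, biota_classes(), "biota",
                                   seq_len(nrow(df)))
    check_bounds(df, raster, "frame")
  } else {
    need <- c("pot_id", "x", "y", "year", "count")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("pots CSV missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    bad <- which(df$count < 0 | is.na(df$count))
    if (length(bad)) {
      stop(sprintf("invalid lobster count at row %d", bad[1]), call. = FALSE)
    }
    df$presence <- df$count > 0
    check_bounds(df, raster, "pot")
  }
  df
}

#' Write frame observations as CSV
#' @param frames data.frame with `x`, `y`, `substrate`, `biota`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frames_csv <- function(frames, path) {
  utils::write.csv(frames[, c("x", "y", "substrate", "biota")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write pot records as CSV
#' @param catch data.frame with `pot_id`, `x`, `y`, `year`, `count`,
#'   `presence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pots_csv <- function(catch, path) {
  utils::write.csv(
    catch[, c("pot_id", "x", "y", "year", "count", "presence")], path,
    row.names = FALSE)
  invisible(path)
}

#' Load a run configuration from YAML
#'
#' Top-level keys: `seed`, `scenario` (any [default_scenario()] /
#' [seascape_params()] field, including an `occupancy` block with
#' `intercept`, `mean_catch` and `coefficients`), and `modelling` (any
#' [pipeline_config()] field). Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed_top <- c("seed", "scenario", "modelling")
  unknown <- setdiff(names(raw), allowed_top)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  seed <- raw$seed %||% 1L
  sc_over <- raw$scenario %||% list()
  seascape_fields <- names(formals(seascape_params))
  ss_over <- sc_over[intersect(names(sc_over), seascape_fields)]
  other <- sc_over[setdiff(names(sc_over), c(seascape_fields, "occupancy"))]
  scenario <- do.call(default_scenario, c(list(seed = seed), other))
  if (length(ss_over)) {
    scenario$seascape <- do.call(seascape_params,
                                 c(ss_over, list(seed = seed)))
  }
  if (!is.null(sc_over$occupancy)) {
    oc <- sc_over$occupancy
    scenario$rule <- occupancy_rule(
      intercept = oc$intercept %||% 0,
      coefficients = unlist(oc$coefficients %||%
                              as.list(occupancy_rule()$coefficients)),
      mean_catch = oc$mean_catch %||% 1.2)
  }
  mod <- raw$modelling %||% list()
  cfg_fields <- setdiff(names(formals(pipeline_config)), c("scenario", "seed"))
  unknown <- setdiff(names(mod), cfg_fields)
  if (length(unknown)) {
    stop("unknown modelling key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config,
          c(list(scenario = scenario, seed = seed), mod))
}

#' Write a machine-readable run manifest
#'
#' Records the package version, seeds and the full configuration of a run as
#' JSON.
#'
#' @param config a [pipeline_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  payload <- list(
    package = "benthoscape",
    version = as.character(utils::packageVersion("benthoscape")),
    seed = config$seed,
    scenario = config$scenario[setdiff(names(config$scenario),
                                       c("rule", "seascape"))],
    seascape = unclass(config$scenario$seascape),
    occupancy = unclass(config$scenario$rule),
    modelling = list(folds = config$folds,
                     rate_threshold = config$rate_threshold,
                     n_boot = config$n_boot,
                     split_fraction = config$split_fraction,
                     block_size = config$block_size,
                     spatial_fraction = config$spatial_fraction,
                     substrate_source = config$substrate_source,
                     control = unclass(config$control)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
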