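#' @title Hierarchical habitat-cascade pipeline
#' @description Orchestrates the full analysis: a seeded 75/25 split of the
#'   frame observations, one-vs-rest substrate models on terrain predictors,
#'   biota models on terrain plus substrate indicators, a lobster
#'   presence/absence model on the full predictor pool, evaluation of every
#'   model (random and spatially independent holdouts), indicator
#'   semivariograms, and full-coverage probability / binary / integrated
#'   class maps.
#' @name pipeline
NULL

#' Seeded random train/validation split
#'
#' Uniform assignment without replacement; the model set receives
#' `round(fraction * n)` records (round-half-even, so 3122 records at 0.75
#' give 2342). Identical seeds give identical membership.
#'
#' @param n number of records (or a data.frame, whose row count is used).
#' @param fraction model-set fraction, strictly between 0 and 1 (default 0.75).
#' @param seed integer seed.
#' @return list with integer index vectors `model` and `validation`.
#' @export
seeded_split <- function(n, fraction = 0.75, seed = 1) {
  if (is.data.frame(n)) n <- nrow(n)
  if (n < 4L) stop("need at least 4 records to split", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must be strictly between 0 and 1", call. = FALSE)
  }
  k <- round(fraction * n)
  idx <- with_seed(seed, sample.int(n, k))
  list(model = sort(idx), validation = setdiff(seq_len(n), idx))
}

#' Pipeline configuration
#'
#' Bundles the scenario (or externally loaded inputs), growth controls,
#' evaluation settings and the kernel/block geometry. Every random stage
#' draws from a substream derived from `seed` by a fixed offset
#' (frame split +6, CV folds +7, bootstrap +8, spatial blocks +9, pot split
#' +10), so stages are independently reproducible.
#'
#' @param scenario a [default_scenario()] (used when inputs are simulated).
#' @param control a [growth_control()].
#' @param folds cross-validation folds (default 10).
#' @param rate_threshold CV misclassification threshold for pruning
#'   (default 0.15).
#' @param n_boot bootstrap replicates for AUC intervals (default 1000).
#' @param split_fraction model-set fraction (default 0.75).
#' @param block_size spatial-block edge for the spatially independent split
#'   (m, default 250).
#' @param spatial_fraction holdout fraction of the spatial split
#'   (default 0.25).
#' @param spatial_buffer drop model points in blocks adjacent to validation
#'   blocks (default FALSE).
#' @param substrate_source `"predicted"` (default) to feed biota and lobster
#'   models full-coverage predicted substrate indicators, `"observed"` to use
#'   the frame annotations (biota models only).
#' @param seed master integer seed (defaults to the scenario seed).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = default_scenario(),
                            control = growth_control(), folds = 10,
                            rate_threshold = 0.15, n_boot = 1000,
                            split_fraction = 0.75, block_size = 250,
                            spatial_fraction = 0.25, spatial_buffer = FALSE,
                            substrate_source = c("predicted", "observed"),
                            seed = NULL) {
  substrate_source <- match.arg(substrate_source)
  if (is.null(seed)) seed <- scenario$seed
  structure(list(scenario = scenario, control = control, folds = folds,
                 rate_threshold = rate_threshold, n_boot = n_boot,
                 split_fraction = split_fraction, block_size = block_size,
                 spatial_fraction = spatial_fraction,
                 spatial_buffer = spatial_buffer,
                 substrate_source = substrate_source, seed = seed),
            class = "pipeline_config")
}

# fit + prune + evaluate one binary model; returns NULL when the class is
# absent from the training rows
fit_class_model <- function(X, y, split, label, config) {
  ytr <- y[split$model]
  if (length(unique(ytr)) < 2L) {
    warning("class '", label, "' absent (or universal) in training data; skipped")
    return(NULL)
  }
  Xtr <- X[split$model, , drop = FALSE]
  grown <- grow_tree(Xtr, ytr, config$control)
  pruned <- cv_prune(grown, Xtr, ytr, folds = config$folds,
                     rate_threshold = config$rate_threshold,
                     seed = config$seed + 7L)
  fit_stat <- adjusted_d2(pruned$tree, Xtr, ytr)
  Xva <- X[split$validation, , drop = FALSE]
  yva <- y[split$validation]
  report <- tryCatch(
    model_report(pruned$tree, predict_prob(pruned$tree, Xva), yva,
                 adj_d2 = fit_stat$adj_d2, label = label,
                 n_boot = config$n_boot, seed = config$seed + 8L),
    error = function(e) {
      warning("evaluation of '", label, "' failed: ", conditionMessage(e))
      NULL
    })
  list(tree = pruned$tree, sequence = pruned$sequence, report = report,
       fit = fit_stat, label = label)
}

substrate_model_defs <- function() {
  list(sand = "sand", rhodolith = "rhodolith",
       obscured_reef = "obscured_reef", flat_reef = "flat_reef",
       low_reef = "low_reef",
       reef = c("low_reef", "medium_reef", "high_reef"))
}

#' Fit the one-vs-rest substrate models
#'
#' Six binary models on terrain predictors only: sand, rhodolith, obscured
#' reef, flat reef, low reef, and a comprehensive reef class merging low,
#' medium and high relief reef. All models share one seeded 75/25 frame
#' split. Frames with missing predictor values are excluded.
#'
#' @param stack a [terrain_stack()].
#' @param frames data.frame with `x`, `y`, `substrate`.
#' @param config a [pipeline_config()].
#' @return list of class-model fits (each with `tree`, `report`, `fit`),
#'   with attributes `split` and `frame_data`.
#' @export
fit_substrate_models <- function(stack, frames, config = pipeline_config()) {
  X <- stack_extract(stack, frames$x, frames$y, terrain_codes())
  keep <- stats::complete.cases(X)
  if (!all(keep)) {
    warning(sum(!keep), " frame(s) with missing predictors excluded")
    X <- X[keep, , drop = FALSE]
    frames <- frames[keep, , drop = FALSE]
  }
  split <- seeded_split(nrow(X), config$split_fraction, config$seed + 6L)
  defs <- substrate_model_defs()
  models <- list()
  for (nm in names(defs)) {
    y <- as.integer(as.character(frames$substrate) %in% defs[[nm]])
    models[[nm]] <- fit_class_model(X, y, split, nm, config)
  }
  models <- Filter(Negate(is.null), models)
  attr(models, "split") <- split
  attr(models, "frame_data") <- cbind(frames[, c("x", "y")], X)
  models
}

# predicted binary class indicators (prob >= the model's P_fair) at points;
# `extra` supplies indicator columns upstream models already produced
predict_binary_at <- function(models, stack, x, y, extra = NULL) {
  X <- stack_extract(stack, x, y)
  if (!is.null(extra)) X <- cbind(X, extra)
  out <- list()
  for (nm in names(models)) {
    m <- models[[nm]]
    thr <- if (!is.null(m$report)) m$report$p_fair else 0.5
    out[[nm]] <- as.integer(predict_prob(m$tree, X) >= thr)
  }
  as.data.frame(out, optional = TRUE)
}

biota_model_classes <- function() {
  c("ecklonia", "other_macroalgae", "sessile_invertebrates")
}

#' Fit the biota models
#'
#' Three binary models (*Ecklonia* kelp, other macroalgae, sessile
#' invertebrates) on terrain predictors plus substrate indicators. Hard coral
#' is not modelled (too rare). Substrate indicators come from the predicted
#' substrate models by default (`config$substrate_source`), or from the
#' observed frame annotations.
#'
#' @param stack a [terrain_stack()].
#' @param frames data.frame with `x`, `y`, `substrate`, `biota`.
#' @param substrate_models result of [fit_substrate_models()].
#' @param config a [pipeline_config()].
#' @return list of class-model fits with attribute `split`.
#' @export
fit_biota_models <- function(stack, frames, substrate_models,
                             config = pipeline_config()) {
  X <- stack_extract(stack, frames$x, frames$y, terrain_codes())
  keep <- stats::complete.cases(X)
  if (!all(keep)) {
    warning(sum(!keep), " frame(s) with missing predictors excluded")
    X <- X[keep, , drop = FALSE]
    frames <- frames[keep, , drop = FALSE]
  }
  if (config$substrate_source == "predicted") {
    sub <- predict_binary_at(substrate_models, stack, frames$x, frames$y)
  } else {
    s <- as.character(frames$substrate)
    sub <- data.frame(
      sand = as.integer(s == "sand"),
      rhodolith = as.integer(s == "rhodolith"),
      obscured_reef = as.integer(s == "obscured_reef"),
      flat_reef = as.integer(s == "flat_reef"),
      reef = as.integer(s %in% c("low_reef", "medium_reef", "high_reef")))
  }
  names(sub) <- paste0("SUB_", names(sub))
  X <- cbind(X, sub)
  split <- seeded_split(nrow(X), config$split_fraction, config$seed + 6L)
  models <- list()
  for (nm in biota_model_classes()) {
    y <- as.integer(as.character(frames$biota) == nm)
    models[[nm]] <- fit_class_model(X, y, split, nm, config)
  }
  models <- Filter(Negate(is.null), models)
  attr(models, "split") <- split
  models
}

#' Fit the lobster presence/absence model
#'
#' Pools catches across years (one record per pot; presence = any lobster in
#' any year) and fits a binary tree on the full predictor pool: the twenty
#' terrain layers plus the predicted substrate and biota indicators at the
#' pot coordinates. Evaluated on a seeded 25% random holdout and, separately,
#' refitted and evaluated on a block-based spatially independent holdout.
#'
#' @param stack a [terrain_stack()].
#' @param substrate_models,biota_models fitted model lists.
#' @param catch a [simulate_catch()]-style data.frame (`pot_id`, `x`, `y`,
#'   `year`, `count`, `presence`).
#' @param config a [pipeline_config()].
#' @return a model fit (as in [fit_substrate_models()]) with extra elements
#'   `spatial_report` and `spatial_fit`, and attribute `pot_data`.
#' @export
fit_lobster_model <- function(stack, substrate_models, biota_models, catch,
                              config = pipeline_config()) {
  agg <- stats::aggregate(presence ~ pot_id + x + y, data = catch, FUN = any)
  y <- as.integer(agg$presence)
  X <- stack_extract(stack, agg$x, agg$y, terrain_codes())
  sub <- predict_binary_at(substrate_models, stack, agg$x, agg$y)
  names(sub) <- paste0("SUB_", names(sub))
  bio <- predict_binary_at(biota_models, stack, agg$x, agg$y, extra = sub)
  names(bio) <- paste0("BIO_", names(bio))
  X <- cbind(X, sub, bio)
  keep <- stats::complete.cases(X)
  if (!all(keep)) {
    warning(sum(!keep), " pot(s) with missing predictors excluded")
    X <- X[keep, , drop = FALSE]
    agg <- agg[keep, , drop = FALSE]
    y <- y[keep]
  }
  if (length(unique(y)) < 2L) {
    warning("all pots share one presence state; returning a single-leaf model")
    tree <- grow_tree(X, y * 0L + y, growth_control(minsize = .Machine$integer.max))
    return(list(tree = tree, report = NULL, spatial_report = NULL,
                label = "lobster"))
  }
  split <- seeded_split(nrow(X), config$split_fraction, config$seed + 10L)
  fit <- fit_class_model(X, y, split, "lobster", config)
  sp <- spatial_split(agg$x, agg$y, config$spatial_fraction,
                      config$block_size, seed = config$seed + 9L,
                      buffer = config$spatial_buffer)
  sp_fit <- fit_class_model(X, y, list(model = sp$model,
                                       validation = sp$validation),
                            "lobster_spatial", config)
  fit$spatial_report <- if (!is.null(sp_fit)) sp_fit$report else NULL
  fit$spatial_fit <- if (!is.null(sp_fit)) sp_fit$fit else NULL
  attr(fit, "pot_data") <- cbind(agg[, c("x", "y")], X, presence = y)
  fit
}

#' Predict full-coverage class maps
#'
#' Routes every raster cell through each fitted model to produce a
#' probability map, thresholds it at the model's P-fair to produce a binary
#' presence/absence map, and combines the maps into one integrated
#' categorical map: each cell takes the class with the highest probability
#' among classes whose probability reaches their own P-fair, or
#' `"unclassified"`.
#'
#' @param models a named list of fitted class models.
#' @param stack a [terrain_stack()] (plus any indicator layers the models
#'   split on, supplied via `extra`).
#' @param extra optional named list of additional predictor rasters.
#' @param classes classes entering the integrated map (default: all models).
#' @return list of class `class_map_set`: per class `probability`, `p_fair`,
#'   `binary`; plus `integrated` (integer raster with a `classes` attribute,
#'   0 = unclassified).
#' @export
predict_class_maps <- function(models, stack, extra = NULL, classes = NULL) {
  lay <- stack$layers
  if (!is.null(extra)) lay <- c(lay, extra)
  full <- terrain_stack(lay)
  X <- stack_as_df(full)
  if (is.null(classes)) classes <- names(models)
  ref <- full$layers[[1]]
  mk <- function(vals, code) {
    raster_grid(matrix(vals, nrow(ref$values), ncol(ref$values)),
                ref$cell_size, ref$origin_x, ref$origin_y, code)
  }
  out <- list()
  prob_mat <- matrix(NA_real_, nrow(X), length(classes),
                     dimnames = list(NULL, classes))
  for (nm in names(models)) {
    m <- models[[nm]]
    need <- setdiff(unique(m$tree$frame$var), "<leaf>")
    missing <- setdiff(need, names(X))
    if (length(missing)) {
      stop("stack lacks layer(s) required by model '", nm, "': ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    p <- predict_prob(m$tree, X)
    thr <- if (!is.null(m$report)) m$report$p_fair else 0.5
    out[[nm]] <- list(probability = mk(p, paste0("P_", nm)), p_fair = thr,
                      binary = mk(as.numeric(p >= thr), paste0("B_", nm)))
    if (nm %in% classes) {
      q <- p
      q[p < thr] <- NA_real_     # below its own P_fair: not a candidate
      prob_mat[, nm] <- q
    }
  }
  best <- rep(0L, nrow(prob_mat))
  any_ok <- rowSums(!is.na(prob_mat)) > 0
  best[any_ok] <- max.col(replace(prob_mat, is.na(prob_mat), -1),
                          ties.method = "first")[any_ok]
  integrated <- mk(as.numeric(best), "INTEGRATED")
  attr(integrated, "classes") <- classes
  structure(c(out, list(integrated = integrated)), class = "class_map_set")
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) the study inputs and executes the hierarchical
#' cascade: terrain stack, substrate models, biota models (using substrate
#' indicators), lobster model (using everything), evaluation reports,
#' indicator semivariograms and full-coverage maps. The hierarchy order is
#' enforced by construction. Rerunning with the same configuration
#' reproduces every report byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, writes
#'   `reports.csv`, serialized trees, semivariogram CSVs, ESRI ASCII rasters
#'   and a JSON run manifest.
#' @param maps compute full-coverage maps (default TRUE).
#' @param semivariograms compute indicator semivariograms of the observed
#'   classes (default TRUE).
#' @param inputs optional pre-generated inputs (a [simulate_scenario()]
#'   result) to analyse instead of simulating.
#' @return list with `inputs`, `substrate`, `biota`, `lobster`, `reports`
#'   (data.frame), `semivariograms`, `maps`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         maps = TRUE, semivariograms = TRUE, inputs = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  inputs <- inputs %||% stage("simulate", simulate_scenario(config$scenario))
  stack <- inputs$stack
  sub_models <- stage("substrate", fit_substrate_models(stack, inputs$frames, config))
  bio_models <- stage("biota", fit_biota_models(stack, inputs$frames, sub_models, config))
  lob <- stage("lobster", fit_lobster_model(stack, sub_models, bio_models,
                                            inputs$catch, config))
  all_models <- c(sub_models, bio_models, list(lobster = lob))
  reports <- lapply(all_models, function(m) m$report)
  reports <- Filter(Negate(is.null), reports)
  report_df <- do.call(rbind, lapply(reports, as.data.frame))
  if (!is.null(lob$spatial_report)) {
    spr <- as.data.frame(lob$spatial_report)
    report_df <- rbind(report_df, spr)
  }
  rownames(report_df) <- NULL
  svs <- NULL
  if (semivariograms) {
    svs <- stage("semivariogram", {
      fr <- inputs$frames
      out <- list()
      for (cl in names(substrate_model_defs())) {
        ind <- as.integer(as.character(fr$substrate) %in%
                            substrate_model_defs()[[cl]])
        out[[paste0("substrate_", cl)]] <-
          indicator_semivariogram(fr$x, fr$y, ind)
      }
      for (cl in biota_model_classes()) {
        ind <- as.integer(as.character(fr$biota) == cl)
        out[[paste0("biota_", cl)]] <-
          indicator_semivariogram(fr$x, fr$y, ind)
      }
      out
    })
  }
  map_set <- NULL
  if (maps) {
    map_set <- stage("maps", {
      sub_maps <- predict_class_maps(
        sub_models, stack,
        classes = intersect(c("sand", "rhodolith", "obscured_reef",
                              "flat_reef", "reef"), names(sub_models)))
      sub_layers <- lapply(sub_models, function(m) {
        sub_maps[[m$label]]$binary
      })
      names(sub_layers) <- paste0("SUB_", names(sub_models))
      bio_maps <- predict_class_maps(bio_models, stack, extra = sub_layers)
      bio_layers <- lapply(bio_models, function(m) bio_maps[[m$label]]$binary)
      names(bio_layers) <- paste0("BIO_", names(bio_models))
      lob_maps <- predict_class_maps(list(lobster = lob), stack,
                                     extra = c(sub_layers, bio_layers))
      list(substrate = sub_maps, biota = bio_maps, lobster = lob_maps)
    })
  }
  result <- list(inputs = inputs, substrate = sub_models, biota = bio_models,
                 lobster = lob, reports = report_df, semivariograms = svs,
                 maps = map_set, config = config)
  if (!is.null(out_dir)) {
    stage("write", write_pipeline_outputs(result, out_dir))
  }
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$reports, file.path(out_dir, "reports.csv"),
                   row.names = FALSE)
  tree_dir <- file.path(out_dir, "trees")
  dir.create(tree_dir, showWarnings = FALSE)
  for (m in c(result$substrate, result$biota, list(result$lobster))) {
    write_tree(m$tree, file.path(tree_dir, paste0(m$label, ".txt")))
  }
  if (!is.null(result$semivariograms)) {
    sv_dir <- file.path(out_dir, "semivariograms")
    dir.create(sv_dir, showWarnings = FALSE)
    for (nm in names(result$semivariograms)) {
      write_semivariogram_csv(result$semivariograms[[nm]],
                              file.path(sv_dir, paste0(nm, ".csv")))
    }
  }
  write_raster(result$inputs$bathymetry, file.path(out_dir, "bathymetry.asc"))
  if (!is.null(result$maps)) {
    write_raster(result$maps$substrate$integrated,
                 file.path(out_dir, "substrate_integrated.asc"))
    write_raster(result$maps$biota$integrated,
                 file.path(out_dir, "biota_integrated.asc"))
    write_raster(result$maps$lobster$lobster$probability,
                 file.path(out_dir, "lobster_probability.asc"))
    write_raster(result$maps$lobster$lobster$binary,
                 file.path(out_dir, "lobster_binary.asc"))
  }
  write_manifest(result$config, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' Planted-signal recovery study
#'
#' Reruns the pipeline over several seeds at zero noise — no substrate or
#' biota label noise and no sounding noise — with the default planted
#' occupancy rule (signal on DETRND, F7S, RNG25 and HYP5) and records, per
#' seed: whether the pruned lobster tree retained only geophysical (terrain)
#' predictors, its random-holdout and spatially-independent-holdout AUCs,
#' its training adjusted D-squared, and the share of explained deviance
#' carried by the planted variables.
#'
#' @param n_seeds number of replicate seeds (default 20).
#' @param base_seed first seed; replicate s uses `base_seed + s - 1`.
#' @param n_boot bootstrap replicates per model (default 200; intervals are
#'   not part of the recovery metrics).
#' @param noise_sd sounding-noise level passed to the seascape (default 0).
#' @param ... further scenario overrides passed to [default_scenario()].
#' @return data.frame, one row per seed.
#' @export
recovery_study <- function(n_seeds = 20, base_seed = 1, n_boot = 200,
                           noise_sd = 0, ...) {
  planted <- c("DETRND", "F7S", "RNG25", "HYP5")
  rows <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    sc <- default_scenario(seed = base_seed + s - 1L,
                           substrate_noise = 0, biota_noise = 0, ...)
    sc$seascape$noise_sd <- noise_sd
    cfg <- pipeline_config(scenario = sc, n_boot = n_boot)
    res <- run_pipeline(cfg, maps = FALSE, semivariograms = FALSE)
    lob <- res$lobster
    used <- setdiff(unique(lob$tree$frame$var), "<leaf>")
    contrib <- variable_contribution(lob$tree)
    rows[[s]] <- data.frame(
      seed = sc$seed,
      geophysical_only = all(used %in% terrain_codes()),
      planted_share = sum(contrib[names(contrib) %in% planted]),
      auc_random = if (!is.null(lob$report)) lob$report$auc else NA_real_,
      auc_spatial = if (!is.null(lob$spatial_report)) lob$spatial_report$auc else NA_real_,
      adj_d2 = lob$fit$adj_d2,
      terminal_nodes = n_leaves(lob$tree),
      vars = paste(sort(used), collapse = "+"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
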