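#' @title Spatial dependence diagnostics
#' @description Indicator semivariograms for binary (presence/absence or
#'   class-indicator) point data, and block-based spatially independent
#'   validation splits used to measure how spatial autocorrelation inflates
#'   apparent model accuracy.
#' @name spatial
NULL

#' Indicator semivariogram
#'
#' Omnidirectional empirical semivariogram of a 0/1 indicator:
#' `gamma(h) = sum over pairs in bin (I_i - I_j)^2 / (2 N(h))` over all
#' unordered point pairs whose separation falls in the lag bin. For a
#' spatially independent indicator with prevalence `q` the sill is
#' `q (1 - q)` at every lag. Invariant to relabelling 0 and 1.
#'
#' @param x,y point coordinates (m).
#' @param indicator 0/1 values, one per point.
#' @param bin_width lag bin width (m); default max_lag / 15.
#' @param max_lag largest lag considered (m); default half the diagonal of
#'   the point bounding box.
#' @return data.frame of class `semivariogram`: `lag` (bin centre), `gamma`,
#'   `n_pairs` (`gamma` is `NA` for empty bins).
#' @export
indicator_semivariogram <- function(x, y, indicator, bin_width = NULL,
                                    max_lag = NULL) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  if (diff(range(x)) < 1e-12 && diff(range(y)) < 1e-12) {
    stop("all coordinates identical; semivariogram undefined", call. = FALSE)
  }
  indicator <- as.numeric(indicator)
  if (is.null(max_lag)) {
    max_lag <- sqrt(diff(range(x))^2 + diff(range(y))^2) / 2
  }
  if (is.null(bin_width)) bin_width <- max_lag / 15
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  h <- as.vector(stats::dist(cbind(x, y)))
  d2 <- as.vector(stats::dist(indicator))^2
  keep <- h <= max_lag & h > 0
  h <- h[keep]; d2 <- d2[keep]
  nbin <- ceiling(max_lag / bin_width)
  bin <- pmin(floor(h / bin_width) + 1L, nbin)
  n_pairs <- tabulate(bin, nbins = nbin)
  ssd <- vapply(seq_len(nbin), function(b) sum(d2[bin == b]), 0)
  gamma <- ifelse(n_pairs > 0, ssd / (2 * n_pairs), NA_real_)
  out <- data.frame(lag = (seq_len(nbin) - 0.5) * bin_width,
                    gamma = gamma, n_pairs = n_pairs)
  attr(out, "bin_width") <- bin_width
  attr(out, "max_lag") <- max_lag
  class(out) <- c("semivariogram", "data.frame")
  out
}

#' Spatially independent validation split
#'
#' Tiles the point bounding box into square blocks of side `block_size` and
#' assigns whole blocks (in seeded random order) to the validation set until
#' it holds at least `holdout_fraction` of the points. With `buffer = TRUE`,
#' model-set points in blocks adjacent (8-neighbourhood) to any validation
#' block are dropped, guaranteeing a minimum separation of one block between
#' the two sets.
#'
#' @param x,y point coordinates (m).
#' @param holdout_fraction fraction of points for validation (0 < f < 1).
#' @param block_size block edge length (m).
#' @param seed integer seed for block ordering.
#' @param buffer drop model points in blocks bordering validation blocks.
#' @return list with integer index vectors `model`, `validation`, `dropped`.
#' @export
spatial_split <- function(x, y, holdout_fraction, block_size, seed = 1,
                          buffer = FALSE) {
  n <- length(x)
  if (block_size <= 0) stop("`block_size` must be positive", call. = FALSE)
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("`holdout_fraction` must be in (0, 1)", call. = FALSE)
  }
  bi <- floor((x - min(x)) / block_size)
  bj <- floor((y - min(y)) / block_size)
  key <- paste(bi, bj)
  blocks <- unique(key)
  if (length(blocks) < 2L) {
    stop("block_size leaves fewer than 2 occupied blocks; split unreachable",
         call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  ord <- sample(blocks)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  counts <- table(key)[ord]
  target <- holdout_fraction * n
  cum <- cumsum(counts)
  n_val_blocks <- which(cum >= target)[1]
  if (n_val_blocks >= length(blocks)) {
    stop("holdout fraction unreachable: validation would take every block",
         call. = FALSE)
  }
  val_blocks <- ord[seq_len(n_val_blocks)]
  is_val <- key %in% val_blocks
  dropped <- integer(0)
  if (buffer) {
    vb <- do.call(rbind, lapply(strsplit(val_blocks, " "), as.numeric))
    near <- vapply(seq_len(n), function(i) {
      any(abs(bi[i] - vb[, 1]) <= 1 & abs(bj[i] - vb[, 2]) <= 1)
    }, logical(1))
    dropped <- which(!is_val & near)
  }
  model <- setdiff(which(!is_val), dropped)
  if (!length(model)) {
    stop("holdout fraction unreachable: no model points remain", call. = FALSE)
  }
  list(model = model, validation = which(is_val), dropped = dropped)
}

#' Write a semivariogram as CSV
#'
#' @param sv a [indicator_semivariogram()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_semivariogram_csv <- function(sv, path) {
  utils::write.csv(as.data.frame(sv), path, row.names = FALSE)
  invisible(path)
}
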