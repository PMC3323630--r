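# Independent brute-force oracles used across the suite. Each oracle is a
# naive direct implementation, kept deliberately separate from the package's
# code paths.

# per-cell circular-kernel statistic by exhaustive scan over every cell pair
oracle_focal <- function(values, cell_size, radius, stat) {
  nr <- nrow(values); nc <- ncol(values)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- c()
      for (ii in seq_len(nr)) {
        for (jj in seq_len(nc)) {
          d <- cell_size * sqrt((ii - i)^2 + (jj - j)^2)
          if (d <= radius + 1e-9 && !is.na(values[ii, jj])) {
            vals <- c(vals, values[ii, jj])
          }
        }
      }
      n <- length(vals)
      out[i, j] <- switch(stat,
        mean = if (n > 0) mean(vals) else NA_real_,
        sd = if (n >= 3) sqrt(mean((vals - mean(vals))^2)) else NA_real_,
        range = if (n > 0) max(vals) - min(vals) else NA_real_,
        hyp = if (n > 0) {
          rel <- max(vals) - min(vals)
          if (rel < 1e-12 || is.na(values[i, j])) {
            if (is.na(values[i, j])) NA_real_ else 0.5
          } else (max(vals) - values[i, j]) / rel
        } else NA_real_)
    }
  }
  out
}

# exhaustive best-split search over every (predictor, midpoint) pair
oracle_best_split <- function(X, y, mincut = 5) {
  dev2 <- function(n0, n1) {
    n <- n0 + n1
    t0 <- if (n0 > 0) n0 * log(n0 / n) else 0
    t1 <- if (n1 > 0) n1 * log(n1 / n) else 0
    -2 * (t0 + t1)
  }
  parent <- dev2(sum(y == 0), sum(y == 1))
  best <- NULL
  for (v in names(X)) {
    sv <- sort(unique(X[[v]]))
    if (length(sv) < 2) next
    for (k in seq_len(length(sv) - 1)) {
      thr <- (sv[k] + sv[k + 1]) / 2
      left <- X[[v]] < thr
      if (min(sum(left), sum(!left)) < mincut) next
      red <- parent -
        dev2(sum(y[left] == 0), sum(y[left] == 1)) -
        dev2(sum(y[!left] == 0), sum(y[!left] == 1))
      if (red > 1e-12 && (is.null(best) || red > best$reduction + 1e-12)) {
        best <- list(var = v, threshold = thr, reduction = red)
      }
    }
  }
  best
}

# Mann-Whitney AUC by explicit pair counting (ties count one half)
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# semivariogram by explicit enumeration of all unordered pairs
oracle_semivariogram <- function(x, y, ind, bin_width, max_lag) {
  nbin <- ceiling(max_lag / bin_width)
  ssd <- numeric(nbin); np <- integer(nbin)
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    h <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    if (h > 0 && h <= max_lag) {
      b <- min(floor(h / bin_width) + 1, nbin)
      ssd[b] <- ssd[b] + (ind[i] - ind[j])^2
      np[b] <- np[b] + 1L
    }
  }
  list(gamma = ifelse(np > 0, ssd / (2 * np), NA_real_), n_pairs = np)
}

# Jenness-style surface area of the central cell of a 3x3 patch via an
# explicit triangle mesh (midpoint vertices, vector cross products)
oracle_jenness_cell <- function(z, cell) {
  ctr <- c(0, 0, z[2, 2])
  off <- list(n = c(0, cell), ne = c(cell, cell), e = c(cell, 0),
              se = c(cell, -cell), s = c(0, -cell), sw = c(-cell, -cell),
              w = c(-cell, 0), nw = c(-cell, cell))
  zz <- c(n = z[1, 2], ne = c(z[1, 3]), e = z[2, 3], se = z[3, 3],
          s = z[3, 2], sw = z[3, 1], w = z[2, 1], nw = z[1, 1])
  ring <- c("n", "ne", "e", "se", "s", "sw", "w", "nw")
  tri_area <- function(a, b, c) {
    u <- b - a; v <- c - a
    0.5 * sqrt(sum(c(u[2] * v[3] - u[3] * v[2],
                     u[3] * v[1] - u[1] * v[3],
                     u[1] * v[2] - u[2] * v[1])^2))
  }
  tot <- 0
  for (k in 1:8) {
    a <- ring[k]; b <- ring[if (k == 8) 1 else k + 1]
    p1 <- c(off[[a]], zz[[a]]); p2 <- c(off[[b]], zz[[b]])
    # halved triangle: midpoints of centre->neighbour edges and the
    # neighbour-neighbour midpoint chord scale area by 1/4
    tot <- tot + tri_area(ctr, p1, p2) / 4
  }
  tot
}

# small raster helper
mk_raster <- function(m, cell = 3, code = "DTH") {
  raster_grid(m, cell_size = cell, code = code)
}

# deterministic separable training set with a planted 2-variable signal
planted_xy <- function(n, seed, noise_preds = 0) {
  set.seed(seed)
  X <- data.frame(a = runif(n), b = runif(n))
  y <- as.integer(X$a > 0.5 & X$b < 0.6)
  if (noise_preds > 0) {
    for (k in seq_len(noise_preds)) X[[paste0("noise", k)]] <- runif(n)
  }
  list(X = X, y = y)
}
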