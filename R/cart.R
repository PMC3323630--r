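#' @title Deviance-based binary classification trees
#' @description Recursive binary partitioning of a presence/absence response
#'   by minimising multinomial node deviance, with cost-complexity
#'   (weakest-link) pruning guided by ten-fold cross-validated
#'   misclassification. This is the statistical engine behind every habitat
#'   and lobster model in the package.
#' @name cart
NULL

#' Growth controls for tree fitting
#'
#' Defaults follow the classic S recursive-partitioning conventions: a node is
#' split only when it holds at least `minsize` observations and its own
#' deviance is at least `mindev` times the root deviance, and each child must
#' receive at least `mincut` observations.
#'
#' @param minsize smallest node that may be split (default 10).
#' @param mincut smallest allowed child node (default 5).
#' @param mindev minimum node deviance, as a fraction of root deviance, for a
#'   split to be attempted (default 0.01).
#' @param max_depth maximum tree depth (root = depth 1; default unlimited).
#' @return list of class `growth_control`.
#' @export
growth_control <- function(minsize = 10, mincut = 5, mindev = 0.01,
                           max_depth = Inf) {
  if (minsize <= 0 || mincut <= 0 || mindev <= 0 || max_depth <= 0) {
    stop("all growth controls must be positive", call. = FALSE)
  }
  structure(list(minsize = minsize, mincut = mincut, mindev = mindev,
                 max_depth = max_depth),
            class = "growth_control")
}

# vectorised two-class deviance from count vectors
binom_dev <- function(n0, n1) {
  n <- n0 + n1
  t0 <- ifelse(n0 > 0, n0 * log(n0 / n), 0)
  t1 <- ifelse(n1 > 0, n1 * log(n1 / n), 0)
  -2 * (t0 + t1)
}

#' Deviance of a binary class-count node
#'
#' Multinomial deviance `D = -2 * sum_k n_k * ln(n_k / n)` with the convention
#' `0 * ln 0 = 0` (natural log). Zero iff the node is pure.
#'
#' @param counts length-2 vector `(n_absent, n_present)` of non-negative counts.
#' @return non-negative deviance.
#' @export
node_deviance <- function(counts) {
  if (length(counts) != 2L || any(counts < 0)) {
    stop("`counts` must be two non-negative numbers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("node has no observations", call. = FALSE)
  binom_dev(counts[1], counts[2])
}

#' Best single split of a node
#'
#' Searches every predictor and every midpoint threshold between consecutive
#' distinct sorted values for the split maximising
#' `deviance(parent) - deviance(left) - deviance(right)`, subject to the
#' child-size control. Ties are broken in favour of the predictor declared
#' earlier in `names(X)`, then the smaller threshold. Rows with `x < threshold`
#' go left.
#'
#' @param X data.frame of numeric predictors.
#' @param y binary response (0/1).
#' @param control a [growth_control()].
#' @return list with `var`, `threshold`, `reduction`, or `NULL` when no
#'   admissible split exists.
#' @export
best_split <- function(X, y, control = growth_control()) {
  n <- length(y)
  n1 <- sum(y)
  parent <- binom_dev(n - n1, n1)
  if (parent <= 0) return(NULL)
  best <- NULL
  for (v in names(X)) {
    x <- X[[v]]
    o <- order(x)
    xs <- x[o]
    c1 <- cumsum(y[o])
    k <- which(xs[-n] < xs[-1])
    if (!length(k)) next
    k <- k[pmin(k, n - k) >= control$mincut]
    if (!length(k)) next
    c0 <- k - c1[k]
    devL <- binom_dev(c0, c1[k])
    devR <- binom_dev((n - n1) - c0, n1 - c1[k])
    red <- parent - (devL + devR)
    i <- which.max(red)
    if (red[i] > 1e-12 && (is.null(best) || red[i] > best$reduction + 1e-12)) {
      best <- list(var = v, threshold = (xs[k[i]] + xs[k[i] + 1]) / 2,
                   reduction = red[i])
    }
  }
  best
}

#' Grow a deviance classification tree
#'
#' Recursively applies [best_split()] until the growth controls stop it.
#' A single-class response yields a single-leaf tree (not an error). Rows
#' containing missing predictor values must be excluded beforehand.
#'
#' @param X data.frame of numeric predictors (no `NA`).
#' @param y binary response (0/1 or logical).
#' @param control a [growth_control()].
#' @return an object of class `benthic_tree`.
#' @export
grow_tree <- function(X, y, control = growth_control()) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("`y` must be binary 0/1", call. = FALSE)
  if (nrow(X) != length(y)) stop("`X` and `y` lengths differ", call. = FALSE)
  if (anyNA(X)) {
    stop("`X` contains missing values; exclude those rows first", call. = FALSE)
  }
  n_all <- length(y)
  root_dev <- binom_dev(n_all - sum(y), sum(y))
  rows <- list()
  build <- function(idx, id, depth) {
    yy <- y[idx]
    n <- length(yy); n1 <- sum(yy); n0 <- n - n1
    dev <- binom_dev(n0, n1)
    sp <- NULL
    if (n >= control$minsize && depth < control$max_depth &&
        dev >= control$mindev * root_dev) {
      sp <- best_split(X[idx, , drop = FALSE], yy, control)
      # min-reduction gate: a split must buy at least the mindev fraction of
      # the root deviance (the classic S stopping rule)
      if (!is.null(sp) && sp$reduction < control$mindev * root_dev) sp <- NULL
    }
    if (is.null(sp)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        id = id, var = "<leaf>", threshold = NA_real_, n = n, n0 = n0, n1 = n1,
        dev = dev, prob = n1 / n, reduction = NA_real_,
        stringsAsFactors = FALSE)
      return(invisible(NULL))
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, var = sp$var, threshold = sp$threshold, n = n, n0 = n0, n1 = n1,
      dev = dev, prob = n1 / n, reduction = sp$reduction,
      stringsAsFactors = FALSE)
    left <- X[[sp$var]][idx] < sp$threshold
    build(idx[left], 2 * id, depth + 1L)
    build(idx[!left], 2 * id + 1, depth + 1L)
  }
  build(seq_len(n_all), 1, 1L)
  frame <- do.call(rbind, rows)
  structure(list(frame = frame, predictors = names(X), control = control,
                 n = n_all, root_dev = root_dev),
            class = "benthic_tree")
}

#' @export
print.benthic_tree <- function(x, ...) {
  nl <- sum(x$frame$var == "<leaf>")
  cat(sprintf("<benthic_tree> n = %d, %d terminal nodes, root deviance %.4g\n",
              x$n, nl, x$root_dev))
  used <- setdiff(unique(x$frame$var), "<leaf>")
  if (length(used)) cat("  splits on:", paste(used, collapse = ", "), "\n")
  invisible(x)
}

#' Number of terminal nodes
#' @param tree a `benthic_tree`.
#' @return integer leaf count.
#' @export
n_leaves <- function(tree) sum(tree$frame$var == "<leaf>")

#' Predict presence probability
#'
#' Routes each row to its leaf (rows with `x < threshold` go left) and returns
#' the leaf's empirical presence fraction.
#'
#' @param tree a `benthic_tree`.
#' @param X data.frame holding every predictor the tree splits on.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(tree, X) {
  fr <- tree$frame
  need <- setdiff(unique(fr$var), "<leaf>")
  missing <- setdiff(need, names(X))
  if (length(missing)) {
    stop("X is missing predictor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  node <- rep(1, nrow(X))
  for (r in seq_len(nrow(fr))) {       # preorder: parents precede children
    if (fr$var[r] == "<leaf>") next
    sel <- which(!is.na(node) & node == fr$id[r])
    if (!length(sel)) next
    left <- X[[fr$var[r]]][sel] < fr$threshold[r]   # NA predictor -> NA leaf
    node[sel] <- ifelse(left, 2 * fr$id[r], 2 * fr$id[r] + 1)
  }
  fr$prob[match(node, fr$id)]
}

# ---- cost-complexity pruning -------------------------------------------------

# per-node branch leaf-deviance sum, leaf count and weakest-link g
branch_g <- function(frame) {
  nr <- nrow(frame)
  S <- numeric(nr); L <- integer(nr)
  pos <- match(frame$id, frame$id)  # identity; frame is preorder
  for (r in nr:1) {
    if (frame$var[r] == "<leaf>") {
      S[r] <- frame$dev[r]; L[r] <- 1L
    } else {
      ch <- match(c(2 * frame$id[r], 2 * frame$id[r] + 1), frame$id)
      S[r] <- S[ch[1]] + S[ch[2]]
      L[r] <- L[ch[1]] + L[ch[2]]
    }
  }
  g <- ifelse(L > 1L, (frame$dev - S) / (L - 1L), Inf)
  list(S = S, L = L, g = g)
}

# collapse the branch rooted at each id in `ids` into a leaf
collapse_nodes <- function(frame, ids) {
  drop <- logical(nrow(frame))
  is_desc <- function(id, anc) {
    while (id > anc) id <- floor(id / 2)
    id == anc
  }
  for (r in seq_len(nrow(frame))) {
    for (a in ids) {
      if (frame$id[r] != a && is_desc(frame$id[r], a)) drop[r] <- TRUE
    }
  }
  keep <- frame[!drop, , drop = FALSE]
  sel <- keep$id %in% ids
  keep$var[sel] <- "<leaf>"
  keep$threshold[sel] <- NA_real_
  keep$reduction[sel] <- NA_real_
  keep
}

# weakest-link sequence: frames, their sizes and the alpha at which each
# subtree becomes optimal (alpha[1] = 0 for the full tree)
prune_sequence_frames <- function(frame) {
  frames <- list(frame)
  alphas <- 0
  cur <- frame
  while (sum(cur$var == "<leaf>") > 1L) {
    bg <- branch_g(cur)
    internal <- which(cur$var != "<leaf>")
    gmin <- min(bg$g[internal])
    weak <- cur$id[internal][bg$g[internal] <= gmin + 1e-12]
    cur <- collapse_nodes(cur, weak)
    frames[[length(frames) + 1L]] <- cur
    alphas <- c(alphas, gmin)
  }
  list(frames = frames, alphas = alphas,
       sizes = vapply(frames, function(f) sum(f$var == "<leaf>"), 0L))
}

# prune a frame at complexity alpha (collapse while min g <= alpha)
prune_frame_at <- function(frame, alpha) {
  repeat {
    internal <- which(frame$var != "<leaf>")
    if (!length(internal)) return(frame)
    bg <- branch_g(frame)
    gmin <- min(bg$g[internal])
    if (gmin > alpha + 1e-12) return(frame)
    weak <- frame$id[internal][bg$g[internal] <= gmin + 1e-12]
    frame <- collapse_nodes(frame, weak)
  }
}

with_frame <- function(tree, frame) {
  tree$frame <- frame
  tree
}

#' Cross-validation cost-complexity pruning
#'
#' Builds the deviance-based weakest-link subtree sequence of the grown tree,
#' estimates each subtree's misclassification rate by `folds`-fold
#' cross-validation (the tree is regrown on each fold complement and pruned to
#' the candidate complexity), and returns the smallest subtree whose mean CV
#' misclassification rate is at most `rate_threshold`. The threshold is only
#' applied when it is informative: for a class rarer than the threshold even
#' the single-leaf tree (predict always-absent) meets it, so whenever the
#' root subtree satisfies the threshold — and likewise when no subtree does —
#' the CV-misclassification-minimising size is selected instead. Ties go to
#' the smaller tree. A row is classed as present when its predicted
#' probability is at least 0.5. Fold assignment is seeded and reproducible.
#'
#' @param tree a grown `benthic_tree`.
#' @param X,y the training data the tree was grown on.
#' @param folds number of cross-validation folds (default 10).
#' @param rate_threshold acceptable mean CV misclassification rate
#'   (default 0.15).
#' @param seed integer seed for fold assignment.
#' @return list with `tree` (the pruned model) and `sequence` (data.frame:
#'   `alpha`, `size`, per-fold rates as a matrix attribute, `cv_misclass`).
#' @export
cv_prune <- function(tree, X, y, folds = 10, rate_threshold = 0.15, seed = 1) {
  y <- as.integer(y)
  n <- length(y)
  if (folds < 2) stop("`folds` must be at least 2", call. = FALSE)
  if (folds > n) stop("`folds` exceeds the number of observations", call. = FALSE)
  sq <- prune_sequence_frames(tree$frame)
  m <- length(sq$frames)
  if (m == 1L) {
    seq_df <- data.frame(alpha = 0, size = sq$sizes, cv_misclass = NA_real_)
    return(list(tree = tree, sequence = seq_df))
  }
  # candidate complexities: geometric means of consecutive sequence alphas
  a <- sq$alphas
  cand <- numeric(m)
  cand[1] <- 0
  for (k in 2:m) {
    nxt <- if (k < m) a[k + 1] else 2 * a[k]
    cand[k] <- if (a[k] > 0 && nxt > 0) sqrt(a[k] * nxt) else a[k]
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  rates <- matrix(NA_real_, m, folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    ft <- grow_tree(X[tr, , drop = FALSE], y[tr], tree$control)
    Xte <- X[!tr, , drop = FALSE]
    yte <- y[!tr]
    fr <- ft$frame
    for (k in seq_len(m)) {
      fr <- prune_frame_at(fr, cand[k])   # sequence is nested; prune onward
      p <- predict_prob(with_frame(ft, fr), Xte)
      rates[k, f] <- mean((p >= 0.5) != yte)
    }
  }
  mean_rate <- rowMeans(rates)
  eligible <- which(mean_rate <= rate_threshold)
  threshold_binding <- length(eligible) > 0 && mean_rate[m] > rate_threshold
  if (threshold_binding) {
    k_star <- eligible[which.min(sq$sizes[eligible])]
  } else {
    best <- min(mean_rate)
    k_star <- max(which(mean_rate <= best + 1e-12))  # ties -> smaller tree
  }
  seq_df <- data.frame(alpha = cand, size = sq$sizes, cv_misclass = mean_rate)
  attr(seq_df, "fold_rates") <- rates
  list(tree = with_frame(tree, sq$frames[[k_star]]), sequence = seq_df)
}

#' Explained deviance and adjusted D-squared
#'
#' `D^2 = (D_null - D_model) / D_null` evaluated on the supplied data, with
#' `AdjD^2 = 1 - ((n - 1) / (n - p)) * (1 - D^2)` where `p` is the number of
#' terminal nodes. On data other than the training set a row can fall in a
#' leaf whose empirical rate is 0 or 1 for the opposite class; the evaluated
#' log-probability is floored at `log(1e-3)` so the deviance stays finite
#' (a pure leaf predicting its own class still contributes exactly zero).
#'
#' @param tree a `benthic_tree`.
#' @param X,y evaluation data (training data for the fit statistic).
#' @return list with `d2`, `adj_d2`, `n`, `p`.
#' @export
adjusted_d2 <- function(tree, X, y) {
  y <- as.integer(y)
  n <- length(y)
  p <- n_leaves(tree)
  if (n <= p) stop("adjusted D^2 undefined: n <= terminal nodes", call. = FALSE)
  eps <- 1e-3
  pr <- predict_prob(tree, X)
  ll <- y * log(pmax(pr, eps)) + (1 - y) * log(pmax(1 - pr, eps))
  d_model <- -2 * sum(ll)
  q <- mean(y)
  if (q <= 0 || q >= 1) {
    d2 <- 0
  } else {
    d_null <- -2 * sum(y * log(q) + (1 - y) * log(1 - q))
    d2 <- (d_null - d_model) / d_null
  }
  adj <- 1 - ((n - 1) / (n - p)) * (1 - d2)
  list(d2 = d2, adj_d2 = adj, n = n, p = p)
}

#' Per-variable share of explained deviance
#'
#' Sums the deviance reduction of every split a variable makes and expresses
#' it as a percentage of the tree's total deviance reduction (the Table-style
#' contribution breakdown). Percentages sum to 100.
#'
#' @param tree a `benthic_tree`.
#' @return named numeric vector (percent); empty for a single-leaf tree.
#' @export
variable_contribution <- function(tree) {
  fr <- tree$frame
  int <- fr$var != "<leaf>"
  if (!any(int)) return(stats::setNames(numeric(0), character(0)))
  red <- tapply(fr$reduction[int], fr$var[int], sum)
  out <- 100 * red / sum(red)
  out <- out[order(-out)]
  stats::setNames(as.numeric(out), names(out))
}

#' Deviance-explained cost of dropping a predictor
#'
#' Refits (grow + CV prune) without the named predictor and reports the drop
#' in training adjusted D-squared relative to the full model. Dropping the
#' only predictor reports the full model's adjusted D-squared (everything is
#' lost).
#'
#' @param X,y training data.
#' @param code predictor column to drop.
#' @param control a [growth_control()].
#' @param seed fold seed passed to [cv_prune()].
#' @param folds,rate_threshold pruning settings.
#' @return list with `change`, `full_adj_d2`, `reduced_adj_d2`.
#' @export
drop_term <- function(X, y, code, control = growth_control(), seed = 1,
                      folds = 10, rate_threshold = 0.15) {
  if (!code %in% names(X)) stop("`code` is not a column of X", call. = FALSE)
  full <- cv_prune(grow_tree(X, y, control), X, y, folds = folds,
                   rate_threshold = rate_threshold, seed = seed)
  full_adj <- adjusted_d2(full$tree, X, y)$adj_d2
  if (ncol(X) == 1L) {
    return(list(change = full_adj, full_adj_d2 = full_adj,
                reduced_adj_d2 = 0))
  }
  Xr <- X[, setdiff(names(X), code), drop = FALSE]
  red <- cv_prune(grow_tree(Xr, y, control), Xr, y, folds = folds,
                  rate_threshold = rate_threshold, seed = seed)
  red_adj <- adjusted_d2(red$tree, Xr, y)$adj_d2
  list(change = full_adj - red_adj, full_adj_d2 = full_adj,
       reduced_adj_d2 = red_adj)
}

# ---- plain-text serialization ------------------------------------------------

#' Write a tree to a plain-text file
#'
#' One row per node (id, split variable, threshold, class counts, deviance,
#' leaf probability, split reduction) preceded by comment lines recording the
#' predictor set and training size. Round-trips through [read_tree()].
#'
#' @param tree a `benthic_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# predictors: ", paste(tree$predictors, collapse = ",")),
    sprintf("# n: %d", tree$n),
    sprintf("# root_dev: %.17g", tree$root_dev),
    sprintf("# control: minsize=%g mincut=%g mindev=%g max_depth=%g",
            tree$control$minsize, tree$control$mincut, tree$control$mindev,
            tree$control$max_depth)
  ), con)
  utils::write.table(tree$frame, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a tree written by [write_tree()]
#'
#' @param path file path.
#' @return a `benthic_tree`.
#' @export
read_tree <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) sub(paste0("# ", key, ": "), "", hdr[startsWith(hdr, paste0("# ", key, ":"))])
  preds <- strsplit(get("predictors"), ",")[[1]]
  ctrl_raw <- strsplit(get("control"), " ")[[1]]
  ctrl_vals <- as.numeric(sub(".*=", "", ctrl_raw))
  names(ctrl_vals) <- sub("=.*", "", ctrl_raw)
  frame <- utils::read.table(text = paste(lines[!startsWith(lines, "#")],
                                          collapse = "\n"),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  structure(list(frame = frame, predictors = preds,
                 control = growth_control(ctrl_vals[["minsize"]],
                                          ctrl_vals[["mincut"]],
                                          ctrl_vals[["mindev"]],
                                          ctrl_vals[["max_depth"]]),
                 n = as.integer(get("n")),
                 root_dev = as.numeric(get("root_dev"))),
            class = "benthic_tree")
}
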